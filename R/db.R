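# In-house CNV database: calls predicted from the reference exome
# collection, kept per program (quality-score scales are not comparable
# across callers). Screening a query against it yields:
#   db_count - number of DISTINCT reference samples with an overlapping
#              same-type call (recurrence flags coverage artifacts)
#   cnvq     - median quality score of the overlapping database calls
#              (recurrent technical artifacts have low medians; real
#              variants score high)

#' Build an in-house CNV database from reference-collection call sets
#'
#' One database per prediction program: score scales differ across
#' programs, so mixing programs in one database is rejected.
#'
#' @param call_sets list of canonical call data.frames, one per reference
#'   sample (each must have a single, non-empty `sample_id`; IDs must be
#'   unique across sets). A single data.frame covering several samples is
#'   also accepted and is split on `sample_id`.
#' @param program the prediction program the calls came from.
#' @return object of class `cnv_db` with fields `program`, `entries`
#'   (data.frame: chrom, start, end, cnv_type, score, sample_id),
#'   `n_samples`, and an overlap index.
#' @export
build_db <- function(call_sets, program) {
  program <- as.character(program)
  if (is.data.frame(call_sets))
    call_sets <- split(call_sets, call_sets$sample_id)
  if (length(call_sets) == 0L)
    stop("empty reference collection: at least one sample call set required")
  sids <- vapply(seq_along(call_sets), function(i) {
    cs <- call_sets[[i]]
    if (nrow(cs) == 0L) {
      # a reference sample with no calls still counts toward n_samples
      nm <- names(call_sets)[i]
      return(if (!is.null(nm) && nzchar(nm)) nm else sprintf(".empty%d", i))
    }
    u <- unique(as.character(cs$sample_id))
    if (length(u) != 1L || is.na(u) || !nzchar(u))
      stop("each call set must carry exactly one non-empty sample_id")
    u
  }, "")
  if (anyDuplicated(sids))
    stop(sprintf("duplicate sample IDs in reference collection: %s",
                 paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  entries <- do.call(rbind, lapply(call_sets, function(cs) {
    bad <- unique(cs$program[cs$program != program])
    if (length(bad))
      stop(sprintf("call set for sample '%s' contains program(s) %s; database is %s",
                   unique(cs$sample_id), paste(bad, collapse = ", "), program))
    cs[, c("chrom", "start", "end", "cnv_type", "score", "sample_id")]
  }))
  rownames(entries) <- NULL
  if (any(!is.finite(entries$score)))
    stop("non-finite quality score in reference collection")
  entries$chrom <- normalize_chrom(entries$chrom)
  validate_interval_frame(entries, "database entries")
  structure(list(program = program,
                 entries = entries,
                 n_samples = length(sids),
                 index = build_index(entries)),
            class = "cnv_db")
}

#' @export
print.cnv_db <- function(x, ...) {
  cat(sprintf("In-house CNV database: %d calls from %d reference sample(s), program %s\n",
              nrow(x$entries), x$n_samples, x$program))
  invisible(x)
}

#' Write / read an in-house database
#'
#' The entry table is tab-delimited (chrom, start, end, cnv_type, score,
#' sample_id), coordinate-sorted; program and sample count travel in a JSON
#' sidecar `<path>.meta.json`. The write/read round trip is lossless.
#'
#' @param db a `cnv_db`.
#' @param path path for the entry table.
#' @return `write_db`: invisibly, the path. `read_db`: a `cnv_db`.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "cnv_db"))
  e <- db$entries
  e <- e[order(e$chrom, e$start, e$end, e$sample_id), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  jsonlite::write_json(list(program = db$program, n_samples = db$n_samples),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_db
#' @export
read_db <- function(path) {
  if (!file.exists(path)) stop(sprintf("database file not found: %s", path))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("database metadata sidecar not found: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  e <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  e$start <- as.integer(e$start); e$end <- as.integer(e$end)
  e$score <- as.numeric(e$score)
  validate_interval_frame(e, "database entries")
  structure(list(program = meta$program,
                 entries = e,
                 n_samples = as.integer(meta$n_samples),
                 index = build_index(e)),
            class = "cnv_db")
}

#' Query the in-house database with one CNV call
#'
#' Matches are database entries sharing >= 1 bp with the query and, by
#' default, carrying the same CNV type (a duplication in the reference
#' collection says nothing about a deletion query). `db_count` counts
#' distinct reference samples among the matches; `cnvq` is the median of
#' their quality scores — defined here for any db_count >= 1 (the median
#' of a single score is that score), and missing (NA) when nothing
#' overlaps.
#'
#' @param db a `cnv_db`.
#' @param query a one-row canonical call data.frame (or list with chrom,
#'   start, end, cnv_type, sample_id).
#' @param exclude_sample drop database entries from the query's own sample
#'   before counting (default TRUE: when the query sample is part of the
#'   reference collection its own calls would trivially match themselves).
#' @param type_blind match ignoring DEL/DUP (default FALSE).
#' @return list(db_count, cnvq, matches) where matches is the data.frame
#'   of matching entries.
#' @export
query_db <- function(db, query, exclude_sample = TRUE, type_blind = FALSE) {
  stopifnot(inherits(db, "cnv_db"))
  m <- query_index(db$index, query$chrom, query$start, query$end)
  if (!type_blind && !is.null(query$cnv_type))
    m <- m[m$cnv_type == as.character(query$cnv_type), , drop = FALSE]
  if (exclude_sample && !is.null(query$sample_id))
    m <- m[m$sample_id != as.character(query$sample_id), , drop = FALSE]
  n <- length(unique(m$sample_id))
  list(db_count = n,
       cnvq = if (nrow(m) >= 1L) stats::median(m$score) else NA_real_,
       matches = m)
}

#' Screen CNV calls against the in-house database
#'
#' The first analysis stage after parsing: attaches to every call the
#' quality metadata (`cnvq`, `db_count`) obtained from [query_db()] with
#' self-exclusion. Calls must come from the same program as the database;
#' cross-program CNVQ is meaningless because score scales differ.
#'
#' @param calls canonical call data.frame.
#' @param db a `cnv_db` for the same program.
#' @param exclude_xy drop calls on X/Y before screening (mixed-sex
#'   reference collections bias sex-chromosome prediction).
#' @param keep_self disable self-exclusion (see [query_db()]).
#' @param type_blind match ignoring DEL/DUP.
#' @return the input calls (order preserved, minus X/Y rows when
#'   `exclude_xy`) with columns `cnvq` and `db_count` appended.
#' @export
screen_calls <- function(calls, db, exclude_xy = FALSE, keep_self = FALSE,
                         type_blind = FALSE) {
  stopifnot(inherits(db, "cnv_db"))
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) > 0L) {
    bad <- unique(calls$program[calls$program != db$program])
    if (length(bad))
      stop(sprintf("calls from program(s) %s screened against a %s database; scores are not comparable across programs",
                   paste(bad, collapse = ", "), db$program))
    calls$chrom <- normalize_chrom(calls$chrom)
  }
  if (exclude_xy && nrow(calls) > 0L)
    calls <- calls[!is_sex_chromosome(calls$chrom), , drop = FALSE]
  rownames(calls) <- NULL
  if (nrow(calls) == 0L) {
    calls$cnvq <- numeric(0); calls$db_count <- integer(0)
    return(calls)
  }
  pairs <- overlap_pairs(calls, db$entries)
  if (nrow(pairs) > 0L) {
    keep <- rep(TRUE, nrow(pairs))
    if (!type_blind)
      keep <- keep & (calls$cnv_type[pairs$query] ==
                        db$entries$cnv_type[pairs$subject])
    if (!keep_self)
      keep <- keep & (calls$sample_id[pairs$query] !=
                        db$entries$sample_id[pairs$subject])
    pairs <- pairs[keep, , drop = FALSE]
  }
  cnvq <- rep(NA_real_, nrow(calls))
  db_count <- integer(nrow(calls))
  if (nrow(pairs) > 0L) {
    by_q <- split(pairs$subject, pairs$query)
    for (qi in names(by_q)) {
      i <- as.integer(qi); subj <- by_q[[qi]]
      db_count[i] <- length(unique(db$entries$sample_id[subj]))
      cnvq[i] <- stats::median(db$entries$score[subj])
    }
  }
  calls$cnvq <- cnvq
  calls$db_count <- db_count
  calls
}
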