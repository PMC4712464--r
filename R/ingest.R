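# Parsing of caller-native CNV tables into the canonical call frame.
#
# Canonical call frame columns (in order): chrom, start, end, cnv_type
# {DEL|DUP}, score, sample_id, program, then any passthrough columns kept
# verbatim from the native file.

CANONICAL_COLS <- c("chrom", "start", "end", "cnv_type", "score",
                    "sample_id", "program")

PROGRAMS <- c("ExomeCopy", "ExCopyDepth", "ExomeDepth", "CoNIFER", "XHMM",
              "other")

#' Normalise CNV type vocabulary
#'
#' Maps the vocabularies used by the different callers onto DEL/DUP:
#' deletion/del/loss -> DEL; duplication/dup/gain/insertion -> DUP.
#'
#' @param x character vector of type labels.
#' @return character vector of "DEL"/"DUP" (NA where unrecognised).
#' @export
normalize_cnv_type <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("del", "deletion", "loss")] <- "DEL"
  out[key %in% c("dup", "duplication", "gain", "insertion", "ins")] <- "DUP"
  out
}

#' Describe a caller's native output format
#'
#' A dialect maps native column names onto the canonical fields and states
#' the file's coordinate convention. Built-in dialects for the supported
#' read-depth programs are best-effort reconstructions of each program's
#' documented output (exact native layouts vary by version); any layout can
#' be described with a user dialect, see [read_dialect()].
#'
#' @param name one of "canonical", "exomedepth", "excopydepth", "xhmm",
#'   "conifer", "exomecopy", "bed".
#' @return an object of class `cnv_dialect`.
#' @export
#' @examples
#' dialect("xhmm")
dialect <- function(name) {
  name <- tolower(name)
  d <- switch(name,
    canonical = list(
      program = NA_character_,  # taken from the file's program column
      columns = c(chrom = "chrom", start = "start", end = "end",
                  cnv_type = "cnv_type", score = "score"),
      sample_column = "sample_id", program_column = "program",
      coords = "one_based_closed", header = TRUE),
    exomedepth = list(
      program = "ExomeDepth",
      columns = c(chrom = "chromosome", start = "start", end = "end",
                  cnv_type = "type", score = "BF"),
      coords = "one_based_closed", header = TRUE),
    excopydepth = list(
      program = "ExCopyDepth",
      columns = c(chrom = "chromosome", start = "start", end = "end",
                  cnv_type = "type", score = "BF"),
      coords = "one_based_closed", header = TRUE),
    xhmm = list(
      program = "XHMM",
      columns = c(cnv_type = "CNV", score = "Q_SOME"),
      interval_column = "INTERVAL",  # chr:start-end
      sample_column = "SAMPLE",
      coords = "one_based_closed", header = TRUE),
    conifer = list(
      program = "CoNIFER",
      columns = c(chrom = "chromosome", start = "start", end = "stop",
                  cnv_type = "state", score = "svd_zrpkm"),
      sample_column = "sampleID",
      abs_score = TRUE,  # signed SVD-ZRPKM in [-3, 3]; magnitude is the score
      coords = "one_based_closed", header = TRUE),
    exomecopy = list(
      program = "ExomeCopy",
      columns = c(chrom = "seqnames", start = "start", end = "end",
                  cnv_type = "type", score = "log.odds"),
      coords = "one_based_closed", header = TRUE),
    bed = list(
      program = "other",
      columns = c(chrom = "V1", start = "V2", end = "V3",
                  cnv_type = "V4", score = "V5"),
      coords = "zero_based_half_open", header = FALSE),
    stop(sprintf("unknown dialect '%s'", name))
  )
  d$name <- name
  if (is.null(d$abs_score)) d$abs_score <- FALSE
  structure(d, class = "cnv_dialect")
}

#' @export
print.cnv_dialect <- function(x, ...) {
  cat(sprintf("cnv_dialect '%s' (program %s, %s coordinates)\n",
              x$name, x$program, x$coords))
  invisible(x)
}

#' Read a dialect definition from a YAML file
#'
#' The file carries the `cnv_dialect` fields: `program`, a `columns` map
#' with keys chrom/start/end/cnv_type/score (or an `interval_column`),
#' optional `sample_column`, `coords` (`one_based_closed` or
#' `zero_based_half_open`), `header`, `abs_score`.
#'
#' @param path path to a YAML dialect file.
#' @return a `cnv_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) stop(sprintf("dialect file not found: %s", path))
  y <- yaml::read_yaml(path)
  d <- list(
    name = if (!is.null(y$name)) y$name else "custom",
    program = if (!is.null(y$program)) y$program else "other",
    columns = unlist(y$columns),
    interval_column = y$interval_column,
    sample_column = y$sample_column,
    program_column = y$program_column,
    coords = if (!is.null(y$coords)) y$coords else "one_based_closed",
    header = if (!is.null(y$header)) isTRUE(y$header) else TRUE,
    abs_score = isTRUE(y$abs_score)
  )
  if (!d$coords %in% c("one_based_closed", "zero_based_half_open"))
    stop("coords must be one_based_closed or zero_based_half_open")
  need <- c("cnv_type", "score")
  if (is.null(d$interval_column)) need <- c("chrom", "start", "end", need)
  miss <- setdiff(need, names(d$columns))
  if (length(miss))
    stop(sprintf("dialect columns map missing: %s", paste(miss, collapse = ", ")))
  structure(d, class = "cnv_dialect")
}

#' Parse a caller output file into canonical CNV calls
#'
#' Coordinates are converted to 1-based closed at this boundary (BED-style
#' input gains 1 on the start). For CoNIFER the stored score is the
#' absolute value of the signed SVD-ZRPKM statistic; the signed value is
#' kept in a `raw_score` passthrough column. Unmapped columns are preserved
#' verbatim after the canonical columns.
#'
#' Rows with non-numeric coordinates/scores or unrecognised CNV types are
#' dropped and reported (with their line numbers) in the `parse_errors`
#' attribute; input row count always equals output rows plus reported
#' errors.
#'
#' @param path input file.
#' @param dialect a `cnv_dialect`, or a built-in dialect name.
#' @param sample_id sample identifier to assign when the dialect has no
#'   sample column.
#' @return data.frame of canonical calls (attribute `parse_errors`:
#'   data.frame with columns line, message).
#' @export
parse_calls <- function(path, dialect = "canonical", sample_id = NULL) {
  if (is.character(dialect)) dialect <- dialect(dialect)
  stopifnot(inherits(dialect, "cnv_dialect"))
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))

  raw <- utils::read.delim(path, header = dialect$header, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  errors <- data.frame(line = integer(0), message = character(0))
  hdr <- if (dialect$header) 1L else 0L

  if (nrow(raw) == 0L)
    return(empty_calls(errors))

  # schema check: every mapped column must exist
  mapped <- unname(dialect$columns)
  if (!is.null(dialect$interval_column)) mapped <- c(mapped, dialect$interval_column)
  if (!is.null(dialect$sample_column)) mapped <- c(mapped, dialect$sample_column)
  if (!is.null(dialect$program_column) && dialect$program_column %in% names(raw)) {
    prog_col <- dialect$program_column
  } else prog_col <- NULL
  miss <- setdiff(setdiff(mapped, prog_col), names(raw))
  if (length(miss))
    stop(sprintf("input does not match dialect '%s': missing column(s) %s",
                 dialect$name, paste(miss, collapse = ", ")))

  if (!is.null(dialect$interval_column)) {
    iv <- raw[[dialect$interval_column]]
    m <- regmatches(iv, regexec("^([^:]+):([0-9]+)-([0-9]+)$", iv))
    ok_iv <- lengths(m) == 4L
    chrom <- ifelse(ok_iv, vapply(m, function(p) if (length(p) == 4L) p[2] else NA_character_, ""), NA)
    start <- ifelse(ok_iv, vapply(m, function(p) if (length(p) == 4L) p[3] else NA_character_, ""), NA)
    end   <- ifelse(ok_iv, vapply(m, function(p) if (length(p) == 4L) p[4] else NA_character_, ""), NA)
  } else {
    chrom <- raw[[dialect$columns[["chrom"]]]]
    start <- raw[[dialect$columns[["start"]]]]
    end   <- raw[[dialect$columns[["end"]]]]
  }
  type_raw  <- raw[[dialect$columns[["cnv_type"]]]]
  score_raw <- raw[[dialect$columns[["score"]]]]

  start_n <- suppressWarnings(as.numeric(start))
  end_n   <- suppressWarnings(as.numeric(end))
  score_n <- suppressWarnings(as.numeric(score_raw))
  type_n  <- normalize_cnv_type(type_raw)

  if (dialect$coords == "zero_based_half_open") start_n <- start_n + 1

  bad_coord <- is.na(start_n) | is.na(end_n) | start_n < 1 | end_n < start_n
  bad_score <- is.na(score_n) | !is.finite(score_n)
  bad_type  <- is.na(type_n)
  bad <- bad_coord | bad_score | bad_type
  if (any(bad)) {
    msg <- ifelse(bad_coord, "invalid coordinates",
           ifelse(bad_score, "non-numeric or non-finite score",
                  "unrecognised CNV type"))
    errors <- data.frame(line = which(bad) + hdr, message = msg[bad],
                         stringsAsFactors = FALSE)
  }

  keep <- !bad
  if (!any(keep)) return(empty_calls(errors))

  sid <- if (!is.null(dialect$sample_column)) {
    raw[[dialect$sample_column]]
  } else if (!is.null(sample_id)) {
    rep(as.character(sample_id), nrow(raw))
  } else rep(NA_character_, nrow(raw))
  if (!is.null(sample_id) && !is.null(dialect$sample_column) &&
      all(is.na(sid) | !nzchar(sid)))
    sid <- rep(as.character(sample_id), nrow(raw))

  prog <- if (!is.null(prog_col)) raw[[prog_col]]
          else rep(dialect$program, nrow(raw))

  score_out <- if (dialect$abs_score) abs(score_n) else score_n

  calls <- data.frame(
    chrom = normalize_chrom(chrom[keep]),
    start = as.integer(start_n[keep]),
    end = as.integer(end_n[keep]),
    cnv_type = type_n[keep],
    score = score_out[keep],
    sample_id = sid[keep],
    program = prog[keep],
    stringsAsFactors = FALSE
  )
  if (dialect$abs_score) calls$raw_score <- score_n[keep]

  # passthrough of unmapped native columns
  used <- unique(c(unname(dialect$columns), dialect$interval_column,
                   dialect$sample_column, prog_col))
  extra <- setdiff(names(raw), used)
  extra <- setdiff(extra, names(calls))
  for (col in extra) calls[[col]] <- raw[[col]][keep]

  rownames(calls) <- NULL
  attr(calls, "parse_errors") <- errors
  calls
}

empty_calls <- function(errors = data.frame(line = integer(0),
                                            message = character(0))) {
  calls <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cnv_type = character(0),
                      score = numeric(0), sample_id = character(0),
                      program = character(0), stringsAsFactors = FALSE)
  attr(calls, "parse_errors") <- errors
  calls
}

#' Write calls as canonical tab-delimited text
#'
#' Writes the canonical columns first, then any passthrough columns.
#' `parse_calls(write_calls(x), "canonical")` reproduces `x` field for
#' field. Missing values are written as "NA".
#'
#' @param calls canonical call data.frame.
#' @param path output path.
#' @param sort sort rows by (chrom, start) before writing (the convention
#'   for published tables); default FALSE preserves input order so the
#'   write/parse round trip is the identity.
#' @return invisibly, the path.
#' @export
write_calls <- function(calls, path, sort = FALSE) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  cols <- c(CANONICAL_COLS, setdiff(names(calls), CANONICAL_COLS))
  if (nrow(calls) > 0L) {
    miss <- setdiff(CANONICAL_COLS, names(calls))
    if (length(miss))
      stop(sprintf("calls missing canonical column(s): %s",
                   paste(miss, collapse = ", ")))
    calls <- calls[, cols, drop = FALSE]
    if (sort) calls <- calls[order(calls$chrom, calls$start, calls$end), ,
                             drop = FALSE]
  } else {
    calls <- empty_calls()[, , drop = FALSE]
  }
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a canonical calls/screened/annotated table
#'
#' @param path canonical TSV written by [write_calls()] or the pipeline
#'   stages.
#' @return data.frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", colClasses = "character")
  if (nrow(df) == 0L) {
    out <- empty_calls()
    for (col in setdiff(names(df), names(out))) out[[col]] <- character(0)
    return(out)
  }
  for (col in c("start", "end")) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(c("score", "cnvq", "raw_score"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("db_count" %in% names(df)) df$db_count <- as.integer(df$db_count)
  for (col in intersect(c("exon_count_internal", "phastcon_count",
                          "sanger_count", "dgv_count", "kg_del_count",
                          "kg_dup_count"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  for (col in intersect(c("utr5_overlap", "utr3_overlap",
                          "dgv_curated_inclusive", "dgv_curated_stringent"),
                        names(df)))
    df[[col]] <- as.logical(df[[col]])
  if ("phastcon_max_score" %in% names(df))
    df$phastcon_max_score <- as.numeric(df$phastcon_max_score)
  df
}
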