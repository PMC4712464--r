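# Annotation of screened CNVs from interval tracks, all under the same
# minimum-overlap rule: a single shared base between the CNV and a track
# record is enough (breakpoints from different platforms/programs rarely
# agree exactly).
#
# Track families:
#   gene/functional  - gencode (genes, exons, UTRs), phastcon conserved
#                      elements, haploinsufficiency and genic-intolerance
#                      scores (gene-keyed, joined via the gene overlap set)
#   known CNVs       - sanger high-resolution CNVs, raw DGV, curated DGV
#                      (inclusive/stringent maps + population frequencies),
#                      1000 Genomes deletions/duplications
#   clinical         - OMIM morbid map, DECIPHER DDD genes, ClinVar

TRACK_NAMES <- c("gencode", "phastcon", "haploinsufficiency",
                 "gene_intolerance", "sanger_cnv", "dgv", "dgv_curated",
                 "kg_cnv", "omim", "decipher_ddd", "clinvar")

TRACK_SCHEMAS <- list(
  gencode = c("gene_name", "gene_type", "gene_id", "transcript_id", "feature"),
  phastcon = c("score"),
  haploinsufficiency = c("gene_name", "hi_score"),
  gene_intolerance = c("gene_name", "rvis_score"),
  sanger_cnv = c("type"),
  dgv = c("type", "subtype", "pubmed_id"),
  dgv_curated = c("stringency", "frequency"),
  kg_cnv = c("type"),
  omim = c("disease", "pubmed_id"),
  decipher_ddd = c("gene_name"),
  clinvar = c("disease", "hgvs")
)

#' Load an annotation source track
#'
#' All tracks are tab-delimited with header `chrom`, `start`, `end`
#' (1-based closed) followed by the track-specific payload columns:
#' \describe{
#'   \item{gencode}{gene_name, gene_type, gene_id, transcript_id, feature
#'     (gene | exon | UTR5 | UTR3)}
#'   \item{phastcon}{score}
#'   \item{haploinsufficiency}{gene_name, hi_score}
#'   \item{gene_intolerance}{gene_name, rvis_score}
#'   \item{sanger_cnv / kg_cnv}{type (DEL | DUP)}
#'   \item{dgv}{type, subtype, pubmed_id}
#'   \item{dgv_curated}{stringency (inclusive | stringent), frequency}
#'   \item{omim}{disease, pubmed_id}
#'   \item{decipher_ddd}{gene_name}
#'   \item{clinvar}{disease, hgvs}
#' }
#'
#' @param path track file.
#' @param name one of the track names above.
#' @return object of class `cnv_track` (fields name, data, index).
#' @export
load_track <- function(path, name) {
  name <- match.arg(name, TRACK_NAMES)
  if (!file.exists(path)) stop(sprintf("track file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("chrom", "start", "end", TRACK_SCHEMAS[[name]])
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("track '%s' (%s) missing column(s): %s", name, path,
                 paste(miss, collapse = ", ")))
  if (nrow(df) > 0L) {
    df$chrom <- normalize_chrom(df$chrom)
    df$start <- suppressWarnings(as.integer(df$start))
    df$end <- suppressWarnings(as.integer(df$end))
    bad <- is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start
    if (any(bad))
      stop(sprintf("track '%s': malformed interval(s) at data row(s) %s",
                   name, paste(utils::head(which(bad), 5L), collapse = ", ")))
    for (col in intersect(c("score", "hi_score", "rvis_score", "frequency"),
                          names(df)))
      df[[col]] <- as.numeric(df[[col]])
  } else {
    df$start <- integer(0); df$end <- integer(0)
  }
  structure(list(name = name, data = df, index = build_index(df)),
            class = "cnv_track")
}

#' @export
print.cnv_track <- function(x, ...) {
  cat(sprintf("cnv_track '%s': %d record(s)\n", x$name, nrow(x$data)))
  invisible(x)
}

join_vals <- function(x, collapse = ",") {
  x <- unique(x[!is.na(x) & nzchar(as.character(x))])
  if (length(x) == 0L) NA_character_ else paste(x, collapse = collapse)
}

# overlap rows of one track for each call; returns list of data.frames
track_hits <- function(calls, track) {
  hits <- vector("list", nrow(calls))
  empty <- track$data[0, , drop = FALSE]
  for (i in seq_len(nrow(calls))) hits[[i]] <- empty
  if (is.null(track) || nrow(track$data) == 0L) return(hits)
  pairs <- overlap_pairs(calls, track$data)
  if (nrow(pairs) == 0L) return(hits)
  by_q <- split(pairs$subject, pairs$query)
  for (qi in names(by_q))
    hits[[as.integer(qi)]] <- track$data[by_q[[qi]], , drop = FALSE]
  hits
}

#' Annotate screened CNVs from a set of source tracks
#'
#' Every annotation field is computed from >= 1 bp overlaps with the track
#' records, except `exon_count_internal`, which counts exons *fully
#' contained* within the CNV (a deletion of exons 3–8 with intact flanking
#' exons 2 and 9 has 6 internal exons). Gene-keyed scores
#' (haploinsufficiency, genic intolerance) are joined by gene name from
#' the gene overlap set, so they are only reported for genes listed in
#' `genes`. Typed known-CNV catalogs are matched type-aware (1000 Genomes
#' deletions vs duplications reported separately; Sanger counts same-type
#' records); the raw DGV count is type-blind. Missing tracks leave their
#' fields empty/zero; coordinates, scores, cnvq and db_count are never
#' modified.
#'
#' @param screened screened call data.frame ([screen_calls()]).
#' @param tracks named list of `cnv_track` objects (any subset of the
#'   track names).
#' @return the input with annotation columns appended (list-valued fields
#'   comma-joined; missing values "NA").
#' @export
annotate_calls <- function(screened, tracks = list()) {
  stopifnot(is.list(tracks))
  if (length(tracks)) {
    nm <- vapply(tracks, function(t) t$name, "")
    names(tracks) <- nm
    bad <- setdiff(nm, TRACK_NAMES)
    if (length(bad)) stop(sprintf("unknown track(s): %s", paste(bad, collapse = ", ")))
  }
  out <- as.data.frame(screened, stringsAsFactors = FALSE)
  n <- nrow(out)
  if (n > 0L) out$chrom <- normalize_chrom(out$chrom)

  chr <- function(def = NA_character_) rep(def, n)
  gene_names <- chr(); gene_types <- chr(); gene_ids <- chr(); tx_ids <- chr()
  exon_int <- integer(n); utr5 <- logical(n); utr3 <- logical(n)
  pc_count <- integer(n); pc_max <- rep(NA_real_, n); pc_scores <- chr()
  hi_scores <- chr(); rvis_scores <- chr()
  sanger_count <- integer(n)
  dgv_count <- integer(n); dgv_types <- chr()
  dgvc_incl <- logical(n); dgvc_str <- logical(n); dgvc_freq <- chr()
  kg_del <- integer(n); kg_dup <- integer(n)
  omim <- chr(); ddd <- chr(); clinvar <- chr()

  gene_lists <- vector("list", n)

  if (n > 0L && !is.null(tracks$gencode)) {
    hits <- track_hits(out, tracks$gencode)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      g <- h[h$feature == "gene", , drop = FALSE]
      gene_lists[[i]] <- unique(g$gene_name)
      gene_names[i] <- join_vals(g$gene_name)
      gene_types[i] <- join_vals(g$gene_type)
      gene_ids[i] <- join_vals(g$gene_id)
      tx_ids[i] <- join_vals(h$transcript_id)
      ex <- h[h$feature == "exon", , drop = FALSE]
      exon_int[i] <- sum(ex$start >= out$start[i] & ex$end <= out$end[i])
      utr5[i] <- any(h$feature == "UTR5")
      utr3[i] <- any(h$feature == "UTR3")
    }
  }
  if (n > 0L && !is.null(tracks$phastcon)) {
    hits <- track_hits(out, tracks$phastcon)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      pc_count[i] <- nrow(h)
      if (nrow(h)) {
        pc_max[i] <- max(h$score)
        pc_scores[i] <- paste(h$score, collapse = ",")
      }
    }
  }
  # gene-keyed scores: joined by gene symbol, restricted to overlapped genes
  if (n > 0L && !is.null(tracks$haploinsufficiency)) {
    tab <- tracks$haploinsufficiency$data
    lut <- tab$hi_score[!duplicated(tab$gene_name)]
    names(lut) <- tab$gene_name[!duplicated(tab$gene_name)]
    for (i in seq_len(n)) {
      g <- intersect(gene_lists[[i]], names(lut))
      if (length(g))
        hi_scores[i] <- paste(sprintf("%s:%s", g, lut[g]), collapse = ",")
    }
  }
  if (n > 0L && !is.null(tracks$gene_intolerance)) {
    tab <- tracks$gene_intolerance$data
    lut <- tab$rvis_score[!duplicated(tab$gene_name)]
    names(lut) <- tab$gene_name[!duplicated(tab$gene_name)]
    for (i in seq_len(n)) {
      g <- intersect(gene_lists[[i]], names(lut))
      if (length(g))
        rvis_scores[i] <- paste(sprintf("%s:%s", g, lut[g]), collapse = ",")
    }
  }
  if (n > 0L && !is.null(tracks$sanger_cnv)) {
    hits <- track_hits(out, tracks$sanger_cnv)
    for (i in seq_len(n))
      sanger_count[i] <- sum(hits[[i]]$type == out$cnv_type[i])
  }
  if (n > 0L && !is.null(tracks$dgv)) {
    hits <- track_hits(out, tracks$dgv)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      dgv_count[i] <- nrow(h)
      if (nrow(h))
        dgv_types[i] <- paste(sprintf("%s:%s:%s", h$type, h$subtype,
                                      h$pubmed_id), collapse = ";")
    }
  }
  if (n > 0L && !is.null(tracks$dgv_curated)) {
    hits <- track_hits(out, tracks$dgv_curated)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      dgvc_incl[i] <- any(h$stringency == "inclusive")
      dgvc_str[i] <- any(h$stringency == "stringent")
      if (nrow(h)) dgvc_freq[i] <- paste(h$frequency, collapse = ",")
    }
  }
  if (n > 0L && !is.null(tracks$kg_cnv)) {
    hits <- track_hits(out, tracks$kg_cnv)
    for (i in seq_len(n)) {
      kg_del[i] <- sum(hits[[i]]$type == "DEL")
      kg_dup[i] <- sum(hits[[i]]$type == "DUP")
    }
  }
  if (n > 0L && !is.null(tracks$omim)) {
    hits <- track_hits(out, tracks$omim)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      if (nrow(h))
        omim[i] <- paste(sprintf("%s:%s", h$disease, h$pubmed_id),
                         collapse = ";")
    }
  }
  if (n > 0L && !is.null(tracks$decipher_ddd)) {
    hits <- track_hits(out, tracks$decipher_ddd)
    for (i in seq_len(n)) ddd[i] <- join_vals(hits[[i]]$gene_name)
  }
  if (n > 0L && !is.null(tracks$clinvar)) {
    hits <- track_hits(out, tracks$clinvar)
    for (i in seq_len(n)) {
      h <- hits[[i]]
      if (nrow(h))
        clinvar[i] <- paste(sprintf("%s:%s", h$disease, h$hgvs),
                            collapse = ";")
    }
  }

  out$genes <- gene_names
  out$gene_types <- gene_types
  out$gene_ids <- gene_ids
  out$transcript_ids <- tx_ids
  out$exon_count_internal <- exon_int
  out$utr5_overlap <- utr5
  out$utr3_overlap <- utr3
  out$phastcon_count <- pc_count
  out$phastcon_max_score <- pc_max
  out$phastcon_scores <- pc_scores
  out$hi_scores <- hi_scores
  out$intolerance_scores <- rvis_scores
  out$sanger_count <- sanger_count
  out$dgv_count <- dgv_count
  out$dgv_types <- dgv_types
  out$dgv_curated_inclusive <- dgvc_incl
  out$dgv_curated_stringent <- dgvc_str
  out$dgv_curated_freq <- dgvc_freq
  out$kg_del_count <- kg_del
  out$kg_dup_count <- kg_dup
  out$omim <- omim
  out$ddd_genes <- ddd
  out$clinvar <- clinvar
  out
}

#' Is a CNV already reported in the public CNV catalogs?
#'
#' "Known" (common, non-disease-causing) status is driven by the healthy-
#' population catalogs only: Sanger high-resolution CNVs, type-matched
#' 1000 Genomes CNVs, and the curated high-quality DGV maps. The raw DGV
#' count does NOT make a CNV known — only the curated subset does.
#'
#' @param annotated annotated call data.frame ([annotate_calls()]).
#' @param stringent_only only the stringent curated-DGV map confers known
#'   status (default FALSE: either stringency level counts).
#' @return logical vector, one element per call.
#' @export
is_known_cnv <- function(annotated, stringent_only = FALSE) {
  kg <- ifelse(annotated$cnv_type == "DEL",
               annotated$kg_del_count, annotated$kg_dup_count)
  dgvc <- if (stringent_only) annotated$dgv_curated_stringent
          else annotated$dgv_curated_inclusive | annotated$dgv_curated_stringent
  annotated$sanger_count > 0 | kg > 0 | dgvc
}
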