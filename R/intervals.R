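#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb Seqinfo
NULL

# Coordinate convention used throughout: 1-based, fully closed intervals
# (the native convention of the exome CNV callers). BED input (0-based,
# half-open) is converted at the parser boundary, never downstream.

#' Normalise chromosome names to the "chr"-prefixed dialect
#'
#' Both naming dialects ("1"/"chr1", "X"/"chrX") are accepted on input;
#' internally everything is "chr"-prefixed.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector, "chr"-prefixed.
#' @export
#' @examples
#' normalize_chrom(c("1", "chrX", "MT"))
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  bare <- !grepl("^chr", chrom)
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' Is a chromosome a sex chromosome?
#'
#' Mixed-sex reference collections bias read-depth CNV prediction on X and
#' Y, so screening and benchmarking support dropping those calls. True for
#' X and Y under either naming dialect.
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
#' @examples
#' is_sex_chromosome(c("chrX", "Y", "chr2"))
is_sex_chromosome <- function(chrom) {
  normalize_chrom(chrom) %in% c("chrX", "chrY")
}

#' Construct a validated genomic interval
#'
#' @param chrom chromosome name (either dialect; stored "chr"-prefixed).
#' @param start 1-based inclusive start (>= 1).
#' @param end 1-based inclusive end (>= start).
#' @return a list of class `genomic_interval` with fields chrom/start/end.
#' @export
#' @examples
#' genomic_interval("1", 100, 200)
genomic_interval <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  if (length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop("chrom must be a single non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || is.na(start) || start < 1 || start != trunc(start))
    stop("start must be a positive integer (1-based)")
  if (length(end) != 1L || is.na(end) || end < start || end != trunc(end))
    stop("end must be an integer >= start")
  structure(list(chrom = normalize_chrom(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d\n", x$chrom, as.integer(x$start), as.integer(x$end)))
  invisible(x)
}

as_interval <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(genomic_interval(x$chrom, x$start, x$end))
  }
  if (is.list(x)) return(genomic_interval(x$chrom, x$start, x$end))
  stop("cannot interpret object as a genomic interval")
}

#' Do two intervals share at least one base?
#'
#' Annotation and database matching use a minimum-overlap rule of a single
#' shared base: in closed coordinates, `max(starts) <= min(ends)` on the
#' same chromosome. Adjacent intervals (end + 1 == start) do not overlap.
#'
#' @param a,b intervals (`genomic_interval`, one-row data.frame with
#'   chrom/start/end, or a plain list with those fields).
#' @return TRUE iff the intervals share >= 1 bp. Symmetric.
#' @export
#' @examples
#' overlaps(genomic_interval("chr1", 100, 200), genomic_interval("chr1", 200, 300))
overlaps <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  a$chrom == b$chrom && max(a$start, b$start) <= min(a$end, b$end)
}

intervals_to_granges <- function(df, levels = NULL) {
  chrom <- normalize_chrom(df$chrom)
  if (is.null(levels)) levels <- unique(chrom)
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(levels)))
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = levels),
    ranges   = IRanges::IRanges(start = as.integer(df$start),
                                end   = as.integer(df$end))
  )
}

validate_interval_frame <- function(df, what = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  start <- as.numeric(df$start); end <- as.numeric(df$end)
  bad <- is.na(start) | is.na(end) | start < 1 | end < start |
    is.na(df$chrom) | !nzchar(as.character(df$chrom))
  if (any(bad))
    stop(sprintf("%s: %d invalid interval row(s) (first at row %d)",
                 what, sum(bad), which(bad)[1L]))
  invisible(df)
}

#' Build a queryable interval index over payload-bearing intervals
#'
#' Wraps the rows of `df` (which must carry chrom/start/end plus any payload
#' columns) in an overlap index so that point and range queries cost far
#' less than a full scan of the track.
#'
#' @param df data.frame with columns chrom, start, end plus payload columns.
#' @return an object of class `interval_index`.
#' @seealso [query_index()]
#' @export
build_index <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    validate_interval_frame(df, "index input")
    df$chrom <- normalize_chrom(df$chrom)
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  structure(list(gr = intervals_to_granges(df), data = df),
            class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("interval_index of %d record(s) on %d chromosome(s)\n",
              nrow(x$data),
              length(unique(x$data$chrom))))
  invisible(x)
}

#' Query an interval index
#'
#' Returns the payload rows whose interval shares >= 1 bp with the query.
#'
#' @param index an [build_index()] object.
#' @param chrom,start,end the query interval (1-based closed), or pass a
#'   one-row data.frame / `genomic_interval` as `chrom` and leave the rest
#'   missing.
#' @return the matching rows of the indexed data.frame (possibly 0 rows),
#'   in track order.
#' @export
query_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "interval_index"))
  if (missing(start)) {
    q <- as_interval(chrom)
    chrom <- q$chrom; start <- q$start; end <- q$end
  }
  if (nrow(index$data) == 0L) return(index$data)
  q <- genomic_interval(chrom, start, end)
  if (!q$chrom %in% index$data$chrom)
    return(index$data[0, , drop = FALSE])
  qgr <- GenomicRanges::GRanges(
    factor(q$chrom, levels = unique(index$data$chrom)),
    IRanges::IRanges(q$start, q$end))
  hits <- GenomicRanges::findOverlaps(qgr, index$gr)
  index$data[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# Vectorised overlap join used by the screening/annotation internals.
# Returns a data.frame with columns query (row in qdf) and subject (row in
# sdf) for every >= 1 bp overlap pair.
overlap_pairs <- function(qdf, sdf) {
  if (nrow(qdf) == 0L || nrow(sdf) == 0L)
    return(data.frame(query = integer(0), subject = integer(0)))
  lv <- unique(normalize_chrom(c(qdf$chrom, sdf$chrom)))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(qdf, lv),
                                      intervals_to_granges(sdf, lv))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# round-half-up, for reporting percentages; base round() is half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
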