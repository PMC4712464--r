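# Variant- and gene-based filtration of annotated CNVs down to rare,
# high-quality candidates. Threshold semantics are strict ">": the
# published stringency presets are "quality score > 10, CNVQ > 10" (low)
# and "> 40, > 40" (high), both also requiring absence from the public
# CNV catalogs.

#' Build a filtration configuration
#'
#' @param min_score keep calls with program quality score strictly greater
#'   than this (default -Inf: no score filter).
#' @param min_cnvq keep calls with CNVQ strictly greater than this. A call
#'   absent from the reference collection has no CNVQ (db_count 0); such
#'   calls PASS this rule by default — they are the rarest calls and must
#'   not be discarded for lack of a score. Set `strict_cnvq = TRUE` to
#'   fail them instead.
#' @param exclude_known drop calls reported in the public catalogs
#'   ([is_known_cnv()]).
#' @param max_db_count when set, keep only calls seen in fewer than this
#'   many reference samples (`db_count < max_db_count`). Disabled in both
#'   presets — recurrence can reflect a disease variant shared across
#'   samples — but useful as an extra artifact filter (5 is the
#'   conventional cut).
#' @param candidate_genes optional character vector of gene symbols; keep
#'   only calls overlapping at least one of them.
#' @param strict_cnvq fail-closed on missing CNVQ (see `min_cnvq`).
#' @param stringent_only pass-through to [is_known_cnv()].
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_score = -Inf, min_cnvq = -Inf,
                          exclude_known = FALSE, max_db_count = NULL,
                          candidate_genes = NULL, strict_cnvq = FALSE,
                          stringent_only = FALSE) {
  if (is.na(min_score) || is.nan(min_cnvq))
    stop("thresholds must be numbers (use -Inf to disable)")
  if (!is.null(max_db_count)) {
    max_db_count <- as.integer(max_db_count)
    if (is.na(max_db_count) || max_db_count < 1L)
      stop("max_db_count must be >= 1 when set")
  }
  structure(list(min_score = as.numeric(min_score),
                 min_cnvq = as.numeric(min_cnvq),
                 exclude_known = isTRUE(exclude_known),
                 max_db_count = max_db_count,
                 candidate_genes = candidate_genes,
                 strict_cnvq = isTRUE(strict_cnvq),
                 stringent_only = isTRUE(stringent_only)),
            class = "filter_config")
}

#' Published stringency presets
#'
#' `low`: quality score > 10 and CNVQ > 10; `high`: > 40 and > 40. Both
#' exclude catalog-known CNVs and leave the database-count filter off.
#'
#' @param name "low" or "high".
#' @return a [filter_config()].
#' @export
#' @examples
#' preset("high")
preset <- function(name) {
  switch(as.character(name),
    low = filter_config(min_score = 10, min_cnvq = 10, exclude_known = TRUE),
    high = filter_config(min_score = 40, min_cnvq = 40, exclude_known = TRUE),
    stop(sprintf("unknown preset '%s' (use \"low\" or \"high\")", name))
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "filter_config: score > %s, CNVQ > %s%s, exclude_known=%s, max_db_count=%s, genes=%s\n",
    x$min_score, x$min_cnvq, if (x$strict_cnvq) " (strict)" else "",
    x$exclude_known,
    if (is.null(x$max_db_count)) "off" else x$max_db_count,
    if (is.null(x$candidate_genes)) "off"
    else sprintf("%d symbol(s)", length(x$candidate_genes))))
  invisible(x)
}

#' Filter annotated CNVs
#'
#' A call is kept iff it passes every enabled rule; each removed call is
#' logged once with the FIRST rule it fails, rules tested in the order
#' known -> score -> cnvq -> db_count -> genes (most interpretable first).
#'
#' @param annotated annotated call data.frame ([annotate_calls()]).
#' @param cfg a [filter_config()] or preset name ("low"/"high").
#' @return list with `kept` (data.frame) and `removed` (data.frame with a
#'   `removal_reason` column). `nrow(kept) + nrow(removed) == nrow(input)`.
#' @export
filter_variants <- function(annotated, cfg = filter_config()) {
  if (is.character(cfg)) cfg <- preset(cfg)
  stopifnot(inherits(cfg, "filter_config"))
  df <- as.data.frame(annotated, stringsAsFactors = FALSE)
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  if (n > 0L) {
    if (cfg$exclude_known) {
      known <- is_known_cnv(df, stringent_only = cfg$stringent_only)
      reason[is.na(reason) & known] <- "known"
    }
    fail_score <- !(df$score > cfg$min_score)
    reason[is.na(reason) & fail_score] <- "score"
    if (cfg$strict_cnvq) {
      fail_cnvq <- is.na(df$cnvq) | !(df$cnvq > cfg$min_cnvq)
    } else {
      fail_cnvq <- !is.na(df$cnvq) & !(df$cnvq > cfg$min_cnvq)
    }
    reason[is.na(reason) & fail_cnvq] <- "cnvq"
    if (!is.null(cfg$max_db_count)) {
      fail_db <- !(df$db_count < cfg$max_db_count)
      reason[is.na(reason) & fail_db] <- "db_count"
    }
    if (!is.null(cfg$candidate_genes)) {
      gl <- strsplit(ifelse(is.na(df$genes), "", df$genes), ",", fixed = TRUE)
      hit <- vapply(gl, function(g) any(g %in% cfg$candidate_genes), TRUE)
      reason[is.na(reason) & !hit] <- "genes"
    }
  }
  kept <- df[is.na(reason), , drop = FALSE]
  removed <- df[!is.na(reason), , drop = FALSE]
  removed$removal_reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL; rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Filtration accounting
#'
#' Percentage of calls removed and retained, rounded half-up to 2
#' decimals (e.g. flagging 1004 of 1742 calls removes 57.63 %).
#'
#' @param input_n number of calls before filtering (>= 1).
#' @param kept_n number kept (0 <= kept_n <= input_n).
#' @return list(input_n, kept_n, removed_n, removed_pct, retained_pct).
#' @export
#' @examples
#' summarize_filtration(1742, 738)$removed_pct
summarize_filtration <- function(input_n, kept_n) {
  input_n <- as.numeric(input_n); kept_n <- as.numeric(kept_n)
  if (is.na(input_n) || input_n < 1) stop("input_n must be >= 1")
  if (is.na(kept_n) || kept_n < 0 || kept_n > input_n)
    stop("kept_n must satisfy 0 <= kept_n <= input_n")
  list(input_n = input_n, kept_n = kept_n, removed_n = input_n - kept_n,
       removed_pct = round_half_up(100 * (input_n - kept_n) / input_n, 2),
       retained_pct = round_half_up(100 * kept_n / input_n, 2))
}
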