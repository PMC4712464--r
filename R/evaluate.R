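# Benchmarking of predicted CNVs against an orthogonal array-CGH truth
# set. A prediction confirmed by a same-type array call is a TP; an
# unconfirmed prediction counts as FP only when the array design could
# have seen it (>= 4 probes inside the predicted interval); anything else
# is INDETERMINATE and excluded from the curves.

#' Bundle array calls and probe positions into a truth set
#'
#' @param array_calls data.frame with chrom, start, end, cnv_type
#'   (array-derived CNV intervals).
#' @param probes data.frame with chrom, pos (1-based probe positions of
#'   the array design).
#' @return object of class `cnv_truth`.
#' @export
truth_set <- function(array_calls, probes) {
  array_calls <- as.data.frame(array_calls, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (nrow(array_calls)) {
    validate_interval_frame(array_calls, "array calls")
    if (!"cnv_type" %in% names(array_calls))
      stop("array calls need a cnv_type column")
    array_calls$chrom <- normalize_chrom(array_calls$chrom)
  }
  if (!all(c("chrom", "pos") %in% names(probes)))
    stop("probes need chrom and pos columns")
  if (nrow(probes)) {
    probes$chrom <- normalize_chrom(probes$chrom)
    probes$pos <- as.integer(probes$pos)
    if (any(is.na(probes$pos) | probes$pos < 1))
      stop("probe positions must be positive integers (1-based)")
  }
  structure(list(array_calls = array_calls, probes = probes),
            class = "cnv_truth")
}

#' @export
print.cnv_truth <- function(x, ...) {
  cat(sprintf("cnv_truth: %d array call(s), %d probe(s)\n",
              nrow(x$array_calls), nrow(x$probes)))
  invisible(x)
}

#' Label predictions as TP / FP / INDETERMINATE against the truth set
#'
#' TP: >= 1 bp overlap with an array call (same type unless
#' `type_aware = FALSE`). Otherwise FP when the predicted interval
#' contains >= `min_probes` probe positions (the array had power to see
#' it); otherwise INDETERMINATE. X/Y calls are dropped first when
#' `exclude_xy` (sex-chromosome prediction is biased by mixed-sex
#' reference collections).
#'
#' @param screened screened call data.frame (needs cnvq/db_count only for
#'   the downstream CNVQ tables).
#' @param truth a [truth_set()].
#' @param exclude_xy drop X/Y calls before labeling.
#' @param type_aware an array duplication does not validate a predicted
#'   deletion (default TRUE).
#' @param min_probes probe support required to call an unconfirmed
#'   prediction FP (default 4).
#' @return the input rows (minus X/Y when excluded) with a `label` column.
#' @export
label_calls <- function(screened, truth, exclude_xy = FALSE,
                        type_aware = TRUE, min_probes = 4L) {
  stopifnot(inherits(truth, "cnv_truth"))
  df <- as.data.frame(screened, stringsAsFactors = FALSE)
  if (nrow(df)) df$chrom <- normalize_chrom(df$chrom)
  if (exclude_xy && nrow(df))
    df <- df[!is_sex_chromosome(df$chrom), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  if (n == 0L) { df$label <- character(0); return(df) }

  tp <- logical(n)
  pairs <- overlap_pairs(df, truth$array_calls)
  if (nrow(pairs)) {
    if (type_aware)
      pairs <- pairs[df$cnv_type[pairs$query] ==
                       truth$array_calls$cnv_type[pairs$subject], , drop = FALSE]
    tp[unique(pairs$query)] <- TRUE
  }

  probe_n <- integer(n)
  if (nrow(truth$probes)) {
    pdf <- data.frame(chrom = truth$probes$chrom,
                      start = truth$probes$pos, end = truth$probes$pos)
    pp <- overlap_pairs(df, pdf)
    if (nrow(pp)) {
      tab <- table(pp$query)
      probe_n[as.integer(names(tab))] <- as.integer(tab)
    }
  }

  df$label <- ifelse(tp, "TP",
              ifelse(probe_n >= min_probes, "FP", "INDETERMINATE"))
  df
}

#' Cumulative TP/FP counts and FDR across quality-score thresholds
#'
#' Scores of TP and FP calls are swept from highest to lowest; at each
#' distinct score q the row reports cTP/cFP (calls scoring >= q), the
#' false discovery rate FDR = cFP / (cTP + cFP) and the FP/TP ratio
#' cFP / cTP (Inf while no TP has been reached). INDETERMINATE calls are
#' excluded.
#'
#' @param labeled output of [label_calls()].
#' @return data.frame(score, cTP, cFP, FDR, fp_tp_ratio), scores strictly
#'   decreasing.
#' @export
cumulative_curve <- function(labeled) {
  lab <- labeled[labeled$label %in% c("TP", "FP"), , drop = FALSE]
  if (nrow(lab) == 0L) stop("no TP or FP calls to build a curve from")
  qs <- sort(unique(lab$score), decreasing = TRUE)
  cTP <- vapply(qs, function(q) sum(lab$score >= q & lab$label == "TP"), 0)
  cFP <- vapply(qs, function(q) sum(lab$score >= q & lab$label == "FP"), 0)
  data.frame(score = qs, cTP = as.integer(cTP), cFP = as.integer(cFP),
             FDR = cFP / (cTP + cFP),
             fp_tp_ratio = ifelse(cTP > 0, cFP / cTP, Inf))
}

#' CNVQ-ratio table by database CNV count
#'
#' Recurrent technical artifacts score low in the reference collection,
#' so within a database-count stratum the TP calls should out-score the
#' FP calls: the CNVQ ratio (median CNVQ of TPs / median CNVQ of FPs)
#' stays above 1 at low database counts. Calls without a CNVQ
#' (db_count 0) cannot be stratified and are skipped; strata missing
#' either class report no ratio.
#'
#' @param labeled output of [label_calls()] carrying cnvq/db_count.
#' @param max_db_count when set, restrict to `db_count < max_db_count`
#'   (the conventional view uses counts below 5, where quality scores
#'   separate the classes best).
#' @return data.frame(db_count, n_tp, n_fp, median_cnvq_tp,
#'   median_cnvq_fp, cnvq_ratio).
#' @export
cnvq_ratio_table <- function(labeled, max_db_count = NULL) {
  lab <- labeled[labeled$label %in% c("TP", "FP") & !is.na(labeled$cnvq) &
                   labeled$db_count >= 1L, , drop = FALSE]
  if (!is.null(max_db_count))
    lab <- lab[lab$db_count < max_db_count, , drop = FALSE]
  counts <- sort(unique(lab$db_count))
  rows <- lapply(counts, function(k) {
    g <- lab[lab$db_count == k, , drop = FALSE]
    tp <- g$cnvq[g$label == "TP"]; fp <- g$cnvq[g$label == "FP"]
    mtp <- if (length(tp)) stats::median(tp) else NA_real_
    mfp <- if (length(fp)) stats::median(fp) else NA_real_
    data.frame(db_count = k, n_tp = length(tp), n_fp = length(fp),
               median_cnvq_tp = mtp, median_cnvq_fp = mfp,
               cnvq_ratio = if (length(tp) && length(fp)) mtp / mfp
                            else NA_real_)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(db_count = integer(0), n_tp = integer(0),
                  n_fp = integer(0), median_cnvq_tp = numeric(0),
                  median_cnvq_fp = numeric(0), cnvq_ratio = numeric(0))
}

#' Sweep joint score/CNVQ filtration thresholds over labeled calls
#'
#' For each threshold t, keeps calls with quality score > t AND
#' CNVQ > t (missing CNVQ passes, matching the filtration policy) and
#' reports surviving class counts, the FP/TP ratio and the FDR.
#'
#' @param labeled output of [label_calls()].
#' @param thresholds numeric vector, sorted ascending (e.g. 10:40).
#' @return data.frame(threshold, TP_kept, FP_kept, fp_tp_ratio, FDR).
#' @export
filtration_sweep <- function(labeled, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  lab <- labeled[labeled$label %in% c("TP", "FP"), , drop = FALSE]
  rows <- lapply(thresholds, function(t) {
    keep <- lab$score > t & (is.na(lab$cnvq) | lab$cnvq > t)
    tp <- sum(keep & lab$label == "TP"); fp <- sum(keep & lab$label == "FP")
    data.frame(threshold = t, TP_kept = tp, FP_kept = fp,
               fp_tp_ratio = if (tp > 0) fp / tp else Inf,
               FDR = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Convenience wrapper: labels calls, then derives the cumulative curve,
#' the CNVQ-ratio table and a threshold sweep.
#'
#' @inheritParams label_calls
#' @param thresholds thresholds for [filtration_sweep()].
#' @param max_db_count stratification cap for [cnvq_ratio_table()].
#' @return object of class `cnv_eval` with fields labeled, curve,
#'   cnvq_ratio, sweep, n_indeterminate.
#' @export
evaluate_calls <- function(screened, truth, exclude_xy = FALSE,
                           type_aware = TRUE, min_probes = 4L,
                           thresholds = 10:40, max_db_count = 5L) {
  labeled <- label_calls(screened, truth, exclude_xy = exclude_xy,
                         type_aware = type_aware, min_probes = min_probes)
  structure(list(
    labeled = labeled,
    curve = cumulative_curve(labeled),
    cnvq_ratio = cnvq_ratio_table(labeled, max_db_count = max_db_count),
    sweep = filtration_sweep(labeled, thresholds),
    n_indeterminate = sum(labeled$label == "INDETERMINATE")
  ), class = "cnv_eval")
}

#' @export
print.cnv_eval <- function(x, ...) {
  nt <- sum(x$labeled$label == "TP"); nf <- sum(x$labeled$label == "FP")
  cat(sprintf("CNV evaluation: %d TP, %d FP, %d indeterminate (excluded from curves)\n",
              nt, nf, x$n_indeterminate))
  cat(sprintf("  overall FDR %.3f; curve over %d score threshold(s)\n",
              nf / max(nt + nf, 1L), nrow(x$curve)))
  invisible(x)
}

#' Diagnostic panels for an evaluation report
#'
#' Base-graphics panels: cumulative TP/FP counts vs score, FDR vs score,
#' and CNVQ ratio vs database CNV count.
#'
#' @param x a `cnv_eval` object.
#' @param ... ignored.
#' @return invisibly, x.
#' @method plot cnv_eval
#' @export
plot.cnv_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cv <- x$curve
  graphics::plot(cv$score, cv$cTP, type = "s", col = "forestgreen",
                 xlab = "quality score threshold", ylab = "cumulative count",
                 main = "cTP / cFP", ylim = range(c(cv$cTP, cv$cFP)))
  graphics::lines(cv$score, cv$cFP, type = "s", col = "firebrick")
  graphics::legend("topright", legend = c("cTP", "cFP"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  graphics::plot(cv$score, cv$FDR, type = "s", xlab = "quality score threshold",
                 ylab = "FDR", main = "FDR", ylim = c(0, 1))
  rt <- x$cnvq_ratio[!is.na(x$cnvq_ratio$cnvq_ratio), , drop = FALSE]
  if (nrow(rt)) {
    graphics::plot(rt$db_count, rt$cnvq_ratio, type = "b",
                   xlab = "database CNV count", ylab = "CNVQ ratio (TP/FP)",
                   main = "CNVQ ratio")
    graphics::abline(h = 1, lty = 2)
  } else {
    graphics::plot.new(); graphics::title("CNVQ ratio (no strata)")
  }
  invisible(x)
}
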