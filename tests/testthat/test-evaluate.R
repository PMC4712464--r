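simple_truth <- function() {
  truth_set(
    data.frame(chrom = "chr1", start = 1000L, end = 2000L, cnv_type = "DEL"),
    data.frame(chrom = "chr1", pos = seq(5000L, 6000L, by = 200L)))  # 6 probes
}

test_that("labels follow the array-confirmation and probe-support rules", {
  truth <- simple_truth()
  tp <- label_calls(make_call(start = 1500, end = 2500, cnv_type = "DEL"),
                    truth)
  expect_identical(tp$label, "TP")
  # no array overlap but 6 probes inside -> FP
  fp <- label_calls(make_call(start = 4900, end = 6100, cnv_type = "DEL"),
                    truth)
  expect_identical(fp$label, "FP")
  # no array overlap, only 3 probes -> indeterminate
  ind <- label_calls(make_call(start = 4900, end = 5450, cnv_type = "DEL"),
                     truth)
  expect_identical(ind$label, "INDETERMINATE")
  # an array DEL does not validate a predicted DUP...
  dup <- label_calls(make_call(start = 1500, end = 2500, cnv_type = "DUP"),
                     truth)
  expect_identical(dup$label, "INDETERMINATE")
  # ...unless matching is type-blind
  dup2 <- label_calls(make_call(start = 1500, end = 2500, cnv_type = "DUP"),
                      truth, type_aware = FALSE)
  expect_identical(dup2$label, "TP")
  # X/Y exclusion happens before labeling
  xy <- rbind(make_call(start = 1500, end = 2500, cnv_type = "DEL"),
              make_call(chrom = "chrX", start = 1500, end = 2500))
  expect_identical(nrow(label_calls(xy, truth, exclude_xy = TRUE)), 1L)
})

test_that("cumulative curve sweeps distinct scores from high to low", {
  lab <- rbind(make_call(score = 30), make_call(score = 20),
               make_call(score = 10))
  lab$label <- c("TP", "TP", "FP")
  cv <- cumulative_curve(lab)
  expect_equal(cv$score, c(30, 20, 10))
  expect_identical(cv$cTP, c(1L, 2L, 2L))
  expect_identical(cv$cFP, c(0L, 0L, 1L))
  expect_equal(cv$FDR, c(0, 0, 1 / 3))
  expect_equal(cv$fp_tp_ratio[3], 0.5)
  # all-FP input: FDR is 1 everywhere
  fps <- rbind(make_call(score = 5), make_call(score = 9))
  fps$label <- "FP"
  expect_true(all(cumulative_curve(fps)$FDR == 1))
  expect_true(all(is.infinite(cumulative_curve(fps)$fp_tp_ratio)))
  # ties at a single score: FDR = FP/(TP+FP)
  tie <- do.call(rbind, lapply(1:4, function(i) make_call(score = 7)))
  tie$label <- c("TP", "TP", "TP", "FP")
  expect_equal(cumulative_curve(tie)$FDR, 0.25)
  expect_error(cumulative_curve(lab[0, ]), "no TP or FP")
})

test_that("curve matches the brute-force threshold sweep and reconciles totals", {
  set.seed(413)
  for (rep in 1:10) {
    lab <- rand_calls(sample(10:200, 1))
    lab$label <- sample(c("TP", "FP", "INDETERMINATE"), nrow(lab), TRUE)
    if (!any(lab$label %in% c("TP", "FP"))) lab$label[1] <- "TP"
    got <- cumulative_curve(lab)
    want <- oracle_curve(lab)
    expect_equal(got, want, ignore_attr = TRUE)
    # at the lowest score everything labeled TP/FP is counted
    last <- nrow(got)
    expect_identical(got$cTP[last] + got$cFP[last],
                     sum(lab$label %in% c("TP", "FP")))
    expect_true(all(got$FDR >= 0 & got$FDR <= 1))
    expect_true(all(diff(got$cTP) >= 0) && all(diff(got$cFP) >= 0))
    expect_true(all(diff(got$score) < 0))
  }
})

test_that("CNVQ ratio stratifies by database count with median statistics", {
  lab <- rbind(
    make_call(score = 1, cnvq = 20, db_count = 2L),
    make_call(score = 1, cnvq = 30, db_count = 2L),
    make_call(score = 1, cnvq = 10, db_count = 2L),
    make_call(score = 1, cnvq = 10, db_count = 2L),
    make_call(score = 1, cnvq = 50, db_count = 3L))
  lab$label <- c("TP", "TP", "FP", "FP", "TP")
  rt <- cnvq_ratio_table(lab)
  r2 <- rt[rt$db_count == 2, ]
  expect_equal(r2$median_cnvq_tp, 25)
  expect_equal(r2$median_cnvq_fp, 10)
  expect_equal(r2$cnvq_ratio, 2.5)
  # stratum with TPs only: no ratio
  expect_true(is.na(rt$cnvq_ratio[rt$db_count == 3]))
  # restriction to low database counts
  lab$db_count[5] <- 7L
  expect_identical(cnvq_ratio_table(lab, max_db_count = 5L)$db_count, 2L)
})

test_that("joint score/CNVQ sweep matches a brute-force re-filter", {
  set.seed(414)
  lab <- rand_calls(120)
  lab$cnvq <- ifelse(runif(120) < 0.25, NA_real_, round(runif(120, 0, 80), 2))
  lab$db_count <- ifelse(is.na(lab$cnvq), 0L, sample(1:8, 120, TRUE))
  lab$label <- sample(c("TP", "FP"), 120, TRUE)
  th <- c(0, 10, 25, 40, 200)
  sw <- filtration_sweep(lab, th)
  for (i in seq_along(th)) {
    keep <- lab$score > th[i] & (is.na(lab$cnvq) | lab$cnvq > th[i])
    expect_identical(sw$TP_kept[i], sum(keep & lab$label == "TP"))
    expect_identical(sw$FP_kept[i], sum(keep & lab$label == "FP"))
  }
  expect_identical(sw$TP_kept[1], sum(lab$label == "TP"))  # below all scores
  expect_identical(sw$TP_kept[5] + sw$FP_kept[5], 0L)      # above all scores
  expect_true(all(diff(sw$TP_kept) <= 0) && all(diff(sw$FP_kept) <= 0))
  expect_error(filtration_sweep(lab, c(10, 5)), "ascending")
})

test_that("label_calls agrees with the exhaustive oracle on random data", {
  set.seed(415)
  for (rep in 1:8) {
    calls <- rand_calls(80)
    arr <- rand_intervals(40)
    arr$cnv_type <- sample(c("DEL", "DUP"), 40, TRUE)
    probes <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                         pos = sample.int(50000L, 500, TRUE))
    truth <- truth_set(arr, probes)
    got <- label_calls(calls, truth)$label
    want <- oracle_label(calls, arr, probes)
    expect_identical(got, want)
  }
})

test_that("the evaluation wrapper assembles a coherent report", {
  set.seed(416)
  fx <- generate_fixture(sim_config(seed = 5, n_genes = 80, n_true_cnvs = 16,
                                    n_sporadic_fp = 8, n_artifact_loci = 12),
                         withr::local_tempdir())
  scr <- screen_calls(parse_calls(fx$paths$query), build_fixture_db(fx),
                      exclude_xy = TRUE)
  ev <- evaluate_calls(scr, read_fixture_truth(fx), exclude_xy = TRUE)
  expect_s3_class(ev, "cnv_eval")
  expect_identical(nrow(ev$labeled),
                   sum(ev$labeled$label %in% c("TP", "FP")) +
                     ev$n_indeterminate)
  expect_true(all(ev$curve$FDR >= 0 & ev$curve$FDR <= 1))
  # diagnostics render without error
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path); plot(ev); grDevices::dev.off()
  expect_true(file.exists(png_path))
})
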