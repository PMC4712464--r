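db_from <- function(entries, program = "ExomeDepth") {
  build_db(split(entries, entries$sample_id), program)
}

test_that("database construction counts entries and samples", {
  set.seed(405)
  calls <- rand_calls(6, samples = "ignored")
  calls$sample_id <- rep(c("A", "B", "C"), each = 2)
  db <- db_from(calls)
  expect_identical(nrow(db$entries), 6L)
  expect_identical(db$n_samples, 3L)
  expect_error(build_db(list(), "ExomeDepth"), "empty reference collection")
  # mixed programs are rejected, naming the offender
  bad <- calls; bad$program[3] <- "XHMM"
  expect_error(db_from(bad), "XHMM")
  # non-finite scores rejected at build time
  bad2 <- calls; bad2$score[1] <- Inf
  expect_error(db_from(bad2), "non-finite")
})

test_that("database serialisation round-trips losslessly", {
  set.seed(406)
  calls <- rand_calls(40)
  db <- db_from(calls)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_db(db, p)
  back <- read_db(p)
  expect_identical(back$program, db$program)
  expect_identical(back$n_samples, db$n_samples)
  ord <- function(e) {
    e <- e[order(e$chrom, e$start, e$end, e$sample_id), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(ord(back$entries), ord(db$entries))
})

test_that("CNVQ is the median score over distinct-sample matches", {
  entries <- data.frame(
    chrom = "chr1", start = 1000L, end = 2000L, cnv_type = "DEL",
    score = c(10, 20, 30, 40), sample_id = c("S1", "S2", "S3", "S4"),
    program = "ExomeDepth", stringsAsFactors = FALSE)
  q <- make_call(start = 1500, end = 2500, cnv_type = "DEL",
                 sample_id = "QUERY")
  # odd count: middle value
  r3 <- query_db(db_from(entries[1:3, ]), q)
  expect_identical(r3$db_count, 3L)
  expect_equal(r3$cnvq, 20)
  # even count: mean of the middle two
  r4 <- query_db(db_from(entries), q)
  expect_equal(r4$cnvq, 25)
  # type mismatch yields nothing
  qd <- q; qd$cnv_type <- "DUP"
  r0 <- query_db(db_from(entries), qd)
  expect_identical(r0$db_count, 0L)
  expect_true(is.na(r0$cnvq))
  # unless matching is type-blind
  expect_identical(query_db(db_from(entries), qd, type_blind = TRUE)$db_count, 4L)
  # a single match defines CNVQ as that score (median of one)
  r1 <- query_db(db_from(entries[1, , drop = FALSE]), q)
  expect_identical(r1$db_count, 1L)
  expect_equal(r1$cnvq, 10)
})

test_that("query_db matches the brute-force scan on random databases", {
  set.seed(407)
  for (rep in 1:15) {
    entries <- rand_calls(sample(5:150, 1), samples = paste0("S", 1:8))
    db <- db_from(entries)
    queries <- rand_calls(20, samples = paste0("S", 1:8))
    for (i in seq_len(nrow(queries))) {
      for (excl in c(TRUE, FALSE)) {
        got <- query_db(db, queries[i, ], exclude_sample = excl)
        want <- oracle_query_db(entries, queries[i, ], exclude_sample = excl)
        expect_identical(got$db_count, want$db_count)
        expect_equal(got$cnvq, want$cnvq)
        expect_identical(nrow(got$matches), nrow(want$rows))
      }
      expect_lte(query_db(db, queries[i, ])$db_count, db$n_samples)
    }
  }
})

test_that("a query's own database entries are excluded by default", {
  entries <- data.frame(
    chrom = "chr1", start = 1000L, end = 2000L, cnv_type = "DEL",
    score = c(10, 90), sample_id = c("S1", "S2"), program = "ExomeDepth",
    stringsAsFactors = FALSE)
  db <- db_from(entries)
  q <- make_call(cnv_type = "DEL", sample_id = "S1", score = 10)
  scr <- screen_calls(q, db)
  expect_identical(scr$db_count, 1L)   # only S2 counts
  expect_equal(scr$cnvq, 90)
  scr2 <- screen_calls(q, db, keep_self = TRUE)
  expect_identical(scr2$db_count, 2L)
  expect_equal(scr2$cnvq, 50)
})

test_that("screening preserves order, drops X/Y on request, and rejects cross-program use", {
  entries <- rand_calls(10)
  db <- db_from(entries)
  calls <- rbind(make_call(chrom = "chr2", start = 10, end = 20),
                 make_call(chrom = "chrX", start = 10, end = 20),
                 make_call(chrom = "chr3", start = 10, end = 20))
  calls$cnvq <- NULL; calls$db_count <- NULL
  scr <- screen_calls(calls, db, exclude_xy = TRUE)
  expect_identical(scr$chrom, c("chr2", "chr3"))
  scr_all <- screen_calls(calls, db)
  expect_identical(scr_all$chrom, calls$chrom)
  # no overlaps: db_count 0 and missing CNVQ, in lockstep
  expect_true(all(scr$db_count == 0L))
  expect_true(all(is.na(scr$cnvq)))
  wrong <- calls; wrong$program <- "XHMM"
  expect_error(screen_calls(wrong, db), "not comparable")
})

test_that("screened calls satisfy db_count = 0 <=> missing CNVQ", {
  set.seed(408)
  entries <- rand_calls(120, samples = paste0("S", 1:6))
  db <- db_from(entries)
  queries <- rand_calls(150, samples = c(paste0("S", 1:6), "NEW"))
  scr <- screen_calls(queries, db)
  expect_identical(is.na(scr$cnvq), scr$db_count == 0L)
  expect_true(all(scr$db_count <= db$n_samples))
})

test_that("recurrent low-score artifacts get lower CNVQ than rare high-score CNVs", {
  # reference collection with artifact loci planted in >= 5 samples at low
  # scores and real CNVs in single samples at high scores
  set.seed(409)
  sids <- paste0("R", 1:10)
  rows <- list()
  art_pos <- seq(10000, by = 20000, length.out = 8)
  for (p in art_pos)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = "chr1", start = p, end = p + 5000L, cnv_type = "DEL",
      score = round(runif(6, 2, 15), 2), sample_id = sample(sids, 6),
      program = "ExomeDepth")
  true_pos <- seq(400000, by = 20000, length.out = 8)
  for (p in true_pos)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = "chr1", start = p, end = p + 5000L, cnv_type = "DEL",
      score = round(runif(1, 40, 90), 2), sample_id = sample(sids, 1),
      program = "ExomeDepth")
  db <- db_from(do.call(rbind, rows))
  q_art <- data.frame(chrom = "chr1", start = art_pos, end = art_pos + 5000L,
                      cnv_type = "DEL", score = 10, sample_id = "CASE",
                      program = "ExomeDepth")
  q_true <- data.frame(chrom = "chr1", start = true_pos, end = true_pos + 5000L,
                       cnv_type = "DEL", score = 70, sample_id = "CASE",
                       program = "ExomeDepth")
  s_art <- screen_calls(q_art, db)
  s_true <- screen_calls(q_true, db)
  expect_true(all(s_art$db_count >= 5))
  expect_lt(median(s_art$cnvq), median(s_true$cnvq))
})
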