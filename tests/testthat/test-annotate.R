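# small hand-built gene model: one 9-exon gene, exon k spans
# [k*1000, k*1000 + 100]
gene_track <- function() {
  ex <- data.frame(chrom = "chr1", start = (1:9) * 1000L,
                   end = (1:9) * 1000L + 100L, gene_name = "GENE1",
                   gene_type = "protein_coding", gene_id = "G1",
                   transcript_id = "T1", feature = "exon")
  g <- data.frame(chrom = "chr1", start = 900L, end = 9200L,
                  gene_name = "GENE1", gene_type = "protein_coding",
                  gene_id = "G1", transcript_id = "T1", feature = "gene")
  utr <- data.frame(chrom = "chr1", start = c(900L, 9150L),
                    end = c(999L, 9200L), gene_name = "GENE1",
                    gene_type = "protein_coding", gene_id = "G1",
                    transcript_id = "T1", feature = c("UTR5", "UTR3"))
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_track_file(rbind(g, ex, utr), p)
  load_track(p, "gencode")
}

test_that("internal exon count covers only exons fully inside the CNV", {
  gc <- gene_track()
  # deletion spanning exons 3..8; exons 2 and 9 flank it intact
  cnv <- make_call(start = 2950, end = 8150, cnv_type = "DEL")
  ann <- annotate_calls(cnv, list(gc))
  expect_identical(ann$exon_count_internal, 6L)
  expect_identical(ann$genes, "GENE1")
  expect_false(ann$utr5_overlap)
  expect_false(ann$utr3_overlap)
  # whole-gene deletion: all 9 exons and both UTRs
  whole <- annotate_calls(make_call(start = 800, end = 9500), list(gc))
  expect_identical(whole$exon_count_internal, 9L)
  expect_true(whole$utr5_overlap && whole$utr3_overlap)
  # an exon merely touched is not internal
  part <- annotate_calls(make_call(start = 3050, end = 8150), list(gc))
  expect_identical(part$exon_count_internal, 5L)
})

test_that("a CNV overlapping no track records annotates to zeros and empties", {
  gc <- gene_track()
  ann <- annotate_calls(make_call(chrom = "chr9", start = 1, end = 100),
                        list(gc))
  expect_identical(ann$exon_count_internal, 0L)
  expect_true(is.na(ann$genes))
  expect_identical(ann$phastcon_count, 0L)
  expect_identical(ann$sanger_count, 0L)
  expect_identical(ann$kg_del_count, 0L)
  expect_false(ann$dgv_curated_inclusive)
})

test_that("typed catalogs split by CNV type; known status is type-matched", {
  p <- withr::local_tempfile(fileext = ".tsv")
  kg <- load_track(write_track_file(data.frame(
    chrom = "chr1", start = c(1000L, 1200L), end = c(1800L, 2100L),
    type = c("DEL", "DUP")), p), "kg_cnv")
  del <- annotate_calls(make_call(cnv_type = "DEL"), list(kg))
  expect_identical(del$kg_del_count, 1L)
  expect_identical(del$kg_dup_count, 1L)
  expect_true(is_known_cnv(del))
  # a DUP-only catalog hit does not make a DEL known
  p2 <- withr::local_tempfile(fileext = ".tsv")
  kg_dup <- load_track(write_track_file(data.frame(
    chrom = "chr1", start = 1000L, end = 2000L, type = "DUP"), p2), "kg_cnv")
  del2 <- annotate_calls(make_call(cnv_type = "DEL"), list(kg_dup))
  expect_identical(del2$kg_del_count, 0L)
  expect_false(is_known_cnv(del2))
})

test_that("only the curated DGV maps confer known status, not raw DGV", {
  known_sanger <- make_annotated(sanger_count = 1L)
  expect_true(is_known_cnv(known_sanger))
  raw_dgv_only <- make_annotated()
  raw_dgv_only$dgv_count <- 3L
  expect_false(is_known_cnv(raw_dgv_only))
  expect_false(is_known_cnv(make_annotated()))
  incl <- make_annotated(dgv_curated_inclusive = TRUE)
  expect_true(is_known_cnv(incl))
  expect_false(is_known_cnv(incl, stringent_only = TRUE))
  expect_true(is_known_cnv(make_annotated(dgv_curated_stringent = TRUE),
                           stringent_only = TRUE))
})

test_that("gene-keyed scores are joined by symbol and restricted to overlapped genes", {
  gc <- gene_track()
  p <- withr::local_tempfile(fileext = ".tsv")
  hi <- load_track(write_track_file(data.frame(
    chrom = "chr1", start = c(900L, 50000L), end = c(9200L, 60000L),
    gene_name = c("GENE1", "OTHER"), hi_score = c(0.91, 0.2)), p),
    "haploinsufficiency")
  ann <- annotate_calls(make_call(start = 2950, end = 8150), list(gc, hi))
  expect_identical(ann$hi_scores, "GENE1:0.91")
  # without the gene track the overlap set is empty, so no score reported
  ann2 <- annotate_calls(make_call(start = 2950, end = 8150), list(hi))
  expect_true(is.na(ann2$hi_scores))
})

test_that("tracks are independent and annotation never touches the call fields", {
  set.seed(410)
  fxdir <- withr::local_tempdir()
  fx <- generate_fixture(sim_config(seed = 11, n_genes = 60, n_true_cnvs = 10,
                                    n_sporadic_fp = 8, n_artifact_loci = 12),
                         fxdir)
  scr <- screen_calls(parse_calls(fx$paths$query), build_fixture_db(fx))
  tracks <- load_fixture_tracks(fx)
  full <- annotate_calls(scr, tracks)
  # input fields untouched
  for (col in c("chrom", "start", "end", "cnv_type", "score", "cnvq",
                "db_count"))
    expect_identical(full[[col]], scr[[col]])
  # dropping one track empties only its fields
  no_pc <- annotate_calls(scr, tracks[vapply(tracks, function(t)
    t$name != "phastcon", TRUE)])
  expect_true(all(no_pc$phastcon_count == 0L))
  for (col in c("genes", "exon_count_internal", "sanger_count", "dgv_count",
                "kg_del_count", "kg_dup_count", "omim", "clinvar"))
    expect_identical(no_pc[[col]], full[[col]])
})

test_that("every count field equals the brute-force overlap count on random data", {
  set.seed(411)
  for (rep in 1:5) {
    pc <- rand_intervals(60); pc$score <- sample(100:900, 60, replace = TRUE)
    sg <- rand_intervals(40); sg$type <- sample(c("DEL", "DUP"), 40, TRUE)
    p1 <- withr::local_tempfile(fileext = ".tsv")
    p2 <- withr::local_tempfile(fileext = ".tsv")
    tracks <- list(load_track(write_track_file(pc, p1), "phastcon"),
                   load_track(write_track_file(sg, p2), "sanger_cnv"))
    calls <- rand_calls(40)
    ann <- annotate_calls(calls, tracks)
    for (i in seq_len(nrow(calls))) {
      expect_identical(ann$phastcon_count[i],
                       nrow(oracle_query(pc, calls$chrom[i], calls$start[i],
                                         calls$end[i])))
      sg_hit <- oracle_query(sg, calls$chrom[i], calls$start[i], calls$end[i])
      expect_identical(ann$sanger_count[i],
                       sum(sg_hit$type == calls$cnv_type[i]))
    }
  }
})

test_that("track loading validates names and schemas", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_track_file(data.frame(chrom = "chr1", start = 1L, end = 2L), p)
  expect_error(load_track(p, "nonsense"))
  expect_error(load_track(p, "phastcon"), "score")
  # empty track file is valid and annotates to zero
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_track_file(data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), score = numeric(0)), p2)
  t <- load_track(p2, "phastcon")
  expect_identical(annotate_calls(make_call(), list(t))$phastcon_count, 0L)
})
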