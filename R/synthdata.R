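# Seeded generator for every input the pipeline consumes: a reference
# exome collection with planted recurrent low-score artifact calls and
# rare high-score real CNVs, a query call set, all eleven annotation
# tracks, public-catalog plants, a candidate gene panel, and an array
# truth set with a probe grid.
#
# Statistical structure being emulated: read-depth callers normalised
# against a shared reference collection re-call the same coverage
# artifacts in many samples with LOW quality scores, while real CNVs are
# rare and score HIGH — so the database CNV count and the median database
# score (CNVQ) separate the two classes.

SIM_CHROMS <- c("chr1", "chr2", "chr3", "chrX")
SIM_CHROM_LEN <- 1e7L
GENE_SLOT <- 60000L   # gene every 60 kb: 20 kb body + 40 kb gap
GENE_LEN <- 20000L

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a small but structurally complete benchmark: a
#' 20-exome reference collection over a 4-chromosome toy genome
#' (3 autosomes + chrX, 10 Mb each), recurrent artifact loci planted in
#' at least `artifact_recurrence` samples with low scores, rare real CNVs
#' in 1-4 samples with high scores, sporadic low-score false calls in 1-4
#' samples (so low database-count strata contain both classes), and a
#' disease-CNV pair hitting the candidate gene panel while absent from
#' both the reference collection and the public catalogs.
#'
#' Scores are lognormal with the real-CNV median about 3x the
#' false-call median and overlapping tails, so score filtration is
#' non-trivial.
#'
#' @param seed integer seed; identical seeds give byte-identical fixtures.
#' @param n_ref_samples reference-collection size (default 20).
#' @param n_genes genes in the toy genome (default 150).
#' @param n_artifact_loci recurrent artifact sites (default 12; two are
#'   placed on chrX to exercise sex-chromosome exclusion).
#' @param artifact_recurrence minimum number of reference samples carrying
#'   each artifact locus (>= 5; default 8).
#' @param n_true_cnvs real (array-confirmed) CNV loci (default 40).
#' @param n_sporadic_fp low-score false-call loci recurring in only 1-4
#'   reference samples (default 24).
#' @param n_disease_cnvs disease CNVs planted on candidate genes, absent
#'   from reference collection and catalogs, scored above the high
#'   stringency preset (default 2).
#' @param fraction_known fraction of real CNV loci planted into the
#'   synthetic public catalogs (default 0.4).
#' @param score_model list(tp_meanlog, tp_sdlog, fp_meanlog, fp_sdlog) of
#'   the per-class lognormal score distributions.
#' @param program caller name stamped on all generated calls (default
#'   "ExCopyDepth").
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_ref_samples = 20L, n_genes = 150L,
                       n_artifact_loci = 12L, artifact_recurrence = 8L,
                       n_true_cnvs = 40L, n_sporadic_fp = 24L,
                       n_disease_cnvs = 2L, fraction_known = 0.4,
                       score_model = list(tp_meanlog = log(45), tp_sdlog = 0.35,
                                          fp_meanlog = log(15), fp_sdlog = 0.45),
                       program = "ExCopyDepth") {
  cfg <- list(seed = as.integer(seed), n_ref_samples = as.integer(n_ref_samples),
              n_genes = as.integer(n_genes),
              n_artifact_loci = as.integer(n_artifact_loci),
              artifact_recurrence = as.integer(artifact_recurrence),
              n_true_cnvs = as.integer(n_true_cnvs),
              n_sporadic_fp = as.integer(n_sporadic_fp),
              n_disease_cnvs = as.integer(n_disease_cnvs),
              fraction_known = as.numeric(fraction_known),
              score_model = score_model, program = as.character(program))
  counts <- unlist(cfg[c("n_ref_samples", "n_genes", "n_artifact_loci",
                         "n_true_cnvs", "n_sporadic_fp", "n_disease_cnvs")])
  if (any(is.na(counts)) || any(counts < 0))
    stop("all counts must be non-negative integers")
  if (cfg$n_ref_samples < 1L) stop("need at least one reference sample")
  if (cfg$artifact_recurrence < 5L)
    stop("artifact_recurrence must be >= 5 (recurrence below that is not an artifact signature)")
  if (cfg$artifact_recurrence > cfg$n_ref_samples)
    stop("artifact_recurrence cannot exceed n_ref_samples")
  if (cfg$fraction_known < 0 || cfg$fraction_known > 1)
    stop("fraction_known must be in [0, 1]")
  sm <- cfg$score_model
  if (!all(c("tp_meanlog", "tp_sdlog", "fp_meanlog", "fp_sdlog") %in% names(sm)) ||
      !all(is.finite(unlist(sm))))
    stop("score_model needs finite tp_meanlog/tp_sdlog/fp_meanlog/fp_sdlog")
  n_cand <- max(8L, cfg$n_disease_cnvs)
  n_loci <- cfg$n_true_cnvs + cfg$n_sporadic_fp + cfg$n_artifact_loci
  per_chrom <- (SIM_CHROM_LEN - 50000L) %/% GENE_SLOT
  if (cfg$n_genes > 4L * per_chrom)
    stop(sprintf("n_genes must be <= %d for the toy genome", 4L * per_chrom))
  if (cfg$n_genes < n_loci + n_cand + 2L)
    stop("n_genes too small for the requested loci and candidate panel")
  cfg$n_candidate_genes <- n_cand
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config (seed %d): %d ref samples, %d genes, %d real CNV loci,\n",
    "  %d sporadic FP loci, %d artifact loci (recurrence >= %d),\n",
    "  %d disease CNV(s), %.0f%% of real loci planted as catalog-known\n"),
    x$seed, x$n_ref_samples, x$n_genes, x$n_true_cnvs, x$n_sporadic_fp,
    x$n_artifact_loci, x$artifact_recurrence, x$n_disease_cnvs,
    100 * x$fraction_known))
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fmt_score <- function(x) sprintf("%.4f", x)

write_fixture_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  nrow(df)
}

#' Generate a complete synthetic fixture
#'
#' Writes every file the pipeline reads into `out_dir` and returns a
#' manifest. Reruns with the same config are byte-identical. See
#' [sim_config()] for what is planted where; the file `loci.tsv` records
#' the generator's ground truth (locus class, gene, interval, type,
#' planted recurrence, catalog plant) for downstream verification.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest` (data.frame file/n_records),
#'   `paths` (named list of file paths), `loci` (ground-truth loci table)
#'   and `cfg`.
#' @export
generate_fixture <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ref_dir <- file.path(out_dir, "ref_calls")
  if (!dir.exists(ref_dir)) dir.create(ref_dir)

  with_seed(cfg$seed, {
    ## --- toy genome and gene models -----------------------------------
    per_chrom <- ceiling(cfg$n_genes / length(SIM_CHROMS))
    gene_chrom <- rep(SIM_CHROMS, each = per_chrom)[seq_len(cfg$n_genes)]
    slot <- unlist(lapply(table(factor(gene_chrom, levels = SIM_CHROMS)),
                          seq_len), use.names = FALSE)
    genes <- data.frame(
      gene_name = sprintf("GENE%04d", seq_len(cfg$n_genes)),
      chrom = gene_chrom,
      start = 50001L + (slot - 1L) * GENE_SLOT,
      stringsAsFactors = FALSE)
    genes$end <- genes$start + GENE_LEN - 1L
    genes$gene_id <- sprintf("SYNG%06d", seq_len(cfg$n_genes))
    genes$tx_id <- sprintf("SYNT%06d", seq_len(cfg$n_genes))
    genes$n_exons <- sample(5:9, cfg$n_genes, replace = TRUE)

    gencode <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
      g <- genes[i, ]
      ex_start <- as.integer(round(seq(g$start, g$end - 150L,
                                       length.out = g$n_exons)))
      rbind(
        data.frame(chrom = g$chrom, start = g$start, end = g$end,
                   gene_name = g$gene_name, gene_type = "protein_coding",
                   gene_id = g$gene_id, transcript_id = g$tx_id,
                   feature = "gene", stringsAsFactors = FALSE),
        data.frame(chrom = g$chrom, start = ex_start, end = ex_start + 149L,
                   gene_name = g$gene_name, gene_type = "protein_coding",
                   gene_id = g$gene_id, transcript_id = g$tx_id,
                   feature = "exon", stringsAsFactors = FALSE),
        data.frame(chrom = g$chrom,
                   start = c(g$start, g$end - 299L),
                   end = c(g$start + 299L, g$end),
                   gene_name = g$gene_name, gene_type = "protein_coding",
                   gene_id = g$gene_id, transcript_id = g$tx_id,
                   feature = c("UTR5", "UTR3"), stringsAsFactors = FALSE))
    }))

    ## --- locus assignment ---------------------------------------------
    autosomal <- which(!is_sex_chromosome(genes$chrom))
    on_x <- which(is_sex_chromosome(genes$chrom))
    cand_idx <- sort(sample(autosomal, cfg$n_candidate_genes))
    pool_auto <- sample(setdiff(autosomal, cand_idx))
    pool_x <- sample(on_x)

    take <- function(pool, k) list(got = pool[seq_len(k)],
                                   rest = pool[-seq_len(k)])
    t1 <- take(pool_auto, cfg$n_true_cnvs); pool_auto <- t1$rest
    t2 <- take(pool_auto, cfg$n_sporadic_fp); pool_auto <- t2$rest
    n_art_x <- min(2L, cfg$n_artifact_loci, length(pool_x))
    t3x <- take(pool_x, n_art_x)
    t3 <- take(pool_auto, cfg$n_artifact_loci - n_art_x); pool_auto <- t3$rest
    art_idx <- c(t3$got, t3x$got)
    dis_idx <- cand_idx[seq_len(cfg$n_disease_cnvs)]

    mk_loci <- function(idx, class) {
      if (length(idx) == 0L)
        return(data.frame(class = character(0), gene = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), cnv_type = character(0),
                          recurrence = integer(0), catalog = character(0),
                          stringsAsFactors = FALSE))
      g <- genes[idx, ]
      data.frame(class = class, gene = g$gene_name, chrom = g$chrom,
                 start = g$start + 2000L, end = g$end - 2000L,
                 cnv_type = sample(c("DEL", "DUP"), length(idx), replace = TRUE),
                 recurrence = 0L, catalog = NA_character_,
                 stringsAsFactors = FALSE)
    }
    true_loci <- mk_loci(t1$got, "true")
    spor_loci <- mk_loci(t2$got, "sporadic_fp")
    art_loci <- mk_loci(art_idx, "artifact")
    dis_loci <- mk_loci(dis_idx, "disease")
    dis_loci$cnv_type <- rep("DEL", nrow(dis_loci))

    cyc4 <- function(n) ((seq_len(n) - 1L) %% 4L) + 1L
    true_loci$recurrence <- pmin(cyc4(nrow(true_loci)), cfg$n_ref_samples)
    spor_loci$recurrence <- pmin(cyc4(nrow(spor_loci)), cfg$n_ref_samples)
    if (nrow(art_loci))
      art_loci$recurrence <- as.integer(
        sample(cfg$artifact_recurrence:cfg$n_ref_samples, nrow(art_loci),
               replace = TRUE))

    n_known <- floor(cfg$fraction_known * nrow(true_loci))
    if (n_known > 0) {
      known_i <- seq_len(nrow(true_loci)) %in%
        as.integer(round(seq(1, nrow(true_loci), length.out = n_known)))
      true_loci$catalog[known_i] <-
        c("sanger_cnv", "kg_cnv", "dgv_curated")[((seq_len(sum(known_i)) - 1L) %% 3L) + 1L]
    }
    loci <- rbind(true_loci, spor_loci, art_loci, dis_loci)

    ## --- reference collection call sets -------------------------------
    sm <- cfg$score_model
    rscore <- function(n, class) {
      if (class %in% c("true", "disease"))
        stats::rlnorm(n, sm$tp_meanlog, sm$tp_sdlog)
      else
        stats::rlnorm(n, sm$fp_meanlog, sm$fp_sdlog)
    }
    sids <- sprintf("REF%02d", seq_len(cfg$n_ref_samples))
    ref_rows <- list()
    plant <- loci[loci$class != "disease", , drop = FALSE]
    for (i in seq_len(nrow(plant))) {
      l <- plant[i, ]
      carriers <- sample(sids, l$recurrence)
      jit_s <- sample(-500:500, l$recurrence, replace = TRUE)
      jit_e <- sample(-500:500, l$recurrence, replace = TRUE)
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        chrom = l$chrom, start = l$start + jit_s, end = l$end + jit_e,
        cnv_type = l$cnv_type, score = round(rscore(l$recurrence, l$class), 4),
        sample_id = carriers, program = cfg$program, stringsAsFactors = FALSE)
    }
    # private background calls on otherwise unused genes
    n_bg <- min(2L, length(pool_auto) %/% max(cfg$n_ref_samples, 1L))
    if (n_bg > 0) {
      bg_genes <- utils::head(pool_auto, n_bg * cfg$n_ref_samples)
      k <- 0L
      for (s in sids) {
        gi <- bg_genes[k + seq_len(n_bg)]; k <- k + n_bg
        g <- genes[gi, ]
        ref_rows[[length(ref_rows) + 1L]] <- data.frame(
          chrom = g$chrom, start = g$start + 3000L, end = g$end - 3000L,
          cnv_type = sample(c("DEL", "DUP"), n_bg, replace = TRUE),
          score = round(rscore(n_bg, "sporadic_fp"), 4),
          sample_id = s, program = cfg$program, stringsAsFactors = FALSE)
      }
    }
    ref_all <- do.call(rbind, ref_rows)
    ref_all <- split(ref_all, factor(ref_all$sample_id, levels = sids))

    ## --- query call set -----------------------------------------------
    q_rows <- lapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i, ]
      score <- if (l$class == "disease") {
        s <- round(rscore(1, "disease"), 4)
        while (s <= 45) s <- round(rscore(1, "disease"), 4)
        s
      } else round(rscore(1, l$class), 4)
      data.frame(chrom = l$chrom, start = l$start + sample(-300:300, 1L),
                 end = l$end + sample(-300:300, 1L), cnv_type = l$cnv_type,
                 score = score, sample_id = "CASE01", program = cfg$program,
                 locus_class = l$class, locus_gene = l$gene,
                 stringsAsFactors = FALSE)
    })
    query <- do.call(rbind, q_rows)
    query <- query[sample(nrow(query)), , drop = FALSE]
    rownames(query) <- NULL

    ## --- annotation tracks --------------------------------------------
    pc_genes <- genes[sort(sample(cfg$n_genes, cfg$n_genes %/% 2L)), ]
    phastcon <- data.frame(
      chrom = pc_genes$chrom, start = pc_genes$start + 4000L,
      end = pc_genes$start + 4400L,
      score = sample(300:1000, nrow(pc_genes), replace = TRUE))
    hi <- data.frame(chrom = genes$chrom, start = genes$start,
                     end = genes$end, gene_name = genes$gene_name,
                     hi_score = round(stats::runif(cfg$n_genes), 3))
    rvis <- data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, gene_name = genes$gene_name,
                       rvis_score = round(stats::rnorm(cfg$n_genes), 3))

    planted <- loci[!is.na(loci$catalog), , drop = FALSE]
    cat_iv <- function(cat) {
      p <- planted[planted$catalog == cat, , drop = FALSE]
      data.frame(chrom = p$chrom, start = p$start - 100L, end = p$end + 100L,
                 type = p$cnv_type, stringsAsFactors = FALSE)
    }
    sanger <- cat_iv("sanger_cnv")
    kg <- cat_iv("kg_cnv")
    dgvc0 <- cat_iv("dgv_curated")
    dgv_curated <- data.frame(
      chrom = dgvc0$chrom, start = dgvc0$start, end = dgvc0$end,
      stringency = rep(c("inclusive", "stringent"),
                       length.out = nrow(dgvc0)),
      frequency = round(stats::runif(nrow(dgvc0), 0.01, 0.2), 4))
    # raw DGV covers a broad mix of loci, including disease genes: raw DGV
    # membership must NOT confer known status
    dgv_src <- loci[loci$class %in% c("true", "sporadic_fp", "disease"), ]
    dgv_pick <- dgv_src[sample(nrow(dgv_src),
                               max(1L, nrow(dgv_src) %/% 2L)), ]
    dgv <- data.frame(
      chrom = dgv_pick$chrom, start = dgv_pick$start - 200L,
      end = dgv_pick$end + 200L, type = dgv_pick$cnv_type,
      subtype = sample(c("loss", "gain", "complex"), nrow(dgv_pick),
                       replace = TRUE),
      pubmed_id = sample.int(20000000L, nrow(dgv_pick)) + 9999999L)

    cand_genes <- genes[cand_idx, ]
    omim_genes <- rbind(cand_genes,
                        genes[sample(setdiff(seq_len(cfg$n_genes), cand_idx),
                                     5L), ])
    omim <- data.frame(chrom = omim_genes$chrom, start = omim_genes$start,
                       end = omim_genes$end,
                       disease = sprintf("synthetic disorder %s",
                                         omim_genes$gene_name),
                       pubmed_id = sample.int(20000000L, nrow(omim_genes)) +
                         9999999L)
    ddd <- data.frame(chrom = cand_genes$chrom, start = cand_genes$start,
                      end = cand_genes$end, gene_name = cand_genes$gene_name)
    clinvar <- data.frame(
      chrom = cand_genes$chrom, start = cand_genes$start + 5000L,
      end = cand_genes$start + 5400L,
      disease = sprintf("synthetic disorder %s", cand_genes$gene_name),
      hgvs = sprintf("%s:c.100_500del", cand_genes$tx_id))

    ## --- truth set -----------------------------------------------------
    tr <- loci[loci$class %in% c("true", "disease"), , drop = FALSE]
    array_calls <- data.frame(
      chrom = tr$chrom,
      start = tr$start + sample(-100:100, nrow(tr), replace = TRUE),
      end = tr$end + sample(-100:100, nrow(tr), replace = TRUE),
      cnv_type = tr$cnv_type, stringsAsFactors = FALSE)
    probe_src <- loci  # >= 4 probes inside every locus of every class
    probes <- do.call(rbind, lapply(seq_len(nrow(probe_src)), function(i) {
      l <- probe_src[i, ]
      data.frame(chrom = l$chrom,
                 pos = as.integer(round(seq(l$start + 600L, l$end - 600L,
                                            length.out = 6L))))
    }))
    probes <- rbind(probes,
                    data.frame(chrom = genes$chrom,
                               pos = genes$start + 10000L))
    probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]

    ## --- write everything ---------------------------------------------
    paths <- list(
      gencode = file.path(out_dir, "gencode.tsv"),
      phastcon = file.path(out_dir, "phastcon.tsv"),
      haploinsufficiency = file.path(out_dir, "haploinsufficiency.tsv"),
      gene_intolerance = file.path(out_dir, "gene_intolerance.tsv"),
      sanger_cnv = file.path(out_dir, "sanger_cnv.tsv"),
      dgv = file.path(out_dir, "dgv.tsv"),
      dgv_curated = file.path(out_dir, "dgv_curated.tsv"),
      kg_cnv = file.path(out_dir, "kg_cnv.tsv"),
      omim = file.path(out_dir, "omim.tsv"),
      decipher_ddd = file.path(out_dir, "decipher_ddd.tsv"),
      clinvar = file.path(out_dir, "clinvar.tsv"),
      candidate_genes = file.path(out_dir, "candidate_genes.txt"),
      query = file.path(out_dir, "query.tsv"),
      array_calls = file.path(out_dir, "array_calls.tsv"),
      probes = file.path(out_dir, "probes.tsv"),
      loci = file.path(out_dir, "loci.tsv"),
      resources = file.path(out_dir, "resources.yaml"),
      manifest = file.path(out_dir, "manifest.tsv"))

    nrec <- c(
      gencode = write_fixture_tsv(gencode, paths$gencode),
      phastcon = write_fixture_tsv(phastcon, paths$phastcon),
      haploinsufficiency = write_fixture_tsv(hi, paths$haploinsufficiency),
      gene_intolerance = write_fixture_tsv(rvis, paths$gene_intolerance),
      sanger_cnv = write_fixture_tsv(sanger, paths$sanger_cnv),
      dgv = write_fixture_tsv(dgv, paths$dgv),
      dgv_curated = write_fixture_tsv(dgv_curated, paths$dgv_curated),
      kg_cnv = write_fixture_tsv(kg, paths$kg_cnv),
      omim = write_fixture_tsv(omim, paths$omim),
      decipher_ddd = write_fixture_tsv(ddd, paths$decipher_ddd),
      clinvar = write_fixture_tsv(clinvar, paths$clinvar))
    writeLines(cand_genes$gene_name, paths$candidate_genes)
    nrec["candidate_genes"] <- nrow(cand_genes)

    ref_paths <- character(0)
    for (s in sids) {
      p <- file.path(ref_dir, paste0(s, ".tsv"))
      cs <- ref_all[[s]]
      cs$score <- fmt_score(cs$score)
      write_fixture_tsv(cs[, CANONICAL_COLS], p)
      ref_paths[s] <- p
    }
    nrec["ref_calls"] <- sum(vapply(ref_all, nrow, 0L))
    paths$ref_calls <- ref_paths

    qout <- query
    qout$score <- fmt_score(qout$score)
    write_fixture_tsv(qout[, c(CANONICAL_COLS, "locus_class", "locus_gene")],
                      paths$query)
    nrec["query"] <- nrow(query)
    nrec["array_calls"] <- write_fixture_tsv(array_calls, paths$array_calls)
    nrec["probes"] <- write_fixture_tsv(probes, paths$probes)
    nrec["loci"] <- write_fixture_tsv(loci, paths$loci)

    # track paths stored relative to the YAML's own directory, so the
    # fixture is relocatable and byte-identical across output locations
    yaml::write_yaml(lapply(paths[TRACK_NAMES], basename), paths$resources)
    nrec["resources"] <- length(TRACK_NAMES)

    manifest <- data.frame(file = names(nrec), n_records = as.integer(nrec),
                           stringsAsFactors = FALSE)
    write_fixture_tsv(manifest, paths$manifest)

    invisible(structure(list(manifest = manifest, paths = paths, loci = loci,
                             cfg = cfg),
                        class = "cnv_fixture"))
  })
}

#' @export
print.cnv_fixture <- function(x, ...) {
  cat(sprintf("synthetic CNV fixture (seed %d): %d files\n",
              x$cfg$seed, nrow(x$manifest)))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
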