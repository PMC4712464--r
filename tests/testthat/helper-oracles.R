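# Independent brute-force oracles and random-fixture builders. These stay
# deliberately naive (O(n*m) scans, explicit sorting) so they cannot share
# a defect with the indexed implementations they check.

oracle_overlap1 <- function(ac, as_, ae, bc, bs, be) {
  ac == bc & pmax(as_, bs) <= pmin(ae, be)
}

# all rows of `track` overlapping the single query interval
oracle_query <- function(track, chrom, start, end) {
  if (nrow(track) == 0L) return(track)
  hit <- oracle_overlap1(track$chrom, track$start, track$end,
                         chrom, start, end)
  track[hit, , drop = FALSE]
}

oracle_query_db <- function(entries, q, exclude_sample = TRUE,
                            type_blind = FALSE) {
  m <- oracle_query(entries, q$chrom, q$start, q$end)
  if (!type_blind) m <- m[m$cnv_type == q$cnv_type, , drop = FALSE]
  if (exclude_sample) m <- m[m$sample_id != q$sample_id, , drop = FALSE]
  list(db_count = length(unique(m$sample_id)),
       cnvq = if (nrow(m)) median(m$score) else NA_real_,
       rows = m)
}

oracle_label <- function(calls, array_calls, probes, min_probes = 4L,
                         type_aware = TRUE) {
  vapply(seq_len(nrow(calls)), function(i) {
    a <- oracle_query(array_calls, calls$chrom[i], calls$start[i],
                      calls$end[i])
    if (type_aware) a <- a[a$cnv_type == calls$cnv_type[i], , drop = FALSE]
    if (nrow(a) > 0L) return("TP")
    np <- sum(probes$chrom == calls$chrom[i] &
                probes$pos >= calls$start[i] & probes$pos <= calls$end[i])
    if (np >= min_probes) "FP" else "INDETERMINATE"
  }, "")
}

# threshold sweep computed the slow way, one filter pass per threshold
oracle_curve <- function(labeled) {
  lab <- labeled[labeled$label %in% c("TP", "FP"), ]
  qs <- sort(unique(lab$score), decreasing = TRUE)
  do.call(rbind, lapply(qs, function(q) {
    at <- lab[lab$score >= q, ]
    ctp <- sum(at$label == "TP"); cfp <- sum(at$label == "FP")
    data.frame(score = q, cTP = ctp, cFP = cfp, FDR = cfp / (ctp + cfp),
               fp_tp_ratio = if (ctp > 0) cfp / ctp else Inf)
  }))
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000L,
                           max_len = 3000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

rand_calls <- function(n, samples = paste0("S", 1:5), program = "ExomeDepth",
                       chroms = c("chr1", "chr2"), max_pos = 50000L) {
  iv <- rand_intervals(n, chroms, max_pos)
  iv$cnv_type <- sample(c("DEL", "DUP"), n, replace = TRUE)
  iv$score <- round(runif(n, 1, 100), 3)
  iv$sample_id <- sample(samples, n, replace = TRUE)
  iv$program <- program
  iv[, c("chrom", "start", "end", "cnv_type", "score", "sample_id",
         "program")]
}

make_call <- function(chrom = "chr1", start = 1000L, end = 2000L,
                      cnv_type = "DEL", score = 50, sample_id = "S1",
                      program = "ExomeDepth", cnvq = NA_real_,
                      db_count = 0L) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             cnv_type = cnv_type, score = score, sample_id = sample_id,
             program = program, cnvq = cnvq, db_count = as.integer(db_count),
             stringsAsFactors = FALSE)
}

# minimal annotated frame: the columns is_known_cnv()/filter_variants() use
make_annotated <- function(..., sanger_count = 0L, kg_del_count = 0L,
                           kg_dup_count = 0L, dgv_curated_inclusive = FALSE,
                           dgv_curated_stringent = FALSE, genes = NA_character_) {
  df <- make_call(...)
  df$sanger_count <- as.integer(sanger_count)
  df$kg_del_count <- as.integer(kg_del_count)
  df$kg_dup_count <- as.integer(kg_dup_count)
  df$dgv_curated_inclusive <- dgv_curated_inclusive
  df$dgv_curated_stringent <- dgv_curated_stringent
  df$genes <- genes
  df
}

write_track_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

load_fixture_tracks <- function(fx) {
  lapply(names(fx$paths[cnvscreen:::TRACK_NAMES]),
         function(nm) load_track(fx$paths[[nm]], nm))
}

build_fixture_db <- function(fx) {
  build_db(lapply(fx$paths$ref_calls, parse_calls), fx$cfg$program)
}

read_fixture_truth <- function(fx) {
  truth_set(read.delim(fx$paths$array_calls, stringsAsFactors = FALSE),
            read.delim(fx$paths$probes, stringsAsFactors = FALSE))
}
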