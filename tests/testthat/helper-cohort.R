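# Convert generate_cohort() in-memory output into the frames the analysis
# functions take (same normalisation the file readers perform).
cohort_segments <- function(co) {
  seg <- co$segments
  data.frame(sample_id = seg$sample, chrom = as.character(seg$chrom),
             start = as.integer(seg$start - 1L), end = as.integer(seg$end),
             cn_a = pmax(seg$nMajor, seg$nMinor),
             cn_b = pmin(seg$nMajor, seg$nMinor),
             segment_baf = seg$segmentBAF, stringsAsFactors = FALSE)
}

cohort_snps <- function(co) {
  sn <- co$snps
  depth <- sn$ref_count + sn$alt_count
  data.frame(sample_id = sn$sample, chrom = as.character(sn$chrom),
             pos = sn$pos, ref_count = sn$ref_count,
             alt_count = sn$alt_count, depth = depth,
             baf = ifelse(depth > 0, sn$alt_count / depth, NA_real_),
             usable = depth > 0, stringsAsFactors = FALSE)
}

cohort_meta <- function(co) {
  data.frame(sample_id = co$meta$sample, patient_id = co$meta$patient,
             kind = co$meta$kind, purity = co$meta$purity,
             stringsAsFactors = FALSE)
}

analyze_cohort <- function(co, seed = 7L, ...) {
  meta <- cohort_meta(co)
  seg <- cohort_segments(co)
  snp <- cohort_snps(co)
  out <- list()
  for (pid in unique(meta$patient_id)) {
    pm <- meta[meta$patient_id == pid, , drop = FALSE]
    out[[pid]] <- analyze_patient(
      seg[seg$sample_id %in% pm$sample_id, , drop = FALSE],
      snp[snp$sample_id %in% pm$sample_id, , drop = FALSE],
      pm, seed = seed, ...)
  }
  out
}
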