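# End-to-end analysis of one patient: regions -> phasing -> AI/MSAI tests ->
# confident absence -> heterogeneity classification.

#' Analyse one patient's samples for allelic imbalance and heterogeneity
#'
#' Full haplotype-phased copy-number analysis of a multi-sample patient:
#' \enumerate{
#'   \item Segmentations of all samples with purity above `min_ref_purity`
#'     are refined into minimum consistent regions
#'     ([minimum_consistent_regions()]).
#'   \item In each region the most allelically imbalanced sample phases the
#'     SNPs into parental alleles A/B ([select_reference_sample()],
#'     [phase_from_reference()]); labels carry to every sample, including
#'     those with no discernible tumour content.
#'   \item Each sample is tested for allelic imbalance (two-sided rank-sum
#'     on the two phase groups) and, where imbalance is detected, for
#'     mirrored subclonal allelic imbalance (one-sided).
#'   \item Non-detections are qualified by simulation
#'     ([confident_absence()]) and the region is classified
#'     ([classify_segment()]).
#' }
#'
#' @param segments Segment calls for the patient (from [read_segments()]).
#' @param snps SNP observations for the patient (from [read_snp_table()]).
#' @param meta Sample metadata (from [read_sample_meta()]): `sample_id`,
#'   `purity` used here.
#' @param thresholds An [ai_thresholds()] object.
#' @param min_ref_purity Minimum tumour purity for a sample's segmentation
#'   to contribute regions and phasing (default 0.05: below ~5% purity,
#'   allele-specific copy-number calling is unreliable).
#' @param min_region_snps Regions with fewer assigned SNP positions are
#'   flagged `low_confidence` (a rank-sum test on <10 observations cannot
#'   reach p < 0.005 even under complete separation); they are still
#'   processed.
#' @param seed Integer seed for the confident-absence simulations;
#'   per-(region, sample) seeds are derived deterministically so outcomes
#'   are independently reproducible.
#' @return A list with elements `regions`, `results` (one row per region x
#'   sample: `n_snps_a`, `n_snps_b`, `p_ai`, `ai_detected`, `major_allele`,
#'   `p_msai`, `msai`, `absence_confident`, `testable`), `classification`
#'   (one row per region: `class`, `reference_sample`, `phased`,
#'   `low_confidence`), `phased_fraction`, `heterogeneity_fraction`, and
#'   `phase` (per-SNP labels: `chrom`, `pos`, `region_id`, `phase`).
#' @export
analyze_patient <- function(segments, snps, meta,
                            thresholds = ai_thresholds(),
                            min_ref_purity = 0.05,
                            min_region_snps = 10L, seed = 1L) {
  usable <- meta$sample_id[!is.na(meta$purity) & meta$purity > min_ref_purity]
  useg <- segments[segments$sample_id %in% usable, , drop = FALSE]
  if (nrow(useg) == 0L)
    stop("no phasing reference available: no sample with purity > ",
         min_ref_purity, " has segment calls")
  regions <- minimum_consistent_regions(useg, min_snps = min_region_snps)
  states <- region_segment_states(regions, useg)
  snps <- assign_snps(regions, snps)
  purity_of <- setNames(meta$purity, meta$sample_id)
  sample_ids <- sort(unique(snps$sample_id))

  res_rows <- vector("list", nrow(regions))
  cls_rows <- vector("list", nrow(regions))
  phase_rows <- vector("list", nrow(regions))
  snps_by_region <- split(seq_len(nrow(snps)), snps$region_id)

  for (ri in seq_len(nrow(regions))) {
    rid <- regions$region_id[ri]
    st <- states[states$region_id == rid, , drop = FALSE]
    ref <- select_reference_sample(st)
    idx <- snps_by_region[[rid]]
    rsnp <- if (is.null(idx)) snps[0, ] else snps[idx, , drop = FALSE]
    n_pos <- length(unique(rsnp$pos))
    phased <- !is.na(ref)

    phase_map <- NULL
    if (phased) {
      refsnp <- rsnp[rsnp$sample_id == ref, , drop = FALSE]
      labels <- phase_from_reference(refsnp$baf)
      keep <- !is.na(labels)
      phase_map <- setNames(labels[keep], refsnp$pos[keep])
      phased <- length(phase_map) > 0L
    }

    sr <- data.frame(region_id = rid, sample_id = sample_ids,
                     n_snps_a = 0L, n_snps_b = 0L, p_ai = NA_real_,
                     ai_detected = FALSE, major_allele = "none",
                     p_msai = NA_real_, msai = FALSE,
                     absence_confident = NA, testable = FALSE,
                     stringsAsFactors = FALSE)
    if (phased) {
      for (si in seq_along(sample_ids)) {
        s <- sample_ids[si]
        ssnp <- rsnp[rsnp$sample_id == s & rsnp$usable, , drop = FALSE]
        lab <- phase_map[as.character(ssnp$pos)]
        baf_a <- ssnp$baf[lab %in% "A"]
        baf_b <- ssnp$baf[lab %in% "B"]
        sr$n_snps_a[si] <- length(baf_a)
        sr$n_snps_b[si] <- length(baf_b)
        ai <- test_allelic_imbalance(baf_a, baf_b, thresholds)
        sr$p_ai[si] <- ai$p_ai
        sr$ai_detected[si] <- isTRUE(ai$ai_detected)
        sr$testable[si] <- ai$testable
        if (ai$testable) {
          ms <- test_msai(baf_a, baf_b, ai$ai_detected, thresholds)
          sr$p_msai[si] <- ms$p_msai
          sr$msai[si] <- ms$msai
          if (isTRUE(ai$ai_detected))
            sr$major_allele[si] <- if (median(baf_a) >= median(baf_b)) "A" else "B"
        }
      }
      # qualify non-detections: would the detected event have been seen here?
      det <- sr$sample_id[sr$ai_detected]
      det_st <- st[st$sample_id %in% det, , drop = FALSE]
      if (nrow(det_st) > 0L) {
        strongest <- det_st[which.max(abs(det_st$segment_baf - 0.5)), ]
        for (si in seq_along(sample_ids)) {
          if (!sr$testable[si] || sr$ai_detected[si]) next
          n <- sr$n_snps_a[si] + sr$n_snps_b[si]
          cell_seed <- (seed + 104729 * ri + si) %% 2147483647
          sr$absence_confident[si] <- confident_absence(
            strongest$cn_a, strongest$cn_b,
            purity = unname(purity_of[sample_ids[si]]),
            n_snps = n, thresholds = thresholds, seed = as.integer(cell_seed))
        }
      }
    }

    res_rows[[ri]] <- sr
    cls_rows[[ri]] <- data.frame(
      region_id = rid, chrom = regions$chrom[ri], start = regions$start[ri],
      end = regions$end[ri], width = regions$width[ri], phased = phased,
      reference_sample = if (phased) ref else NA_character_,
      n_snps = n_pos, low_confidence = n_pos < min_region_snps,
      class = classify_segment(sr, phased), stringsAsFactors = FALSE)
    if (phased && length(phase_map) > 0L)
      phase_rows[[ri]] <- data.frame(
        region_id = rid, chrom = regions$chrom[ri],
        pos = as.integer(names(phase_map)), phase = unname(phase_map),
        stringsAsFactors = FALSE)
  }

  classification <- do.call(rbind, cls_rows)
  list(regions = regions,
       results = do.call(rbind, res_rows),
       classification = classification,
       phase = do.call(rbind, phase_rows),
       phased_fraction = phased_fraction(classification),
       heterogeneity_fraction = heterogeneity_fraction(classification))
}
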