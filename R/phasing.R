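# Phasing SNPs into parental alleles from the most imbalanced sample.

#' Select the phasing reference sample for a region
#'
#' The sample whose segment BAF deviates most from 0.5 carries the clearest
#' separation between parental alleles and is used to phase the region's
#' SNPs. The folded distance `|segmentBAF - 0.5|` is used so that callers
#' reporting folded (>= 0.5) or unfolded segment BAFs are treated alike; for
#' folded BAFs it reduces to picking the largest segment BAF. If every
#' sample's segment BAF equals 0.5, no copy-number aberration was seen at
#' the locus and the region is not phased.
#'
#' @param states Per-sample segment states for one region, as one
#'   data.frame with columns `sample_id`, `segment_baf` (e.g. a subset of
#'   [region_segment_states()]).
#' @return The reference `sample_id`, or `NA_character_` if the region
#'   cannot be phased. Ties are broken by sample id for determinism.
#' @export
select_reference_sample <- function(states) {
  if (is.null(states) || nrow(states) == 0L) return(NA_character_)
  dev <- abs(states$segment_baf - 0.5)
  dev[is.na(dev)] <- 0
  if (max(dev) == 0) return(NA_character_)
  cand <- states$sample_id[dev == max(dev)]
  sort(cand)[1]
}

#' Phase SNPs from the reference sample's BAFs
#'
#' Within the reference sample, a SNP whose BAF exceeds 0.5 has its counted
#' allele on the major parental allele (labelled A); below 0.5, on the minor
#' allele (B). A BAF of exactly 0.5, or zero depth, leaves the SNP unphased
#' (the dichotomy is exclusive). The labels are then carried to the same
#' SNPs in every other sample of the patient.
#'
#' @param ref_baf BAFs of the region's SNPs in the reference sample (`NA`
#'   for zero-depth SNPs).
#' @return Character vector of the same length: `"A"`, `"B"` or `NA`
#'   (unphased).
#' @export
phase_from_reference <- function(ref_baf) {
  ifelse(is.na(ref_baf), NA_character_,
         ifelse(ref_baf > 0.5, "A", ifelse(ref_baf < 0.5, "B", NA_character_)))
}

#' Length-weighted fraction of the genome that was phased
#'
#' @param classification Per-region classification table from
#'   [analyze_patient()] (columns `width`, `phased`).
#' @return Fraction of the considered genome (union of all regions) lying
#'   in phased regions; 0 when nothing was phased.
#' @export
phased_fraction <- function(classification) {
  total <- sum(classification$width)
  if (total == 0) return(NA_real_)
  sum(classification$width[classification$phased]) / total
}
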