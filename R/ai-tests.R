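#' Detection thresholds and simulation settings
#'
#' Container for the fixed per-test thresholds used throughout:
#' allelic imbalance is called at a two-sided rank-sum p < `alpha_ai`
#' (default 0.005), mirrored subclonal allelic imbalance at a one-sided
#' p < `alpha_msai` (default 0.01), and confident absence of an event is
#' established by `n_absence_sims` simulations (default 100) at depth
#' `absence_sim_depth` (default 50). No multiple-testing correction is
#' applied across regions or samples: thresholds are fixed per test.
#'
#' @param alpha_ai Two-sided p-value threshold for allelic imbalance.
#' @param alpha_msai One-sided p-value threshold for MSAI.
#' @param n_absence_sims Number of simulations backing confident absence.
#' @param absence_sim_depth Read depth of those simulations.
#' @return A list of class `"ai_thresholds"`.
#' @export
ai_thresholds <- function(alpha_ai = 0.005, alpha_msai = 0.01,
                          n_absence_sims = 100L, absence_sim_depth = 50L) {
  stopifnot(alpha_ai > 0, alpha_ai < 1, alpha_msai > 0, alpha_msai < 1,
            n_absence_sims >= 1, absence_sim_depth >= 1)
  structure(list(alpha_ai = alpha_ai, alpha_msai = alpha_msai,
                 n_absence_sims = as.integer(n_absence_sims),
                 absence_sim_depth = as.integer(absence_sim_depth)),
            class = "ai_thresholds")
}

#' Test a phased region for allelic imbalance
#'
#' Two-sided rank-sum comparison of the BAF distributions of SNPs phased to
#' parental alleles A and B within one sample. Significance at strict
#' p < `alpha_ai` calls allelic imbalance.
#'
#' @param baf_a,baf_b BAFs of SNPs phased to alleles A and B in the tested
#'   sample (depth > 0 SNPs only; `NA`s are dropped).
#' @param thresholds An [ai_thresholds()] object.
#' @return A list: `p_ai`, `ai_detected`, `testable` (FALSE when either
#'   phase group is empty, in which case no detection is claimed).
#' @export
test_allelic_imbalance <- function(baf_a, baf_b, thresholds = ai_thresholds()) {
  baf_a <- baf_a[!is.na(baf_a)]; baf_b <- baf_b[!is.na(baf_b)]
  if (length(baf_a) == 0L || length(baf_b) == 0L)
    return(list(p_ai = NA_real_, ai_detected = FALSE, testable = FALSE))
  p <- rank_sum_test(baf_a, baf_b, "two.sided")
  list(p_ai = p, ai_detected = p < thresholds$alpha_ai, testable = TRUE)
}

#' Test a sample for mirrored subclonal allelic imbalance
#'
#' Phase labels are fixed by the patient's reference sample, in which allele
#' A is the major allele. If, in another sample with detected allelic
#' imbalance, the BAFs of allele-A SNPs are significantly *lower* than those
#' of allele-B SNPs (one-sided rank-sum, strict p < `alpha_msai`), the
#' opposite parental allele is imbalanced there: mirrored subclonal allelic
#' imbalance, the signature of parallel evolution.
#'
#' @inheritParams test_allelic_imbalance
#' @param ai_detected Was allelic imbalance detected in this sample? MSAI is
#'   only called on top of a detected imbalance.
#' @return A list: `p_msai`, `msai`.
#' @export
test_msai <- function(baf_a, baf_b, ai_detected,
                      thresholds = ai_thresholds()) {
  baf_a <- baf_a[!is.na(baf_a)]; baf_b <- baf_b[!is.na(baf_b)]
  if (length(baf_a) == 0L || length(baf_b) == 0L)
    return(list(p_msai = NA_real_, msai = FALSE))
  p <- rank_sum_test(baf_a, baf_b, "less")
  list(p_msai = p, msai = isTRUE(ai_detected) && p < thresholds$alpha_msai)
}

#' Is an undetected event confidently absent?
#'
#' When allelic imbalance is detected in one sample of a patient but not in
#' another, the non-detection is only meaningful if the event *would* have
#' been seen given that sample's purity and SNP count. This is assessed by
#' simulation: `n_absence_sims` segments are simulated (via
#' [simulate_segment()]) under the copy-number state of the sample in which
#' the event was detected, at the tested sample's purity and SNP count, at
#' depth `absence_sim_depth`; each is tested for allelic imbalance using the
#' ground-truth phase. The event is confidently absent only if every
#' simulation detects it; a single miss means the sample lacked power and it
#' is excluded from the overall classification.
#'
#' @param cn_a,cn_b Copy-number state of the detected event.
#' @param purity Purity of the tested (non-detecting) sample; `NA` returns
#'   `NA` (untestable).
#' @param n_snps Number of usable phased SNPs on the segment in that sample.
#' @param thresholds An [ai_thresholds()] object.
#' @param seed Optional integer seed.
#' @return `TRUE` (confidently absent), `FALSE`, or `NA` if purity unknown.
#' @export
confident_absence <- function(cn_a, cn_b, purity, n_snps,
                              thresholds = ai_thresholds(), seed = NULL) {
  if (is.na(purity)) return(NA)
  if (n_snps < 2L) return(FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(thresholds$n_absence_sims)) {
    sim <- simulate_segment(purity, cn_a, cn_b, n_snps,
                            depth = thresholds$absence_sim_depth)
    res <- test_allelic_imbalance(sim$baf[sim$allele == "A"],
                                  sim$baf[sim$allele == "B"], thresholds)
    if (!isTRUE(res$ai_detected)) return(FALSE)
  }
  TRUE
}
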