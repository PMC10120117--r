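# Patient-level classification of SCNA heterogeneity.

#' Classify one region across the samples of a patient
#'
#' Aggregates the per-sample test outcomes for one region into an overall
#' class:
#' \itemize{
#'   \item `"no_scna_detected"`: the region could not be phased in any
#'     sample, or allelic imbalance was detected nowhere.
#'   \item `"msai"`: mirrored subclonal allelic imbalance was detected in at
#'     least one sample.
#'   \item `"heterogeneous"`: imbalance confidently detected in at least one
#'     sample and confidently absent in at least one other (or confidently
#'     detected samples disagree on the major allele without reaching
#'     one-sided MSAI significance).
#'   \item `"homogeneous"`: the major allele is consistent across all
#'     samples with a confident call.
#' }
#' Precedence is MSAI > heterogeneous > homogeneous > no_scna_detected.
#' Samples in which the event was neither detected nor confidently absent
#' (see [confident_absence()]) are excluded from the classification.
#'
#' @param sample_results Data frame of per-sample outcomes for one region:
#'   columns `ai_detected`, `msai`, `major_allele`, `absence_confident`,
#'   `testable`.
#' @param phased Was the region phased at all?
#' @return The class, as a length-1 character.
#' @export
classify_segment <- function(sample_results, phased = TRUE) {
  if (!isTRUE(phased) || is.null(sample_results) || nrow(sample_results) == 0L)
    return("no_scna_detected")
  sr <- sample_results[which(sample_results$testable), , drop = FALSE]
  detected <- which(sr$ai_detected %in% TRUE)
  if (length(detected) == 0L) return("no_scna_detected")
  if (any(sr$msai %in% TRUE)) return("msai")
  absent <- which(!(sr$ai_detected %in% TRUE) & sr$absence_confident %in% TRUE)
  if (length(absent) > 0L) return("heterogeneous")
  majors <- unique(sr$major_allele[detected])
  if (length(majors) > 1L) return("heterogeneous")
  "homogeneous"
}

#' Length-weighted heterogeneous fraction of the imbalanced genome
#'
#' Of the genome affected by allelic imbalance (regions classified
#' homogeneous, heterogeneous or MSAI), the fraction classified
#' heterogeneous or MSAI.
#'
#' @param classification Per-region classification table (columns `width`,
#'   `class`).
#' @return The fraction, or `NA` if no region shows allelic imbalance.
#' @export
heterogeneity_fraction <- function(classification) {
  ai <- classification$class %in% c("homogeneous", "heterogeneous", "msai")
  denom <- sum(classification$width[ai])
  if (denom == 0) return(NA_real_)
  het <- classification$class %in% c("heterogeneous", "msai")
  sum(classification$width[het]) / denom
}
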