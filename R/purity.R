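# Tumour-fraction estimation from mean clonal VAF.

#' Ubiquitous (clonal) mutations of a patient
#'
#' Mutations detected -- de novo pass or rescued -- in *every* evaluable
#' sample of the patient. Their mean VAF in a sample scales with that
#' sample's tumour fraction.
#'
#' @param muts Patient mutation table with `status` set (see
#'   [apply_denovo_filters()], [apply_rescue_status()]); `sample_id`
#'   identifies the evaluable samples.
#' @param samples Evaluable sample ids; defaults to all samples in `muts`.
#' @return Data frame of ubiquitous sites: `chrom, pos, ref, alt`.
#' @export
ubiquitous_mutations <- function(muts, samples = unique(muts$sample_id)) {
  det <- muts[muts$status %in% c("pass_de_novo", "rescued") &
                muts$sample_id %in% samples, , drop = FALSE]
  key <- c("chrom", "pos", "ref", "alt")
  site <- do.call(paste, c(det[key], sep = ":"))
  n_det <- tapply(det$sample_id, site, function(s) length(unique(s)))
  ubi <- names(n_det)[n_det == length(samples)]
  out <- det[!duplicated(site) & site %in% ubi, key, drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean clonal VAF of a sample
#'
#' @param muts Patient mutation table (with per-sample `vaf`).
#' @param sample_id The sample to summarise.
#' @param ubiquitous Ubiquitous sites ([ubiquitous_mutations()]).
#' @return Arithmetic mean of the sample's VAFs over the ubiquitous
#'   mutations; `NA` if the patient has none (the sample is then excluded
#'   from purity estimation).
#' @export
mean_clonal_vaf <- function(muts, sample_id, ubiquitous) {
  if (is.null(ubiquitous) || nrow(ubiquitous) == 0L) return(NA_real_)
  key <- c("chrom", "pos", "ref", "alt")
  site <- do.call(paste, c(muts[key], sep = ":"))
  usite <- do.call(paste, c(ubiquitous[key], sep = ":"))
  sel <- muts$sample_id == sample_id & site %in% usite
  if (!any(sel)) return(NA_real_)
  mean(muts$vaf[sel], na.rm = TRUE)
}

#' Calibrate the purity model
#'
#' Ordinary least squares of known purity (from allele-specific copy-number
#' calling on samples of adequate tumour content) on mean clonal VAF. The
#' fitted line converts the mean clonal VAF of a low-purity sample into a
#' tumour-fraction estimate. For diploid heterozygous clonal mutations the
#' theoretical relation is `purity = 2 * VAF`, but the empirical cohort
#' calibration is used rather than that analytic form.
#'
#' @param mean_vaf Mean clonal VAFs of the calibration samples.
#' @param purity Their known purities.
#' @return An object of class `"purity_model"`: `slope`, `intercept`, `r`
#'   (Pearson correlation), `n`.
#' @export
fit_purity_model <- function(mean_vaf, purity) {
  ok <- complete.cases(mean_vaf, purity)
  mean_vaf <- mean_vaf[ok]; purity <- purity[ok]
  if (length(mean_vaf) < 2L)
    stop("at least 2 calibration samples are required")
  if (length(unique(mean_vaf)) < 2L)
    stop("degenerate calibration: mean clonal VAF is constant")
  fit <- lm(purity ~ mean_vaf)
  r <- if (stats::sd(purity) == 0) NA_real_ else cor(mean_vaf, purity)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, n = length(mean_vaf)),
            class = "purity_model")
}

#' @export
print.purity_model <- function(x, ...) {
  cat(sprintf(
    "purity model: purity = %.4f * meanClonalVAF + %.4f (r = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Estimate tumour fraction from mean clonal VAF
#'
#' @param model A fitted [fit_purity_model()] object.
#' @param mean_vaf Mean clonal VAF(s) of the sample(s) to estimate.
#' @return Estimated purity, clipped to `[0, 1]`; a `"clipped"` attribute
#'   flags values that were clipped.
#' @export
estimate_purity <- function(model, mean_vaf) {
  stopifnot(inherits(model, "purity_model"))
  raw <- model$slope * mean_vaf + model$intercept
  out <- pmin(1, pmax(0, raw))
  attr(out, "clipped") <- !is.na(raw) & (raw < 0 | raw > 1)
  out
}
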