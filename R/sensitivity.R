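# Simulation experiments: how low a tumour fraction can phased rank-sum
# testing reach, as a function of SNPs per segment?

#' Detection-rate grid over purity and SNP count
#'
#' For each (purity, SNP count) cell: a perfectly pure reference sample
#' (purity `ref_purity`) is simulated and used to phase the SNPs; a test
#' sample is simulated at the cell's purity with the same ground-truth
#' allele assignment; the two phase groups are compared by the two-sided
#' rank-sum test at `alpha`. The detection rate over `n_reps` replicates is
#' recorded. A purity-0 row serves as the empirical null (false-positive)
#' calibration.
#'
#' @param purities Purities to test; include 0 for the null row.
#' @param snp_counts SNPs per simulated segment.
#' @param depth Read depth per SNP (default 50).
#' @param cn_a,cn_b Copy-number state of the simulated event (default 1+0,
#'   loss of heterozygosity).
#' @param n_reps Replicates per cell (>= 100; thresholds at p < 0.005 need
#'   ~2000 for resolution).
#' @param alpha Detection threshold (strict `p < alpha`).
#' @param ref_purity Purity of the simulated phasing reference.
#' @param seed Root seed; per-cell seeds are derived as
#'   `(seed + 100003 * cell_index) mod (2^31 - 1)` so any cell can be
#'   reproduced in isolation.
#' @return A data.frame: one row per cell with `purity, n_snps, depth,
#'   cn_a, cn_b, n_reps, n_detected, detection_rate`.
#' @export
sensitivity_grid <- function(purities, snp_counts, depth = 50L,
                             cn_a = 1L, cn_b = 0L, n_reps = 2000L,
                             alpha = 0.005, ref_purity = 1, seed = 1L) {
  stopifnot(length(purities) >= 1, length(snp_counts) >= 1, n_reps >= 100)
  cells <- expand.grid(purity = purities, n_snps = snp_counts,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$purity, cells$n_snps), , drop = FALSE]
  baf_ref <- expected_baf(ref_purity, cn_a, cn_b)
  n_det <- integer(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    set.seed(as.integer((seed + 100003 * ci) %% 2147483647))
    n <- cells$n_snps[ci]
    baf_test <- expected_baf(cells$purity[ci], cn_a, cn_b)
    hits <- 0L
    for (rep in seq_len(n_reps)) {
      n_b <- rbinom(1L, n, 0.5)
      prob_ref <- c(rep(baf_ref, n_b), rep(1 - baf_ref, n - n_b))
      ref_baf <- rbinom(n, depth, prob_ref) / depth
      lab_a <- ref_baf > 0.5            # phased from the reference
      usable <- ref_baf != 0.5
      prob_test <- c(rep(baf_test, n_b), rep(1 - baf_test, n - n_b))
      test_baf <- rbinom(n, depth, prob_test) / depth
      p <- rank_sum_test(test_baf[lab_a & usable], test_baf[!lab_a & usable],
                         "two.sided")
      if (!is.na(p) && p < alpha) hits <- hits + 1L
    }
    n_det[ci] <- hits
  }
  data.frame(purity = cells$purity, n_snps = cells$n_snps, depth = depth,
             cn_a = cn_a, cn_b = cn_b, n_reps = n_reps, n_detected = n_det,
             detection_rate = n_det / n_reps)
}

#' Flag rescuable cells of a sensitivity grid
#'
#' A cell is *rescuable* when its detection rate exceeds three times the
#' empirical purity-0 false-positive rate at the same SNP count, with
#' non-overlapping 95% (Clopper-Pearson) binomial confidence intervals --
#' i.e. the signal is clearly separated from the null calibration.
#'
#' @param grid Output of [sensitivity_grid()]; must contain a purity-0 row
#'   for every SNP count.
#' @return The grid (purity > 0 rows) with columns `null_rate`, `ci_lo`,
#'   `ci_hi`, `null_ci_hi`, `rescuable` added.
#' @export
rescuable_cells <- function(grid) {
  null <- grid[grid$purity == 0, , drop = FALSE]
  if (nrow(null) == 0L) stop("grid has no purity-0 null row")
  out <- grid[grid$purity > 0, , drop = FALSE]
  ci <- function(x, n) binom.test(x, n)$conf.int
  null_rate <- setNames(null$detection_rate, null$n_snps)
  null_hi <- setNames(
    vapply(seq_len(nrow(null)),
           function(i) ci(null$n_detected[i], null$n_reps[i])[2], 0),
    null$n_snps)
  key <- as.character(out$n_snps)
  out$null_rate <- unname(null_rate[key])
  cis <- vapply(seq_len(nrow(out)),
                function(i) ci(out$n_detected[i], out$n_reps[i]), c(0, 0))
  out$ci_lo <- cis[1, ]
  out$ci_hi <- cis[2, ]
  out$null_ci_hi <- unname(null_hi[key])
  out$rescuable <- out$detection_rate > 3 * out$null_rate &
    out$ci_lo > out$null_ci_hi
  rownames(out) <- NULL
  out
}

#' Minimum rescuable SNP count at a given purity
#'
#' @param grid Output of [sensitivity_grid()] including the purity-0 row.
#' @param purity The purity row to interrogate.
#' @return The smallest SNP count in the grid that is rescuable at that
#'   purity ([rescuable_cells()]), or `NA` if none is.
#' @export
min_rescuable_snps <- function(grid, purity) {
  rc <- rescuable_cells(grid)
  rc <- rc[abs(rc$purity - purity) < 1e-12 & rc$rescuable, , drop = FALSE]
  if (nrow(rc) == 0L) return(NA_integer_)
  min(rc$n_snps)
}

#' Heatmap of a sensitivity grid
#'
#' Optional visual summary (requires ggplot2): detection rate by purity and
#' SNPs per segment.
#'
#' @param grid Output of [sensitivity_grid()].
#' @return A ggplot object.
#' @export
plot_sensitivity_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  grid$n_snps <- factor(grid$n_snps, levels = sort(unique(grid$n_snps)))
  grid$purity <- factor(grid$purity, levels = sort(unique(grid$purity)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[["n_snps"]],
                                     y = .data[["purity"]],
                                     fill = .data[["detection_rate"]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "detection rate", limits = c(0, 1)) +
    ggplot2::labs(x = "SNPs per segment", y = "tumour purity") +
    ggplot2::theme_minimal()
}
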