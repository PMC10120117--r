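#' Two-sample rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' The workhorse statistic behind allelic-imbalance detection. Uses the
#' exact null distribution of the Mann-Whitney U statistic when both group
#' sizes are at most 25 and there are no ties (decisions at p < 0.005 near
#' small-sample boundaries must not depend on approximation error), and the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y Numeric vectors (e.g. BAFs of SNPs phased to alleles A and B).
#' @param alternative `"two.sided"`, `"less"` (x stochastically smaller than
#'   y) or `"greater"`.
#' @param exact_max Largest group size for which the exact distribution is
#'   used (both groups must be at or below it, and the pooled data untied).
#' @return The p-value. `NA` if either group is empty. When every pooled
#'   value is identical the data carry no ordering information and the
#'   p-value is 1 (two-sided) or 0.5 (one-sided).
#' @examples
#' rank_sum_test(c(.8, .8, .8, .8, .8, .9), c(.1, .2, .2, .2, .1, .2))
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact_max = 25L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) return(NA_real_)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U for x
  ties <- any(duplicated(pooled))
  if (!ties && m <= exact_max && n <= exact_max) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pwilcox(u, m, n),
                                 pwilcox(u - 1, m, n, lower.tail = FALSE))),
      less      = pwilcox(u, m, n),
      greater   = pwilcox(u - 1, m, n, lower.tail = FALSE))
    return(p)
  }
  nn <- m + n
  tie_tab <- rle(sort(pooled))$lengths
  sigma2 <- (m * n / 12) *
    ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(if (alternative == "two.sided") 1 else 0.5)
  z <- u - m * n / 2
  correction <- switch(alternative,
                       two.sided = sign(z) * 0.5, greater = 0.5, less = -0.5)
  z <- (z - correction) / sqrt(sigma2)
  switch(alternative,
         less      = pnorm(z),
         greater   = pnorm(z, lower.tail = FALSE),
         two.sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))))
}
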