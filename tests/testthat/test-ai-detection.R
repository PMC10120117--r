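test_that("allelic-imbalance calls respect the strict p < 0.005 threshold", {
  thr <- ai_thresholds()
  # 5v5 complete separation: p = 2/252 ~ 0.0079, NOT a detection
  r <- test_allelic_imbalance(c(.80, .81, .82, .83, .84),
                              c(.20, .21, .22, .23, .24), thr)
  expect_equal(r$p_ai, 2 / 252)
  expect_false(r$ai_detected)
  # 6v6: p = 2/924 ~ 0.0022, detected
  r <- test_allelic_imbalance(c(.80, .81, .82, .83, .84, .85),
                              c(.20, .21, .22, .23, .24, .25), thr)
  expect_true(r$ai_detected)
  # identical groups: p = 1
  r <- test_allelic_imbalance(rep(.5, 20), rep(.5, 20), thr)
  expect_equal(r$p_ai, 1)
  expect_false(r$ai_detected)
  # empty group: untestable, never a detection
  r <- test_allelic_imbalance(numeric(0), rep(.5, 5), thr)
  expect_false(r$testable)
  expect_false(r$ai_detected)
})

test_that("MSAI is called only when the major allele flips significantly", {
  thr <- ai_thresholds()
  # reference sample (CN 2+1, p=0.95) fixes the phase; test samples share
  # its ground-truth allele assignment (CN 2+1 at p=0.5, D=50, N=100)
  ref <- simulate_segment(0.95, 2, 1, n_snps = 100, depth = 50, seed = 51)
  lab <- phase_from_reference(ref$baf)
  draw_sample <- function(cn_a, cn_b, seed) {
    set.seed(seed)
    b <- expected_baf(0.5, cn_a, cn_b)
    prob <- ifelse(ref$allele == "B", b, 1 - b)
    rbinom(nrow(ref), 50, prob) / 50
  }
  concordant <- draw_sample(2, 1, seed = 52)   # same major allele as ref
  mirrored <- draw_sample(1, 2, seed = 53)     # opposite parental allele

  test_sample <- function(baf) list(a = baf[lab %in% "A"],
                                    b = baf[lab %in% "B"])
  g <- test_sample(concordant)
  ai <- test_allelic_imbalance(g$a, g$b, thr)
  ms <- test_msai(g$a, g$b, ai$ai_detected, thr)
  expect_true(ai$ai_detected)
  expect_false(ms$msai)

  g <- test_sample(mirrored)
  ai <- test_allelic_imbalance(g$a, g$b, thr)
  ms <- test_msai(g$a, g$b, ai$ai_detected, thr)
  expect_true(ai$ai_detected)
  expect_true(ms$msai)

  # identical groups: one-sided p = 0.5, no MSAI
  ms <- test_msai(rep(.5, 10), rep(.5, 10), TRUE, thr)
  expect_equal(ms$p_msai, 0.5)
  expect_false(ms$msai)
})

test_that("confident absence demands universal detectability in simulation", {
  thr <- ai_thresholds()
  # purity 0: expected BAF separation is 0; cannot be confident
  expect_false(confident_absence(2, 0, purity = 0, n_snps = 500,
                                 thresholds = thr, seed = 61))
  # strong event, adequate purity and SNPs: every simulation detects it
  expect_true(confident_absence(2, 0, purity = 0.5, n_snps = 500,
                                thresholds = thr, seed = 62))
  # 5 SNPs: the exact test cannot reach p < 0.005, never confident
  expect_false(confident_absence(2, 0, purity = 1, n_snps = 5,
                                 thresholds = thr, seed = 63))
  # unknown purity: untestable
  expect_true(is.na(confident_absence(2, 0, purity = NA, n_snps = 500,
                                      thresholds = thr)))
})

test_that("per-region classification follows the published precedence", {
  row <- function(det, msai, major, absent, testable = TRUE)
    data.frame(ai_detected = det, msai = msai, major_allele = major,
               absence_confident = absent, testable = testable)
  # unphased in all samples
  expect_equal(classify_segment(NULL, phased = FALSE), "no_scna_detected")
  # AI with allele A major in all three samples
  sr <- rbind(row(TRUE, FALSE, "A", NA), row(TRUE, FALSE, "A", NA),
              row(TRUE, FALSE, "A", NA))
  expect_equal(classify_segment(sr), "homogeneous")
  # detected in one sample, confidently absent in another
  sr <- rbind(row(TRUE, FALSE, "A", NA), row(FALSE, FALSE, "none", TRUE))
  expect_equal(classify_segment(sr), "heterogeneous")
  # non-detection without confident absence is excluded, not heterogeneous
  sr <- rbind(row(TRUE, FALSE, "A", NA), row(FALSE, FALSE, "none", FALSE))
  expect_equal(classify_segment(sr), "homogeneous")
  # MSAI in any sample takes precedence
  sr <- rbind(row(TRUE, FALSE, "A", NA), row(FALSE, FALSE, "none", TRUE),
              row(TRUE, TRUE, "B", NA))
  expect_equal(classify_segment(sr), "msai")
  # phased but nothing detected anywhere
  sr <- rbind(row(FALSE, FALSE, "none", NA), row(FALSE, FALSE, "none", NA))
  expect_equal(classify_segment(sr), "no_scna_detected")
})

test_that("heterogeneous fraction weights the imbalanced genome by length", {
  cl <- data.frame(width = c(40, 60, 100),
                   class = c("msai", "homogeneous", "no_scna_detected"))
  expect_equal(heterogeneity_fraction(cl), 0.40)
  cl$class <- c("homogeneous", "homogeneous", "no_scna_detected")
  expect_equal(heterogeneity_fraction(cl), 0)
  cl$class <- rep("no_scna_detected", 3)
  expect_true(is.na(heterogeneity_fraction(cl)))
})

test_that("false-positive AI rate in purity-0 samples stays at the nominal level", {
  # germline-like samples phased from a pure reference: detection rate over
  # many independent regions should not exceed alpha + 3 SE
  set.seed(77)
  n_reg <- 2000
  hits <- 0
  for (i in seq_len(n_reg)) {
    ref <- rbinom(60, 50, c(rep(0, 30), rep(1, 30))) / 50
    lab <- ref > 0.5
    test <- rbinom(60, 50, 0.5) / 50
    p <- rank_sum_test(test[lab], test[!lab])
    if (!is.na(p) && p < 0.005) hits <- hits + 1
  }
  bound <- 0.005 + 3 * sqrt(0.005 * 0.995 / n_reg)
  expect_lte(hits / n_reg, bound)
})
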