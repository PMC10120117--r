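test_that("expected BAF reproduces the admixture model", {
  # direct substitutions
  expect_equal(expected_baf(0.5, 2, 1), 0.4)
  expect_equal(expected_baf(0, 2, 0), 0.5)   # purity 0: all normal
  expect_equal(expected_baf(1, 1, 0), 0)     # pure LOH, allele B lost
  expect_equal(expected_baf(0.1, 2, 0), 0.9 / 2)

  # allele-swap identity and reduction at p = 0, on a dense grid
  grid <- expand.grid(p = seq(0, 1, by = 0.05), a = 0:4, b = 0:4)
  grid <- grid[!(grid$p == 1 & grid$a + grid$b == 0), ]
  expect_equal(expected_baf(grid$p, grid$a, grid$b) +
                 expected_baf(grid$p, grid$b, grid$a),
               rep(1, nrow(grid)))
  expect_equal(expected_baf(rep(0, 25), grid$a[1:25], grid$b[1:25]),
               rep(0.5, 25))

  # monotone decreasing in purity toward cn_b / (cn_a + cn_b) when a > b
  p <- seq(0, 1, by = 0.01)
  v <- expected_baf(p, 3, 1)
  expect_true(all(diff(v) < 0))
  expect_equal(v[length(v)], 1 / 4)

  # degenerate state rejected
  expect_error(expected_baf(1, 0, 0), "degenerate")
})

test_that("simulated segments follow the binomial read model", {
  s <- simulate_segment(0.5, 2, 0, n_snps = 100, depth = 50, seed = 1)
  expect_equal(nrow(s), 100)                      # N_A + N_B conserved
  expect_setequal(unique(s$allele), c("A", "B"))
  expect_equal(s$baf, s$alt_count / s$depth)

  # purity 0: pooled mean BAF within 0.5 +/- 3 SE (binomial moments)
  s0 <- simulate_segment(0, 2, 0, n_snps = 10000, depth = 50, seed = 2)
  expect_lt(abs(mean(s0$baf) - 0.5), 0.003)

  # pure tumour LOH at high depth: allele-B BAFs concentrate near 0
  s1 <- simulate_segment(1, 2, 0, n_snps = 500, depth = 10000, seed = 3)
  expect_lt(mean(s1$baf[s1$allele == "B"]), 0.01)
  expect_gt(mean(s1$baf[s1$allele == "A"]), 0.99)

  # fixed seed reproduces bit-identically
  expect_identical(simulate_segment(0.3, 2, 1, 200, 50, seed = 9),
                   simulate_segment(0.3, 2, 1, 200, 50, seed = 9))

  expect_error(simulate_segment(1, 0, 0, 10), "degenerate")
})

test_that("count-level germline mixing reaches the target effective purity", {
  tum <- simulate_segment(1, 2, 0, n_snps = 4000, depth = 50, seed = 4)
  germ <- simulate_segment(0, 2, 0, n_snps = 4000, depth = 50, seed = 5)

  expect_identical(mix_with_germline(tum, germ, 1, seed = 6)$alt_count,
                   tum$alt_count)
  expect_identical(mix_with_germline(tum, germ, 0, seed = 6)$alt_count,
                   germ$alt_count)

  # f = 0.1 of a pure tumour ~ purity 0.1: allele-B mean near expected_baf
  mix <- mix_with_germline(tum, germ, 0.1, seed = 7)
  b <- mix$baf[tum$allele == "B"]
  se <- sqrt(0.45 * 0.55 / 50) / sqrt(length(b))
  expect_lt(abs(mean(b) - expected_baf(0.1, 2, 0)), 3 * se + 0.005)

  expect_error(mix_with_germline(tum, germ[-1, ], 0.5), "same SNPs")
})

test_that("detected AI decays monotonically as tumour reads are diluted out", {
  # count-level emulation of BAM downsampling: phase from the pure tumour,
  # test mixtures of decreasing tumour fraction
  set.seed(123)
  fractions <- c(1, 0.1, 0)
  n_reg <- 30
  detected <- sapply(fractions, function(f) {
    hits <- 0
    for (i in seq_len(n_reg)) {
      tum <- simulate_segment(1, 2, 0, n_snps = 300, depth = 50)
      germ <- simulate_segment(0, 2, 0, n_snps = 300, depth = 50)
      mix <- mix_with_germline(tum, germ, f)
      lab <- phase_from_reference(tum$baf)
      r <- test_allelic_imbalance(mix$baf[lab %in% "A"],
                                  mix$baf[lab %in% "B"])
      if (isTRUE(r$ai_detected)) hits <- hits + 1
    }
    hits / n_reg
  })
  expect_true(all(diff(detected) <= 0))
  expect_equal(detected[1], 1)    # pure tumour: always detected
  expect_lt(detected[3], 0.2)     # pure germline: null
})
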