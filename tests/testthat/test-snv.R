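mut_row <- function(var_count, depth, caller_a, caller_b, somatic_p = 0.001,
                    gl_var = 0L, gl_depth = 100L, chrom = "1", pos = 100L,
                    ref = "A", alt = "T", sample = "S1", patient = "P1",
                    is_driver = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample_id = sample, patient_id = patient,
             var_count = var_count, depth = depth, caller_a = caller_a,
             caller_b = caller_b, somatic_p = somatic_p,
             germline_var_count = gl_var, germline_depth = gl_depth,
             is_driver = is_driver,
             vaf = ifelse(depth > 0, var_count / depth, NA_real_),
             stringsAsFactors = FALSE)
}

test_that("de novo filters encode the published rules at their boundaries", {
  # both callers, VAF 3%, somatic p = 0.01, 3 reads, clean germline:
  # the boundary pass
  m <- apply_denovo_filters(mut_row(3L, 100L, TRUE, TRUE, somatic_p = 0.01))
  expect_true(m$pass_de_novo)
  # depth boundary: exactly 10 still passes
  m <- apply_denovo_filters(mut_row(3L, 10L, TRUE, TRUE, somatic_p = 0.01))
  expect_true(m$pass_de_novo)
  m <- apply_denovo_filters(mut_row(4L, 100L, FALSE, TRUE))
  expect_false(m$pass_de_novo)            # single-caller needs VAF >= 5%
  expect_equal(m$fail_reason, "low_vaf_single_caller")
  m <- apply_denovo_filters(mut_row(6L, 100L, FALSE, TRUE))
  expect_true(m$pass_de_novo)             # caller B alone, VAF 6%, >5 reads
  m <- apply_denovo_filters(mut_row(5L, 100L, FALSE, TRUE))
  expect_false(m$pass_de_novo)            # 5 reads not > 5 for single caller
  expect_equal(m$fail_reason, "low_var_reads")
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, TRUE, gl_var = 3L))
  expect_false(m$pass_de_novo)            # germline needs < 3 variant reads
  expect_equal(m$fail_reason, "germline_evidence")
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, TRUE, gl_var = 2L,
                                    gl_depth = 100L))
  expect_false(m$pass_de_novo)            # germline VAF 2% > 1%
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, TRUE, gl_var = NA))
  expect_equal(m$fail_reason, "no germline evidence")
  m <- apply_denovo_filters(mut_row(2L, 9L, TRUE, TRUE))
  expect_equal(m$fail_reason, "low_depth")
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, FALSE))
  expect_equal(m$fail_reason, "caller_support")  # consensus caller alone
  m <- apply_denovo_filters(mut_row(2L, 100L, TRUE, TRUE))
  expect_equal(m$fail_reason, "low_vaf")  # both callers but VAF 2% not > 2%
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, TRUE, somatic_p = 0.02))
  expect_equal(m$fail_reason, "somatic_p")
})

test_that("the patient superset is the union of per-sample passes", {
  m <- rbind(mut_row(30L, 100L, TRUE, TRUE, pos = 1L, sample = "S1"),
             mut_row(30L, 100L, TRUE, TRUE, pos = 2L, sample = "S1"),
             mut_row(30L, 100L, TRUE, TRUE, pos = 2L, sample = "S2"),
             mut_row(30L, 100L, TRUE, TRUE, pos = 3L, sample = "S2"),
             mut_row(1L, 100L, TRUE, TRUE, pos = 4L, sample = "S2"),
             mut_row(30L, 100L, TRUE, TRUE, pos = 5L, alt = "G"),
             mut_row(30L, 100L, TRUE, TRUE, pos = 5L, alt = "C"))
  sup <- collate_patient_mutations(apply_denovo_filters(m))
  expect_equal(sup$pos, c(1L, 2L, 3L, 5L, 5L))  # union, dedup, both ALTs
  # nothing passing anywhere: empty superset
  m <- mut_row(1L, 100L, FALSE, FALSE)
  expect_equal(nrow(collate_patient_mutations(apply_denovo_filters(m))), 0L)
})

test_that("rescue thresholds are >= 3 reads and strictly > 1.5% VAF", {
  sup <- data.frame(chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A",
                    alt = "T", is_driver = FALSE)
  counts <- data.frame(chrom = "1", pos = c(1L, 2L, 3L), ref = "A",
                       alt = "T",
                       var_count = c(3L, 3L, 2L), depth = c(188L, 200L, 20L))
  r <- rescue_mutations(counts, sup)
  expect_equal(r$rescued, c(TRUE,   # 3 reads, VAF 0.01596 > 0.015
                            FALSE,  # 3 reads, VAF exactly 0.015: strict >
                            FALSE)) # VAF 10% but only 2 reads
  # site 4 absent from the count table: unassessable, absent from output
  expect_equal(nrow(r), 3L)
  # a de novo pass is never downgraded by rescue
  m <- apply_denovo_filters(mut_row(30L, 100L, TRUE, TRUE, pos = 9L))
  m2 <- apply_rescue_status(m, r[r$rescued, ])
  expect_equal(m2$status, "pass_de_novo")
})

test_that("rescued sets nest as filters tighten", {
  co <- generate_cohort(seed = 55)
  mu <- co$mutations
  names(mu)[names(mu) == "sample"] <- "sample_id"
  names(mu)[names(mu) == "patient"] <- "patient_id"
  mu$vaf <- mu$var_count / mu$depth
  mu <- apply_denovo_filters(mu)
  sup <- collate_patient_mutations(mu[mu$patient_id == "P1", ])
  rc <- co$readcounts
  names(rc)[names(rc) == "sample"] <- "sample_id"
  counts <- rc[rc$sample_id == "P1_cfdna2", ]
  loose <- rescue_mutations(counts, sup, min_var_reads = 1L, min_vaf = 0)
  mid <- rescue_mutations(counts, sup, min_var_reads = 3L, min_vaf = 0.015)
  tight <- rescue_mutations(counts, sup, min_var_reads = 5L, min_vaf = 0.015)
  expect_true(all(mid$rescued <= loose$rescued))
  expect_true(all(tight$rescued <= mid$rescued))
  # de novo passes imply rescue-eligible counts under the default filters
  denovo <- mu[mu$sample_id == "P1_cfdna2" & mu$pass_de_novo, ]
  if (nrow(denovo) > 0)
    expect_true(all(denovo$var_count >= 3 & denovo$vaf > 0.015))
})

test_that("cross-patient sharing is counted exactly on a toy cohort", {
  # patient 1's cfDNA carries 5 called mutations; one of them (pos 50,
  # non-driver) is also above threshold in patient 2's cfDNA
  sup <- data.frame(patient_id = "Pa", chrom = "1", pos = c(10L, 20L, 30L,
                                                            40L, 50L),
                    ref = "A", alt = "T", is_driver = FALSE,
                    stringsAsFactors = FALSE)
  sup2 <- data.frame(patient_id = "Pb", chrom = "1", pos = 99L, ref = "A",
                     alt = "T", is_driver = FALSE, stringsAsFactors = FALSE)
  rc <- rbind(
    data.frame(sample_id = "Pa_cf", patient_id = "Pa", chrom = "1",
               pos = c(10L, 20L, 30L, 40L, 50L), ref = "A", alt = "T",
               var_count = 10L, depth = 100L, stringsAsFactors = FALSE),
    data.frame(sample_id = "Pb_cf", patient_id = "Pb", chrom = "1",
               pos = c(50L, 99L), ref = "A", alt = "T", var_count = 10L,
               depth = 100L, stringsAsFactors = FALSE))
  sweep <- threshold_sweep(rc, rbind(sup, sup2), read_filters = 3L,
                           vaf_filters = 0.015)
  row <- sweep[sweep$sample_id == "Pa_cf", ]
  expect_equal(row$n_called, 5L)
  expect_equal(row$n_shared, 1L)
  expect_equal(row$sharing_proportion, 1 / 5)

  # a shared driver is excluded from numerator and denominator
  sup$is_driver[sup$pos == 50L] <- TRUE
  sweep <- threshold_sweep(rc, rbind(sup, sup2), read_filters = 3L,
                           vaf_filters = 0.015)
  row <- sweep[sweep$sample_id == "Pa_cf", ]
  expect_equal(row$n_called, 4L)
  expect_equal(row$n_shared, 0L)

  expect_error(threshold_sweep(rc[rc$patient_id == "Pa", ], sup),
               "single-patient")
})

test_that("sweep counts shrink monotonically as filters tighten", {
  co <- generate_cohort(seed = 56)
  mu <- co$mutations
  names(mu)[c(5, 6)] <- c("sample_id", "patient_id")
  mu$vaf <- mu$var_count / mu$depth
  mu <- apply_denovo_filters(mu)
  sups <- do.call(rbind, lapply(split(mu, mu$patient_id), function(pm) {
    s <- collate_patient_mutations(pm)
    if (nrow(s)) s$patient_id <- pm$patient_id[1]
    s
  }))
  rc <- co$readcounts
  names(rc)[names(rc) == "sample"] <- "sample_id"
  names(rc)[names(rc) == "patient"] <- "patient_id"
  rc <- rc[grepl("cfdna", rc$sample_id), ]
  sweep <- threshold_sweep(rc, sups)
  for (s in unique(sweep$sample_id)) {
    sw <- sweep[sweep$sample_id == s & sweep$vaf_filter == 0, ]
    sw <- sw[order(sw$read_filter), ]
    expect_true(all(diff(sw$n_called) <= 0))
    # planted artefacts (1-2 reads) vanish at stringent filters
    strict <- sweep[sweep$sample_id == s & sweep$read_filter == 10 &
                      sweep$vaf_filter == 0.015, ]
    expect_true(is.na(strict$sharing_proportion) ||
                  strict$sharing_proportion == 0)
  }
  # artefact sharing is visible at the loosest cell for host-patient cfDNA
  loose <- sweep[sweep$read_filter == 1 & sweep$vaf_filter == 0, ]
  expect_gt(sum(loose$n_shared, na.rm = TRUE), 0)
})
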