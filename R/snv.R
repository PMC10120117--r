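# Post-caller somatic mutation filtering and patient-informed rescue.

#' Apply the de novo post-caller filters
#'
#' Conjunctive filter over two-caller output (caller A: consensus caller,
#' e.g. MuTect; caller B: the caller reporting a somatic p-value, e.g.
#' VarScan2), applied per sample:
#' \itemize{
#'   \item sequencing depth >= 10 at the mutated position;
#'   \item called by both callers with VAF > 2%, or by caller B alone with
#'     VAF >= 5% (caller-A-only calls fail);
#'   \item somatic p-value <= 0.01 (caller B);
#'   \item > 5 variant reads, relaxed to >= 3 when both callers agree;
#'   \item germline evidence: < 3 variant reads and VAF <= 1% in the
#'     matched germline.
#' }
#'
#' @param muts Mutation table (as from [read_mutations()]).
#' @return `muts` with `pass_de_novo` (logical) and `fail_reason` (first
#'   failing rule, `NA` for passing rows) added, and `status` set to
#'   `"pass_de_novo"` or `"fail"`.
#' @export
apply_denovo_filters <- function(muts) {
  n <- nrow(muts)
  reason <- rep(NA_character_, n)
  gl_vaf <- ifelse(muts$germline_depth > 0,
                   muts$germline_var_count / muts$germline_depth, 0)
  set_fail <- function(reason, cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- set_fail(reason, is.na(muts$germline_var_count) |
                       is.na(muts$germline_depth), "no germline evidence")
  reason <- set_fail(reason, muts$depth < 10, "low_depth")
  both <- muts$caller_a & muts$caller_b
  b_only <- !muts$caller_a & muts$caller_b
  reason <- set_fail(reason, !muts$caller_b, "caller_support")
  reason <- set_fail(reason, both & muts$vaf <= 0.02, "low_vaf")
  reason <- set_fail(reason, b_only & muts$vaf < 0.05, "low_vaf_single_caller")
  somatic_p <- ifelse(is.na(muts$somatic_p), Inf, muts$somatic_p)
  reason <- set_fail(reason, somatic_p > 0.01, "somatic_p")
  reason <- set_fail(reason, both & muts$var_count < 3, "low_var_reads")
  reason <- set_fail(reason, b_only & muts$var_count <= 5, "low_var_reads")
  reason <- set_fail(reason, muts$germline_var_count >= 3 | gl_vaf > 0.01,
                     "germline_evidence")
  muts$pass_de_novo <- is.na(reason)
  muts$fail_reason <- reason
  muts$status <- ifelse(muts$pass_de_novo, "pass_de_novo", "fail")
  muts
}

#' Collate a patient's confidently called mutations
#'
#' The tumour-informed superset: every mutation passing the de novo filters
#' in at least one sample of the patient, deduplicated by site and alleles.
#'
#' @param muts Mutation table for one patient after
#'   [apply_denovo_filters()].
#' @return A data.frame of unique `chrom, pos, ref, alt` (plus `is_driver`)
#'   passing somewhere; zero rows if nothing passed (such patients are
#'   excluded downstream).
#' @export
collate_patient_mutations <- function(muts) {
  passed <- muts[muts$pass_de_novo, , drop = FALSE]
  key <- c("chrom", "pos", "ref", "alt")
  out <- passed[!duplicated(passed[key]), c(key, "is_driver"), drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescue patient-specific mutations in a low-purity sample
#'
#' Re-genotypes a low-purity (e.g. cfDNA) sample at the sites of the
#' patient's mutation superset with relaxed evidence thresholds: a site is
#' rescued iff it shows at least `min_var_reads` variant reads *and* a VAF
#' strictly greater than `min_vaf`. The defaults (3 reads, 1.5%) balance
#' true-positive recovery against recurrent sequencing artefacts (see
#' [threshold_sweep()]). A de novo pass is never downgraded.
#'
#' @param counts Per-site read counts for the sample: `chrom, pos, ref,
#'   alt, var_count, depth` (and optionally `vaf`). Sites of the superset
#'   absent from `counts` are unassessable and not rescued.
#' @param superset Patient mutation superset
#'   ([collate_patient_mutations()]).
#' @param min_var_reads Minimum variant read count (inclusive).
#' @param min_vaf VAF threshold (strict `>`).
#' @return `counts` restricted to superset sites, with `vaf`, `rescued`
#'   added.
#' @export
rescue_mutations <- function(counts, superset, min_var_reads = 3L,
                             min_vaf = 0.015) {
  key <- c("chrom", "pos", "ref", "alt")
  counts_key <- do.call(paste, c(counts[key], sep = ":"))
  superset_key <- do.call(paste, c(superset[key], sep = ":"))
  out <- counts[counts_key %in% superset_key, , drop = FALSE]
  if (!"vaf" %in% names(out))
    out$vaf <- ifelse(out$depth > 0, out$var_count / out$depth, NA_real_)
  out$rescued <- !is.na(out$vaf) & out$var_count >= min_var_reads &
    out$vaf > min_vaf
  rownames(out) <- NULL
  out
}

#' Combine de novo and rescue status
#'
#' @param muts Per-sample mutation table after [apply_denovo_filters()].
#' @param rescued_sites Data frame of rescued sites for the same sample
#'   (output of [rescue_mutations()] filtered to `rescued`).
#' @return `muts` with `status` upgraded to `"rescued"` where a failing
#'   mutation was rescued; `"pass_de_novo"` is never downgraded.
#' @export
apply_rescue_status <- function(muts, rescued_sites) {
  key <- c("chrom", "pos", "ref", "alt")
  mkey <- do.call(paste, c(muts[key], sep = ":"))
  rkey <- do.call(paste, c(rescued_sites[key], sep = ":"))
  muts$status <- ifelse(muts$status == "fail" & mkey %in% rkey,
                        "rescued", muts$status)
  muts
}

#' Cross-patient threshold sweep for the rescue filters
#'
#' Rationale: bona fide rescued mutations should be patient-specific,
#' whereas recurrent artefacts and sequencing noise appear across patients.
#' For every combination of a variant read-count filter and a VAF filter,
#' each cfDNA sample is re-genotyped at its own patient's superset sites
#' (drivers removed first, since genuine driver overlap between patients is
#' expected); the number of mutations called and the proportion also
#' positively identified, under the same filters, in at least one cfDNA
#' sample of a *different* patient is reported.
#'
#' @param readcounts Cohort-wide re-genotyping table: `sample_id,
#'   patient_id, chrom, pos, ref, alt, var_count, depth` for every cfDNA
#'   sample at every superset site of every patient.
#' @param supersets Per-patient supersets, one data.frame with columns
#'   `patient_id, chrom, pos, ref, alt, is_driver`.
#' @param read_filters Variant read-count filters (inclusive >=).
#' @param vaf_filters VAF filters (strict >).
#' @param within_patient If `TRUE`, sharing also counts other cfDNA samples
#'   of the same patient; default `FALSE`: only samples of other patients
#'   count as shared.
#' @return A data.frame: `read_filter, vaf_filter, sample_id, n_called,
#'   n_shared, sharing_proportion` (NA when nothing is called).
#' @export
threshold_sweep <- function(readcounts, supersets,
                            read_filters = c(1L, 2L, 3L, 5L, 10L),
                            vaf_filters = c(0, 0.01, 0.015),
                            within_patient = FALSE) {
  if (length(unique(supersets$patient_id)) < 2L && !within_patient)
    stop("cross-patient sharing is undefined for a single-patient cohort")
  supersets <- supersets[!supersets$is_driver, , drop = FALSE]
  key <- function(df) do.call(paste, c(df[c("chrom", "pos", "ref", "alt")],
                                       sep = ":"))
  readcounts$site <- key(readcounts)
  supersets$site <- key(supersets)
  readcounts$vaf <- ifelse(readcounts$depth > 0,
                           readcounts$var_count / readcounts$depth, 0)
  samples <- unique(readcounts[c("sample_id", "patient_id")])
  rows <- list()
  for (rf in read_filters) for (vf in vaf_filters) {
    pos <- readcounts[readcounts$var_count >= rf & readcounts$vaf > vf, ,
                      drop = FALSE]
    for (i in seq_len(nrow(samples))) {
      s <- samples$sample_id[i]; p <- samples$patient_id[i]
      own_sites <- supersets$site[supersets$patient_id == p]
      called <- unique(pos$site[pos$sample_id == s & pos$site %in% own_sites])
      other <- if (within_patient) pos$sample_id != s else pos$patient_id != p
      shared_sites <- unique(pos$site[other])
      n_called <- length(called)
      n_shared <- sum(called %in% shared_sites)
      rows[[length(rows) + 1L]] <- data.frame(
        read_filter = rf, vaf_filter = vf, sample_id = s,
        n_called = n_called, n_shared = n_shared,
        sharing_proportion = if (n_called > 0) n_shared / n_called
                             else NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
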