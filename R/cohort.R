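# Synthetic multi-sample cohort with ground truth: the test bed for every
# pipeline stage. Statistical structure follows the package's BAF model
# (binomial read sampling around expected_baf) and a binomial VAF model for
# mutations; see the methods vignette for what it does and does not emulate.

#' Default synthetic cohort specification
#'
#' Two patients, each with a PDX (purity 0.95), a metastasis biopsy (0.60),
#' a cfDNA sample of adequate tumour content (0.35), a low-purity cfDNA
#' sample (0.08, below the usability threshold for allele-specific
#' copy-number calling, so no segments are emitted for it) and a germline
#' sample (purity 0). Five chromosomes of 100 Mb carry planted segment
#' classes: homogeneous copy-neutral LOH (2+0 in every tumour sample),
#' MSAI (2+0 with the opposite parental allele lost in one cfDNA sample),
#' heterogeneous (2+0 absent from one cfDNA sample), a homogeneous gain
#' (2+1) and balanced (1+1) segments. SNP depth 50, ~1 SNP per 250 kb;
#' mutation depth 100 with clonal mutations in every tumour sample
#' (VAF ~ purity/2), subclonal mutations confined to the tissue samples,
#' and low-count artefact sites recurring across patients' cfDNA.
#'
#' @return A list understood by [generate_cohort()]; edit fields to vary
#'   the design.
#' @export
default_cohort_spec <- function() {
  list(
    patients = c("P1", "P2"),
    samples = data.frame(
      suffix = c("pdx", "met", "cfdna1", "cfdna2", "germline"),
      kind = c("pdx", "metastasis", "cfdna", "cfdna", "germline"),
      purity = c(0.95, 0.60, 0.35, 0.08, 0),
      has_segments = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    segments = data.frame(
      chrom = c("1", "1", "2", "2", "3", "3", "4", "5"),
      start = c(0, 50e6, 0, 60e6, 0, 40e6, 0, 0),
      end = c(50e6, 100e6, 60e6, 100e6, 40e6, 100e6, 100e6, 100e6),
      type = c("loh_hom", "balanced", "msai", "balanced", "het",
               "balanced", "gain_hom", "balanced"),
      stringsAsFactors = FALSE),
    split_sample = "met", split_chrom = "1",  # exercises region refinement
    snp_depth = 50L, snp_density = 4e-6,
    mut_depth = 100L, n_clonal = 30L, n_subclonal = 10L, n_drivers = 2L,
    n_artefacts = 10L)
}

# ordered parental copy numbers (cn of parent A, cn of parent B) for a
# planted segment type in a given sample
.planted_cn <- function(type, suffix) {
  if (suffix == "germline" || type == "balanced") return(c(1L, 1L))
  switch(type,
         loh_hom = c(2L, 0L),
         gain_hom = c(2L, 1L),
         msai = if (suffix == "cfdna1") c(0L, 2L) else c(2L, 0L),
         het = if (suffix == "cfdna1") c(1L, 1L) else c(2L, 0L),
         stop("unknown planted segment type: ", type))
}

.truth_class <- function(type) {
  switch(type, loh_hom = "homogeneous", gain_hom = "homogeneous",
         msai = "msai", het = "heterogeneous", balanced = "no_scna_detected")
}

.rand_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Generate a synthetic multi-sample cohort with ground truth
#'
#' Emits, in memory and optionally on disk (in the exact dialects the
#' package's readers consume), complete per-patient data sets: sample
#' metadata, ASCAT-style segment tables (model-based folded segment BAFs,
#' 1-based coordinates), per-SNP read counts, mutation tables with
#' two-caller provenance and germline counts, a cohort-wide re-genotyping
#' table for the threshold sweep, and truth sidecars (per-region class,
#' per-SNP parental phase, per-mutation clonality).
#'
#' Consistency of the plant is validated: an MSAI or heterogeneous type on
#' a balanced template is impossible by construction. The same seed yields
#' byte-identical outputs.
#'
#' @param spec Cohort specification ([default_cohort_spec()]).
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, TSVs are written.
#' @return A list: `meta`, `segments`, `snps`, `mutations`, `readcounts`,
#'   `truth` (list of `regions`, `snps`, `mutations`), and `paths` when
#'   `dir` was given.
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = 1L,
                            dir = NULL) {
  stopifnot(all(spec$segments$end > spec$segments$start))
  if (any(spec$segments$type == "msai") &&
      !all(c("pdx", "cfdna1") %in% spec$samples$suffix))
    stop("inconsistent spec: MSAI needs both a reference and a mirrored sample")
  set.seed(as.integer(seed))

  # refine the template where one sample's segmentation is split, so truth
  # regions match the pipeline's minimum consistent regions
  template <- spec$segments
  template$start <- as.integer(template$start)
  template$end <- as.integer(template$end)
  truth_regions <- template
  split_rows <- which(truth_regions$chrom == spec$split_chrom)
  if (length(split_rows) > 0L) {
    r <- split_rows[1]
    mid <- as.integer((truth_regions$start[r] + truth_regions$end[r]) %/% 2)
    top <- truth_regions[r, ]; bottom <- truth_regions[r, ]
    top$end <- mid; bottom$start <- mid
    truth_regions <- rbind(truth_regions[seq_len(r - 1), , drop = FALSE],
                           top, bottom,
                           truth_regions[-seq_len(r), , drop = FALSE])
  }
  truth_regions$class <- vapply(truth_regions$type, .truth_class, "")

  meta_rows <- list(); seg_rows <- list(); snp_rows <- list()
  mut_rows <- list(); tsnp_rows <- list(); tmut_rows <- list()
  all_sites <- list()

  for (pid in spec$patients) {
    sm <- spec$samples
    sm$sample_id <- paste(pid, sm$suffix, sep = "_")
    meta_rows[[pid]] <- data.frame(
      sample = sm$sample_id, patient = pid, kind = sm$kind,
      purity = sm$purity, stringsAsFactors = FALSE)

    # --- SNPs: positions and parental phase are patient-level truth
    for (ti in seq_len(nrow(truth_regions))) {
      tr <- truth_regions[ti, ]
      width <- tr$end - tr$start
      n <- max(2L, round(width * spec$snp_density))
      pos <- sort(sample.int(width, n)) - 1L + tr$start
      parent <- ifelse(rbinom(n, 1L, 0.5) == 1L, "B", "A")
      tsnp_rows[[length(tsnp_rows) + 1L]] <- data.frame(
        patient = pid, chrom = tr$chrom, pos = pos, parent = parent,
        region_start = tr$start, region_end = tr$end, type = tr$type,
        stringsAsFactors = FALSE)
      for (si in seq_len(nrow(sm))) {
        cn <- .planted_cn(tr$type, sm$suffix[si])
        denom <- 2 - 2 * sm$purity[si] + sm$purity[si] * sum(cn)
        p_a <- (1 - sm$purity[si] + sm$purity[si] * cn[1]) / denom
        prob <- ifelse(parent == "A", p_a, 1 - p_a)
        alt <- rbinom(n, spec$snp_depth, prob)
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          chrom = tr$chrom, pos = pos, sample = sm$sample_id[si],
          ref_count = spec$snp_depth - alt, alt_count = alt,
          stringsAsFactors = FALSE)
      }
    }

    # --- segment tables (samples with usable allele-specific CN only);
    # model-based folded segment BAF, 1-based inclusive coordinates
    for (si in which(sm$has_segments)) {
      segs <- template
      if (sm$suffix[si] == spec$split_sample) {
        segs <- truth_regions[, names(template)]  # includes the split
      }
      for (gi in seq_len(nrow(segs))) {
        cn <- .planted_cn(segs$type[gi], sm$suffix[si])
        baf_b <- expected_baf(sm$purity[si], cn[1], cn[2])
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          chrom = segs$chrom[gi], start = segs$start[gi] + 1L,
          end = segs$end[gi], nMajor = max(cn), nMinor = min(cn),
          segmentBAF = max(baf_b, 1 - baf_b), sample = sm$sample_id[si],
          stringsAsFactors = FALSE)
      }
    }

    # --- mutations: clonal everywhere, subclonal in tissue only
    n_sites <- spec$n_clonal + spec$n_subclonal
    chrom <- sample(unique(template$chrom), n_sites, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample.int(max(template$end[template$chrom == ch]), 1L) - 1L, 0L)
    al <- .rand_alleles(n_sites)
    clonal <- c(rep(TRUE, spec$n_clonal), rep(FALSE, spec$n_subclonal))
    is_driver <- c(rep(TRUE, spec$n_drivers),
                   rep(FALSE, n_sites - spec$n_drivers))
    tmut_rows[[length(tmut_rows) + 1L]] <- data.frame(
      patient = pid, chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
      clonality = ifelse(clonal, "clonal", "subclonal"),
      is_driver = is_driver, stringsAsFactors = FALSE)
    tumour <- sm[sm$kind != "germline", , drop = FALSE]
    for (si in seq_len(nrow(tumour))) {
      present <- clonal | tumour$suffix[si] %in% c("pdx", "met")
      vaf_true <- ifelse(present, tumour$purity[si] / 2, 0)
      var <- rbinom(n_sites, spec$mut_depth, vaf_true)
      vaf <- var / spec$mut_depth
      caller_a <- vaf >= 0.05 & var >= 6
      caller_b <- vaf >= 0.03 & var >= 3
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
        sample = tumour$sample_id[si], patient = pid, var_count = var,
        depth = spec$mut_depth, caller_a = caller_a, caller_b = caller_b,
        somatic_p = ifelse(caller_b, 0.001, 1), germline_var_count = 0L,
        germline_depth = spec$mut_depth, is_driver = is_driver,
        stringsAsFactors = FALSE)
    }
    all_sites[[pid]] <- data.frame(patient = pid, chrom = chrom, pos = pos,
                                   ref = al$ref, alt = al$alt,
                                   clonality = ifelse(clonal, "clonal",
                                                      "subclonal"),
                                   stringsAsFactors = FALSE)
  }

  # --- cross-patient artefact sites: pass de novo in one host patient's
  # metastasis, recur at 1-2 reads in every patient's cfDNA samples
  if (spec$n_artefacts > 0L) {
    chrom <- sample(unique(template$chrom), spec$n_artefacts, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample.int(max(template$end[template$chrom == ch]), 1L) - 1L, 0L)
    al <- .rand_alleles(spec$n_artefacts)
    host <- rep_len(spec$patients, spec$n_artefacts)
    for (ai in seq_len(spec$n_artefacts)) {
      for (pid in spec$patients) {
        sm <- spec$samples
        sm$sample_id <- paste(pid, sm$suffix, sep = "_")
        tumour <- sm[sm$kind != "germline", , drop = FALSE]
        for (si in seq_len(nrow(tumour))) {
          is_host_met <- pid == host[ai] && tumour$suffix[si] == "met"
          is_cfdna <- tumour$kind[si] == "cfdna"
          if (!is_host_met && !is_cfdna) next
          var <- if (is_host_met) 10L else 1L + rbinom(1L, 1L, 0.5)
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            chrom = chrom[ai], pos = pos[ai], ref = al$ref[ai],
            alt = al$alt[ai], sample = tumour$sample_id[si], patient = pid,
            var_count = var, depth = spec$mut_depth,
            caller_a = is_host_met, caller_b = is_host_met,
            somatic_p = if (is_host_met) 0.001 else 1,
            germline_var_count = 0L, germline_depth = spec$mut_depth,
            is_driver = FALSE, stringsAsFactors = FALSE)
        }
      }
      tmut_rows[[length(tmut_rows) + 1L]] <- data.frame(
        patient = host[ai], chrom = chrom[ai], pos = pos[ai],
        ref = al$ref[ai], alt = al$alt[ai], clonality = "artefact",
        is_driver = FALSE, stringsAsFactors = FALSE)
      all_sites[[paste0("artefact", ai)]] <- data.frame(
        patient = host[ai], chrom = chrom[ai], pos = pos[ai],
        ref = al$ref[ai], alt = al$alt[ai], clonality = "artefact",
        stringsAsFactors = FALSE)
    }
  }

  meta <- do.call(rbind, meta_rows)
  segments <- do.call(rbind, seg_rows)
  snps <- do.call(rbind, snp_rows)
  mutations <- do.call(rbind, mut_rows)
  truth_snps <- do.call(rbind, tsnp_rows)
  truth_muts <- do.call(rbind, tmut_rows)
  rownames(meta) <- rownames(segments) <- rownames(snps) <-
    rownames(mutations) <- rownames(truth_snps) <- rownames(truth_muts) <- NULL

  # --- cohort-wide re-genotyping (bam-readcount emulation): every sample's
  # counts at every patient's mutation sites
  sites <- do.call(rbind, all_sites)
  mut_key <- with(mutations, paste(sample, chrom, pos, ref, alt, sep = ":"))
  rc_rows <- list()
  for (s in unique(mutations$sample)) {
    pid <- meta$patient[match(s, meta$sample)]
    idx <- match(paste(s, sites$chrom, sites$pos, sites$ref, sites$alt,
                       sep = ":"), mut_key)
    rc_rows[[s]] <- data.frame(
      sample = s, patient = pid, chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt,
      var_count = ifelse(is.na(idx), 0L, mutations$var_count[idx]),
      depth = spec$mut_depth, site_patient = sites$patient,
      stringsAsFactors = FALSE)
  }
  readcounts <- do.call(rbind, rc_rows)
  rownames(readcounts) <- NULL

  truth <- list(
    regions = data.frame(
      patient = rep(spec$patients, each = nrow(truth_regions)),
      chrom = truth_regions$chrom, start = truth_regions$start,
      end = truth_regions$end, type = truth_regions$type,
      class = truth_regions$class, stringsAsFactors = FALSE),
    snps = truth_snps, mutations = truth_muts)

  out <- list(meta = meta, segments = segments, snps = snps,
              mutations = mutations, readcounts = readcounts, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(meta = "meta.tsv", segments = "segments.tsv",
               snps = "snps.tsv", mutations = "mutations.tsv",
               readcounts = "readcounts.tsv",
               truth_regions = "truth_regions.tsv",
               truth_snps = "truth_snps.tsv",
               truth_mutations = "truth_mutations.tsv")
    paths <- setNames(file.path(dir, paths), names(paths))
    write_tsv(meta, paths[["meta"]])
    write_tsv(segments, paths[["segments"]])
    write_tsv(snps, paths[["snps"]])
    write_tsv(mutations, paths[["mutations"]])
    write_tsv(readcounts, paths[["readcounts"]])
    write_tsv(truth$regions, paths[["truth_regions"]])
    write_tsv(truth$snps, paths[["truth_snps"]])
    write_tsv(truth$mutations, paths[["truth_mutations"]])
    out$paths <- paths
  }
  out
}

#' Compare pipeline output against a cohort's ground truth
#'
#' @param analyses Named list (by patient id) of [analyze_patient()]
#'   outputs for a generated cohort.
#' @param truth The `truth` element of [generate_cohort()].
#' @return A list: `region_table` (per region: truth vs called class),
#'   `region_metrics` (per-class precision and recall),
#'   `overall_accuracy`, and `phase_accuracy` (SNP-weighted, per-region
#'   label-switching resolved, over regions carrying true allelic
#'   imbalance).
#' @export
truth_compare <- function(analyses, truth) {
  rows <- list(); acc_num <- 0; acc_den <- 0
  for (pid in names(analyses)) {
    an <- analyses[[pid]]
    tr <- truth$regions[truth$regions$patient == pid, , drop = FALSE]
    cl <- an$classification
    idx <- match(paste(cl$chrom, cl$start, cl$end),
                 paste(tr$chrom, tr$start, tr$end))
    if (anyNA(idx))
      stop("region identifier mismatch between pipeline output and truth")
    rows[[pid]] <- data.frame(patient = pid, region_id = cl$region_id,
                              truth = tr$class[idx], called = cl$class,
                              stringsAsFactors = FALSE)
    # phase accuracy on regions with true allelic imbalance
    ts <- truth$snps[truth$snps$patient == pid &
                       truth$snps$type != "balanced", , drop = FALSE]
    if (!is.null(an$phase) && nrow(ts) > 0L) {
      ph <- an$phase
      key <- paste(ph$chrom, ph$pos)
      tkey <- paste(ts$chrom, ts$pos)
      m <- match(tkey, key)
      ts$called_phase <- ph$phase[m]
      ts <- ts[!is.na(ts$called_phase), , drop = FALSE]
      for (rg in unique(paste(ts$chrom, ts$region_start))) {
        sub <- ts[paste(ts$chrom, ts$region_start) == rg, , drop = FALSE]
        agree <- mean(sub$called_phase == sub$parent)
        acc_num <- acc_num + nrow(sub) * max(agree, 1 - agree)
        acc_den <- acc_den + nrow(sub)
      }
    }
  }
  region_table <- do.call(rbind, rows)
  rownames(region_table) <- NULL
  classes <- sort(unique(c(region_table$truth, region_table$called)))
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(region_table$truth == cl & region_table$called == cl)
    fp <- sum(region_table$truth != cl & region_table$called == cl)
    fn <- sum(region_table$truth == cl & region_table$called != cl)
    data.frame(class = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               n_truth = tp + fn, stringsAsFactors = FALSE)
  }))
  list(region_table = region_table, region_metrics = metrics,
       overall_accuracy = mean(region_table$truth == region_table$called),
       phase_accuracy = if (acc_den > 0) acc_num / acc_den else NA_real_)
}
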