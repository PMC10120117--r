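# YAML-driven orchestration over on-disk tables.

#' Run the full per-patient pipeline from a config
#'
#' Reads cohort-level tables, then for each patient: refines regions,
#' phases SNPs, tests every sample for allelic imbalance and MSAI,
#' classifies heterogeneity, applies de novo mutation filters and
#' patient-informed rescue, and writes one report set per patient plus a
#' cohort summary. Outputs are a pure function of the inputs and the seed;
#' rerunning a config reproduces the reports byte for byte.
#'
#' @param config A YAML file path or an equivalent named list with fields:
#'   \describe{
#'     \item{files}{`meta`, `segments`, `snps` (required); `mutations`,
#'       `readcounts` (optional) -- paths to the tables read by
#'       [read_sample_meta()], [read_segments()], [read_snp_table()],
#'       [read_mutations()].}
#'     \item{out_dir}{Report directory.}
#'     \item{seed}{Integer seed for simulation-backed decisions
#'       (default 1).}
#'     \item{thresholds}{Optional overrides for [ai_thresholds()] fields.}
#'     \item{min_ref_purity}{Purity above which a sample's segmentation is
#'       usable (default 0.05).}
#'     \item{rescue}{Optional `min_var_reads` / `min_vaf` overrides for
#'       [rescue_mutations()].}
#'     \item{segment_dialect}{Coordinate dialect of the segment table
#'       (default `"1-based"`).}
#'   }
#' @return Invisibly, the cohort summary data.frame (per patient: phased
#'   fraction, heterogeneous fraction, region class tallies, mutation
#'   counts). Patients with mutation data but no usable copy-number sample
#'   are processed for mutations only, with a warning.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$files), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  thr <- do.call(ai_thresholds, as.list(config$thresholds))
  min_ref_purity <- if (is.null(config$min_ref_purity)) 0.05
                    else config$min_ref_purity
  dialect <- if (is.null(config$segment_dialect)) "1-based"
             else config$segment_dialect
  rescue_args <- config$rescue
  min_var_reads <- if (is.null(rescue_args$min_var_reads)) 3L
                   else rescue_args$min_var_reads
  min_vaf <- if (is.null(rescue_args$min_vaf)) 0.015 else rescue_args$min_vaf

  meta <- read_sample_meta(config$files$meta)
  segments <- read_segments(config$files$segments, dialect = dialect)
  snps <- read_snp_table(config$files$snps)
  mutations <- if (!is.null(config$files$mutations))
    read_mutations(config$files$mutations) else NULL
  readcounts <- if (!is.null(config$files$readcounts))
    read.delim(config$files$readcounts, stringsAsFactors = FALSE) else NULL

  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  summaries <- list()
  mut_out <- list()
  for (pid in unique(meta$patient_id)) {
    pm <- meta[meta$patient_id == pid, , drop = FALSE]
    pseg <- segments[segments$sample_id %in% pm$sample_id, , drop = FALSE]
    psnp <- snps[snps$sample_id %in% pm$sample_id, , drop = FALSE]
    message("patient ", pid, ": ", nrow(pm), " samples, ",
            nrow(pseg), " segments, ", nrow(psnp), " SNP observations")
    an <- NULL
    usable <- pm$sample_id[!is.na(pm$purity) & pm$purity > min_ref_purity]
    if (any(pseg$sample_id %in% usable)) {
      an <- analyze_patient(pseg, psnp, pm, thresholds = thr,
                            min_ref_purity = min_ref_purity, seed = seed)
      write_results(an, config$out_dir, prefix = pid)
      message("patient ", pid, ": ", nrow(an$regions), " regions, phased ",
              sprintf("%.1f%%", 100 * an$phased_fraction),
              ", heterogeneous ",
              ifelse(is.na(an$heterogeneity_fraction), "n/a",
                     sprintf("%.1f%%", 100 * an$heterogeneity_fraction)))
    } else {
      warning("patient ", pid, ": no sample with purity > ", min_ref_purity,
              " has segment calls; copy-number analysis skipped",
              call. = FALSE)
    }

    pmut <- NULL
    if (!is.null(mutations)) {
      pmut <- mutations[mutations$patient_id == pid, , drop = FALSE]
      if (nrow(pmut) > 0L) {
        pmut <- apply_denovo_filters(pmut)
        superset <- collate_patient_mutations(pmut)
        if (nrow(superset) > 0L && !is.null(readcounts)) {
          for (s in unique(pmut$sample_id)) {
            counts <- readcounts[readcounts$sample == s, , drop = FALSE]
            names(counts)[names(counts) == "sample"] <- "sample_id"
            if (nrow(counts) == 0L) next
            resc <- rescue_mutations(counts, superset,
                                     min_var_reads = min_var_reads,
                                     min_vaf = min_vaf)
            pmut[pmut$sample_id == s, ] <- apply_rescue_status(
              pmut[pmut$sample_id == s, , drop = FALSE],
              resc[resc$rescued, , drop = FALSE])
          }
        }
        mut_out[[pid]] <- pmut
      }
    }

    tallies <- if (!is.null(an)) table(factor(
      an$classification$class,
      levels = c("no_scna_detected", "homogeneous", "heterogeneous",
                 "msai"))) else NULL
    summaries[[pid]] <- data.frame(
      patient_id = pid,
      n_regions = if (is.null(an)) NA_integer_ else nrow(an$regions),
      phased_fraction = if (is.null(an)) NA_real_ else an$phased_fraction,
      heterogeneity_fraction = if (is.null(an)) NA_real_
                               else an$heterogeneity_fraction,
      n_no_scna = if (is.null(an)) NA_integer_
                  else unname(tallies["no_scna_detected"]),
      n_homogeneous = if (is.null(an)) NA_integer_
                      else unname(tallies["homogeneous"]),
      n_heterogeneous = if (is.null(an)) NA_integer_
                        else unname(tallies["heterogeneous"]),
      n_msai = if (is.null(an)) NA_integer_ else unname(tallies["msai"]),
      n_mutations_pass = if (is.null(pmut)) NA_integer_
                         else sum(pmut$status == "pass_de_novo"),
      n_mutations_rescued = if (is.null(pmut)) NA_integer_
                            else sum(pmut$status == "rescued"),
      stringsAsFactors = FALSE)
  }

  if (length(mut_out) > 0L)
    write_tsv(do.call(rbind, mut_out),
              file.path(config$out_dir, "mutations_status.tsv"))
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  invisible(summary)
}
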