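# Readers/writers for the tab-separated tables the pipeline consumes and
# emits. Internal coordinates are 0-based half-open; ASCAT-style inputs are
# 1-based inclusive by default.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("malformed ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "))
}

#' Read an allele-specific segment table
#'
#' Consumes ASCAT-style allele-specific copy-number output: one row per
#' (sample, segment) with major/minor copy numbers and the segment BAF (the
#' median BAF across the segment as reported by the caller). Copy numbers
#' are normalised so that `cn_a >= cn_b` (allele A is the major allele in
#' the calling sample) and coordinates to 0-based half-open.
#'
#' @param path TSV with header columns
#'   `chrom, start, end, nMajor, nMinor, segmentBAF, sample`.
#' @param dialect Coordinate convention of the input: `"1-based"`
#'   (inclusive; ASCAT-style, the default) or `"0-based"` (half-open).
#' @return A data.frame of segment calls: `sample_id, chrom, start, end,
#'   cn_a, cn_b, segment_baf` with 0-based half-open coordinates.
#' @export
read_segments <- function(path, dialect = c("1-based", "0-based")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("chrom", "start", "end", "nMajor", "nMinor",
                         "segmentBAF", "sample"), "segment")
  start <- if (dialect == "1-based") df$start - 1L else df$start
  end <- df$end
  bad <- which(end <= start)
  if (length(bad))
    stop("segment with end <= start at line ", bad[1] + 1L, " of ", path)
  if (any(df$nMajor < 0 | df$nMinor < 0))
    stop("negative copy number in segment table")
  if (any(df$segmentBAF < 0 | df$segmentBAF > 1, na.rm = TRUE))
    stop("segmentBAF outside [0, 1] in segment table")
  data.frame(sample_id = as.character(df$sample),
             chrom = as.character(df$chrom),
             start = as.integer(start), end = as.integer(end),
             cn_a = as.integer(pmax(df$nMajor, df$nMinor)),
             cn_b = as.integer(pmin(df$nMajor, df$nMinor)),
             segment_baf = df$segmentBAF, stringsAsFactors = FALSE)
}

#' Write a segment table
#'
#' Inverse of [read_segments()]; emits the ASCAT-style column layout in the
#' requested coordinate dialect.
#'
#' @param segments Data frame as returned by [read_segments()].
#' @param path Output TSV path.
#' @inheritParams read_segments
#' @export
write_segments <- function(segments, path, dialect = c("1-based", "0-based")) {
  dialect <- match.arg(dialect)
  out <- data.frame(chrom = segments$chrom,
                    start = if (dialect == "1-based") segments$start + 1L
                            else segments$start,
                    end = segments$end,
                    nMajor = segments$cn_a, nMinor = segments$cn_b,
                    segmentBAF = segments$segment_baf,
                    sample = segments$sample_id)
  write_tsv(out, path)
}

#' Read a per-SNP read-count table
#'
#' One row per (sample, heterozygous SNP) with reference and alternate read
#' counts, as produced by genotyping germline-heterozygous sites in the
#' aligned reads. BAF is computed as `alt_count / depth` on the ALT allele
#' as reported -- never folded, since folding destroys the phase information
#' the method depends on. Depth-0 SNPs are retained but flagged unusable.
#'
#' @param path TSV with header columns `chrom, pos, sample, ref_count,
#'   alt_count` (`pos` 0-based).
#' @return A data.frame: `sample_id, chrom, pos, ref_count, alt_count,
#'   depth, baf, usable`.
#' @export
read_snp_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("chrom", "pos", "sample", "ref_count", "alt_count"),
                   "SNP")
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stop("negative read count in SNP table")
  depth <- df$ref_count + df$alt_count
  data.frame(sample_id = as.character(df$sample),
             chrom = as.character(df$chrom), pos = as.integer(df$pos),
             ref_count = as.integer(df$ref_count),
             alt_count = as.integer(df$alt_count),
             depth = as.integer(depth),
             baf = ifelse(depth > 0, df$alt_count / depth, NA_real_),
             usable = depth > 0, stringsAsFactors = FALSE)
}

#' Write a per-SNP read-count table
#' @param snps Data frame as returned by [read_snp_table()].
#' @param path Output TSV path.
#' @export
write_snp_table <- function(snps, path) {
  write_tsv(data.frame(chrom = snps$chrom, pos = snps$pos,
                       sample = snps$sample_id, ref_count = snps$ref_count,
                       alt_count = snps$alt_count), path)
}

#' Read a somatic mutation table
#'
#' One row per (sample, variant) with variant read counts, two-caller
#' provenance (`caller_a`: the consensus caller, e.g. MuTect; `caller_b`:
#' the caller reporting a somatic p-value, e.g. VarScan2), matched-germline
#' counts and a driver annotation.
#'
#' @param path TSV with header columns `chrom, pos, ref, alt, sample,
#'   patient, var_count, depth, caller_a, caller_b, somatic_p,
#'   germline_var_count, germline_depth, is_driver`.
#' @return A data.frame with those columns plus `vaf = var_count / depth`.
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("chrom", "pos", "ref", "alt", "sample", "patient",
                         "var_count", "depth", "caller_a", "caller_b",
                         "somatic_p", "germline_var_count", "germline_depth",
                         "is_driver"), "mutation")
  if (any(df$var_count < 0 | df$depth < 0))
    stop("negative read count in mutation table")
  names(df)[names(df) == "sample"] <- "sample_id"
  names(df)[names(df) == "patient"] <- "patient_id"
  df$caller_a <- as.logical(df$caller_a)
  df$caller_b <- as.logical(df$caller_b)
  df$is_driver <- as.logical(df$is_driver)
  df$vaf <- ifelse(df$depth > 0, df$var_count / df$depth, NA_real_)
  df
}

#' Read a sample metadata table
#'
#' @param path TSV with header columns `sample, patient, kind, purity`
#'   (kind one of primary/metastasis/pdx/cfdna/germline; purity in `[0,1]`
#'   or NA when unknown).
#' @return A data.frame: `sample_id, patient_id, kind, purity`.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("sample", "patient", "kind", "purity"), "metadata")
  kinds <- c("primary", "metastasis", "pdx", "cfdna", "germline")
  if (!all(df$kind %in% kinds))
    stop("unknown sample kind; expected one of ", paste(kinds, collapse = ", "))
  if (any(df$purity < 0 | df$purity > 1, na.rm = TRUE))
    stop("purity outside [0, 1] in metadata table")
  if (anyDuplicated(df[c("patient", "sample")]))
    stop("duplicate sample_id within patient in metadata table")
  data.frame(sample_id = as.character(df$sample),
             patient_id = as.character(df$patient),
             kind = as.character(df$kind), purity = as.numeric(df$purity),
             stringsAsFactors = FALSE)
}

# Deterministic TSV writer: fixed column order as given, full precision,
# no quoting -- reruns on identical input are byte-identical.
write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write region-level and classification results
#'
#' Emits one TSV per result class with deterministic column order and
#' unrounded p-values.
#'
#' @param results A list as returned by [analyze_patient()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, typically the patient id.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, prefix = "patient") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    regions = file.path(dir, paste0(prefix, "_regions.tsv")),
    results = file.path(dir, paste0(prefix, "_region_results.tsv")),
    classification = file.path(dir, paste0(prefix, "_classification.tsv")))
  write_tsv(results$regions, paths[["regions"]])
  write_tsv(results$results, paths[["results"]])
  write_tsv(results$classification, paths[["classification"]])
  invisible(paths)
}
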