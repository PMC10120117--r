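# Harmonising per-sample segmentations into patient-level regions.

.segments_to_granges <- function(segments) {
  GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end))
}

#' Minimum consistent genomic regions across samples
#'
#' Overlays the allele-specific segmentations of every usable sample of a
#' patient and refines them at the union of all breakpoints, yielding
#' disjoint regions each of which lies entirely within at most one segment
#' per sample. Within such a region every sample's copy-number state and
#' segment BAF are constant, so SNP-level evidence can be compared across
#' samples without mixing states.
#'
#' @param segments Segment calls (as from [read_segments()]) for the
#'   samples with usable tumour purity.
#' @param min_snps Regions to which fewer than this many SNPs are later
#'   assigned are flagged low-confidence (see [assign_snps()]); recorded
#'   here as an attribute for downstream use.
#' @return A data.frame of regions: `region_id, chrom, start, end, width`
#'   (0-based half-open), disjoint, jointly covering the union of the input
#'   segments.
#' @export
minimum_consistent_regions <- function(segments, min_snps = 10L) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("no phasing reference available: no usable segment calls")
  gr <- .segments_to_granges(segments)
  dj <- GenomicRanges::disjoin(gr)
  dj <- GenomicRanges::sort(dj)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(dj)),
    start = GenomicRanges::start(dj) - 1L,
    end = GenomicRanges::end(dj), stringsAsFactors = FALSE)
  out$width <- out$end - out$start
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  attr(out, "min_snps") <- as.integer(min_snps)
  out[c("region_id", "chrom", "start", "end", "width")]
}

#' Per-region, per-sample segment state
#'
#' Maps each region back to the segment call covering it in each sample.
#' Samples with no call over a region contribute no row there (and cannot
#' serve as phasing reference for it).
#'
#' @param regions Output of [minimum_consistent_regions()].
#' @param segments Segment calls for the same samples.
#' @return A data.frame: `region_id, sample_id, cn_a, cn_b, segment_baf`.
#' @export
region_segment_states <- function(regions, segments) {
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  sgr <- .segments_to_granges(segments)
  ov <- GenomicRanges::findOverlaps(rgr, sgr, type = "within")
  data.frame(
    region_id = regions$region_id[S4Vectors::queryHits(ov)],
    sample_id = segments$sample_id[S4Vectors::subjectHits(ov)],
    cn_a = segments$cn_a[S4Vectors::subjectHits(ov)],
    cn_b = segments$cn_b[S4Vectors::subjectHits(ov)],
    segment_baf = segments$segment_baf[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
}

#' Assign SNPs to regions
#'
#' Half-open containment: a SNP at position `pos` belongs to region
#' `[start, end)` iff `start <= pos < end`. Regions are disjoint, so each
#' SNP lands in at most one region; SNPs outside all regions are left
#' unassigned (`region_id` NA).
#'
#' @param regions Output of [minimum_consistent_regions()].
#' @param snps SNP observations (as from [read_snp_table()]).
#' @return `snps` with a `region_id` column added.
#' @export
assign_snps <- function(regions, snps) {
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  pgr <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(pgr, rgr, select = "first")
  snps$region_id <- regions$region_id[ov]
  snps
}
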