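#' Expected B-allele frequency under tumour/normal admixture
#'
#' For a sample of tumour purity `p` in which the tumour carries `cn_a`
#' copies of parental allele A and `cn_b` copies of parental allele B at a
#' locus, the expected BAF of a heterozygous SNP whose counted allele lies on
#' allele B is
#' \deqn{BAF_e = \frac{1 - p + p\,CN_b}{2 - 2p + p\,(CN_a + CN_b)}}
#' The normal (admixing) compartment is assumed diploid heterozygous, which
#' contributes one copy of each parental allele.
#'
#' @param p Tumour purity (fraction of DNA derived from tumour cells), in
#'   `[0, 1]`. Vectorised.
#' @param cn_a,cn_b Non-negative tumour copy numbers of parental alleles A
#'   and B. Vectorised.
#' @return Expected BAF in `[0, 1]`.
#' @examples
#' expected_baf(0, 2, 0)      # 0.5: a purity-0 sample is all normal
#' expected_baf(1, 1, 0)      # 0:   pure LOH, allele B lost
#' expected_baf(0.5, 2, 1)    # 0.4
#' @export
expected_baf <- function(p, cn_a, cn_b) {
  stopifnot(is.numeric(p), is.numeric(cn_a), is.numeric(cn_b))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("purity `p` must lie in [0, 1]")
  if (any(cn_a < 0 | cn_b < 0, na.rm = TRUE))
    stop("copy numbers must be non-negative")
  denom <- 2 - 2 * p + p * (cn_a + cn_b)
  if (any(denom <= 0, na.rm = TRUE))
    stop("degenerate copy-number state: 2 - 2p + p*(cn_a + cn_b) must be > 0")
  (1 - p + p * cn_b) / denom
}

#' Simulate per-SNP BAFs for one copy-number segment
#'
#' Generative model for the BAFs of `n_snps` heterozygous SNPs on a segment
#' with allele-specific copy number (`cn_a`, `cn_b`) in a sample of purity
#' `purity`: the number of SNPs whose counted allele lies on parental allele
#' B is drawn as `Binomial(n_snps, 0.5)`; each allele-B SNP then receives
#' `alt_count ~ Binomial(depth, BAF_e)` variant reads and each allele-A SNP
#' `alt_count ~ Binomial(depth, 1 - BAF_e)`, with `BAF_e` from
#' [expected_baf()]. The BAF is `alt_count / depth`.
#'
#' @param purity Tumour purity in `[0, 1]`.
#' @param cn_a,cn_b Tumour copy numbers of parental alleles A and B.
#' @param n_snps Number of SNPs to simulate.
#' @param depth Read depth per SNP; a scalar (the default model) or a vector
#'   of length `n_snps` for per-SNP depths.
#' @param seed Optional integer seed; when given, output is reproducible.
#' @return A data.frame with one row per SNP: `allele` (ground-truth phase,
#'   `"A"`/`"B"`), `alt_count`, `depth`, `baf`.
#' @examples
#' s <- simulate_segment(0.5, 2, 0, n_snps = 100, depth = 50, seed = 1)
#' table(s$allele)
#' @export
simulate_segment <- function(purity, cn_a, cn_b, n_snps, depth = 50L,
                             seed = NULL) {
  stopifnot(length(purity) == 1L, length(n_snps) == 1L, n_snps >= 1)
  if (!length(depth) %in% c(1L, n_snps))
    stop("`depth` must be a scalar or of length `n_snps`")
  if (any(depth < 1)) stop("`depth` must be positive")
  if (!is.null(seed)) set.seed(seed)
  baf_b <- expected_baf(purity, cn_a, cn_b)
  n_b <- rbinom(1L, n_snps, 0.5)
  allele <- c(rep("B", n_b), rep("A", n_snps - n_b))
  d <- rep_len(as.integer(depth), n_snps)
  prob <- ifelse(allele == "B", baf_b, 1 - baf_b)
  alt <- rbinom(n_snps, d, prob)
  data.frame(allele = allele, alt_count = alt, depth = d, baf = alt / d,
             stringsAsFactors = FALSE)
}

#' Mix tumour and germline read counts to emulate a lower-purity sample
#'
#' Count-level analogue of mixing tumour and germline sequencing reads: for
#' each SNP, `round(f * depth)` reads are drawn without replacement from the
#' tumour sample's allele counts (hypergeometric thinning) and the remainder
#' from the germline sample's counts. `f = 1` returns the tumour counts
#' unchanged and `f = 0` the germline counts (exactly so when per-SNP depths
#' match). A pure tumour mixed at fraction `f` has effective purity `f`.
#'
#' @param tumour,germline Data frames over the same SNPs (same order, and
#'   same `chrom`/`pos` when present) with columns `alt_count` and `depth`.
#' @param fraction Tumour fraction `f` of the mixture, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A data.frame like `tumour` with mixed `alt_count`, `depth`, `baf`.
#' @export
mix_with_germline <- function(tumour, germline, fraction, seed = NULL) {
  stopifnot(is.data.frame(tumour), is.data.frame(germline),
            length(fraction) == 1L, fraction >= 0, fraction <= 1)
  if (nrow(tumour) != nrow(germline))
    stop("tumour and germline tables must cover the same SNPs")
  for (col in intersect(c("chrom", "pos"), intersect(names(tumour), names(germline))))
    if (!identical(tumour[[col]], germline[[col]]))
      stop("tumour and germline tables must cover the same SNPs (", col,
           " mismatch)")
  if (!is.null(seed)) set.seed(seed)
  dt <- tumour$depth
  dg <- germline$depth
  k_t <- as.integer(round(fraction * dt))
  out_depth <- k_t + pmin(dg, dt - k_t)
  k_g <- out_depth - k_t
  alt_t <- integer(nrow(tumour))
  take <- k_t > 0L
  alt_t[take] <- rhyper(sum(take), m = tumour$alt_count[take],
                        n = dt[take] - tumour$alt_count[take], k = k_t[take])
  alt_g <- integer(nrow(germline))
  take <- k_g > 0L
  alt_g[take] <- rhyper(sum(take), m = germline$alt_count[take],
                        n = dg[take] - germline$alt_count[take], k = k_g[take])
  out <- tumour
  out$alt_count <- alt_t + alt_g
  out$depth <- out_depth
  if ("ref_count" %in% names(out)) out$ref_count <- out$depth - out$alt_count
  out$baf <- ifelse(out$depth > 0, out$alt_count / out$depth, NA_real_)
  out
}
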