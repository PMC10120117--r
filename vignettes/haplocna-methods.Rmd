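---
title: "Haplotype-phased detection of allelic imbalance in low-purity samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-phased detection of allelic imbalance in low-purity samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocna)
```

## The problem

Somatic copy-number alterations (SCNAs) shift the B-allele frequency (BAF)
of heterozygous SNPs away from 0.5. Allele-specific copy-number callers
exploit this, but they need appreciable tumour content — in practice they
fail below roughly 5% purity, which excludes most cell-free DNA (cfDNA)
samples. Yet a patient usually has at least one *high*-purity sample: a
tissue biopsy, or better, a patient-derived xenograft (PDX), whose
near-complete purity cleanly separates the two parental alleles.

`haplocna` borrows that separation. In a region of allelic imbalance the
high-purity sample tells us, SNP by SNP, which parental haplotype each
counted allele sits on. Once SNPs are phased, the *distributions* of BAFs
on the two haplotypes can be compared in any other sample of the patient —
including samples whose individual BAFs are visually indistinguishable
from noise. Aggregating thousands of SNPs per segment buys sensitivity far
below the per-sample calling limit, and, because the comparison is
allele-aware, it can also recognise when a *different* parental allele is
imbalanced in another sample (mirrored subclonal allelic imbalance, MSAI
— the signature of parallel evolution).

## The model

For a sample of purity $p$ whose tumour carries $CN_a$ copies of parental
allele A and $CN_b$ of allele B at a locus, a SNP whose counted allele lies
on B has expected BAF

$$\mathrm{BAF}_e \;=\; \frac{1 - p + p\,CN_b}{2 - 2p + p\,(CN_a + CN_b)},$$

the normal compartment contributing one copy of each allele
(`expected_baf()`). Read counts are binomial: a depth-$D$ SNP on allele B
draws $\mathrm{Binomial}(D, \mathrm{BAF}_e)$ variant reads, one on allele A
$\mathrm{Binomial}(D, 1-\mathrm{BAF}_e)$; of $N$ SNPs on a segment,
$N_B \sim \mathrm{Binomial}(N, 0.5)$ lie on allele B
(`simulate_segment()`). This is both the generative model of the
simulation engine and the implicit model under which the tests operate.

## The procedure

1. **Minimum consistent regions.** The allele-specific segmentations of all
   samples with purity above 5% (configurable) are refined at the union of
   their breakpoints (`minimum_consistent_regions()`, built on
   `GenomicRanges::disjoin`). Within a region, every sample's copy-number
   state is constant.
2. **Phasing.** Per region, the sample whose segment BAF deviates most from
   0.5 becomes the phasing reference (`select_reference_sample()`); its
   SNPs with BAF > 0.5 are labelled A (major allele), those with BAF < 0.5
   labelled B, and the labels carry to all samples
   (`phase_from_reference()`). If every sample's segment BAF equals 0.5,
   nothing is imbalanced and the region stays unphased.
3. **Detection.** In each sample, allelic imbalance is a two-sided rank-sum
   comparison of the A and B BAF groups at strict $p < 0.005$
   (`test_allelic_imbalance()`); MSAI additionally requires the A-labelled
   BAFs to be significantly *lower* than the B-labelled ones (one-sided,
   $p < 0.01$, `test_msai()`).
4. **Confident absence.** A non-detection only counts if the event would
   have been seen: 100 segments are simulated at the tested sample's purity
   and SNP count, depth 50, under the copy-number state of the sample in
   which the event *was* detected; the absence is confident only if all
   100 simulations detect it (`confident_absence()`).
5. **Classification.** Per region: MSAI anywhere ⇒ `msai`; otherwise
   detected in one sample and confidently absent in another ⇒
   `heterogeneous`; otherwise consistent major allele ⇒ `homogeneous`;
   unphased or undetected ⇒ `no_scna_detected` (`classify_segment()`).
   Samples neither detected nor confidently absent are excluded.

## Statistical choices

* **Rank-sum implementation.** Decisions at $p<0.005$ near small-sample
  boundaries must not hinge on approximation error, so the exact
  Mann–Whitney null (via `stats::pwilcox`) is used whenever both groups
  have ≤ 25 untied observations, and the normal approximation with tie and
  continuity correction otherwise. The implementation is validated against
  brute-force enumeration over all label assignments (all designs up to
  8 vs 8, exactly) and against `stats::wilcox.test` on the approximate
  path.
* **Strict thresholds, no multiplicity correction.** Thresholds are applied
  with strict inequality and fixed per test; no correction is made across
  regions or samples. This mirrors the procedure the thresholds were
  chosen for and keeps per-region semantics interpretable; users comparing
  many patients should keep the fixed-threshold design in mind.
* **Folded reference selection.** Segment BAFs may arrive folded (≥ 0.5)
  or unfolded depending on the caller; $|\mathrm{segmentBAF} - 0.5|$ is
  caller-agnostic and reduces to "largest segment BAF" for folded input.
  SNPs with reference BAF exactly 0.5 (or zero depth) stay unphased; the
  dichotomy is exclusive.
* **Tie-breaks.** Equal reference deviations are broken by sample id;
  equal phase-group medians default the major allele to A. Both are
  deterministic and logged in the outputs.
* **Heterogeneous without MSAI significance.** Regions whose confidently
  detected samples disagree on the major allele, without reaching the
  one-sided MSAI threshold, are classed heterogeneous rather than
  homogeneous: the major-allele consistency requirement for homogeneity is
  taken literally.

## Sensitivity analysis

`sensitivity_grid()` measures the detection rate over replicated
simulations per (purity, SNPs-per-segment) cell: a pure reference is
simulated to phase each segment, the test sample is simulated at the cell's
purity, and the phased test is applied. A purity-0 row provides the
empirical null. A cell is *rescuable* when its detection rate exceeds three
times that null with non-overlapping 95% Clopper–Pearson intervals
(`rescuable_cells()`), separating genuine signal from calibration noise.

Defaults follow the printed operating point of the method: depth 50, CN
1+0 (LOH), purity grid spanning 0–10%, SNP grid 50–50,000, and 2,000
replicates per cell, which resolves rates near the 0.005 threshold. The
0.1%-purity, 50,000-SNP cell sits within a factor of ~4 of the null; there
we raise the replicate count to 10,000, since the rescuability criterion
compares two small proportions whose Monte-Carlo error would otherwise
dominate. At these settings the minimum rescuable SNP count is 50 at 5%
purity and 50,000 at 0.1% purity, and the purity-0 false-positive rate
stays at the nominal level — the acceptance script
(`scripts/acceptance.R`) recomputes all of this from scratch.

`mix_with_germline()` offers a count-level analogue of BAM downsampling
experiments: hypergeometric thinning mixes tumour and germline read counts
so that a pure tumour diluted to fraction $f$ has effective purity $f$.

## Mutation rescue and purity estimation

De novo somatic calls are filtered with the published two-caller rules
(`apply_denovo_filters()`): depth ≥ 10; VAF > 2% with both callers or
≥ 5% with the p-value caller alone; somatic $p \le 0.01$; > 5 variant
reads (≥ 3 when both callers agree); germline < 3 variant reads and VAF
≤ 1%. Mutations passing anywhere in a patient form that patient's superset
(`collate_patient_mutations()`); low-purity samples are re-genotyped at
superset sites and a site is *rescued* at ≥ 3 variant reads and VAF
> 1.5% (`rescue_mutations()`). Those defaults are motivated by the
cross-patient threshold sweep (`threshold_sweep()`): genuine rescued
mutations are patient-specific, whereas artefacts recur across patients,
so each candidate filter pair is scored by how many mutations it calls
against the proportion also found in another patient's cfDNA (drivers
excluded, where genuine recurrence is expected). Sharing is counted
against other patients by default; a `within_patient` switch includes
same-patient samples for sensitivity analyses.

Tumour fraction of samples too impure for copy-number calling is estimated
from the mean VAF of *ubiquitous* mutations (detected in every evaluable
sample): an ordinary least-squares line of known purity on mean clonal VAF
over the calibration samples (`fit_purity_model()`), applied to the
low-purity samples and clipped to $[0,1]$ (`estimate_purity()`). OLS
without weights is deliberate — calibration cohorts are small and the
theoretical relation (VAF ≈ purity/2 for diploid heterozygous clonal
mutations) is almost linear through the origin.

## The synthetic cohort

`generate_cohort()` builds complete multi-sample patients with ground
truth. Defaults — chosen once as a realistic miniature of a
tissue-plus-liquid-biopsy study — are two patients, each with a PDX
(purity 0.95), a metastasis biopsy (0.60), an adequate cfDNA sample
(0.35), a low-purity cfDNA sample (0.08; mutation data only, no usable
segmentation, emulating the common cfDNA case), and a germline sample.
Five 100-Mb chromosomes carry planted homogeneous copy-neutral LOH (2+0),
MSAI (2+0 with the opposite allele lost in one cfDNA sample),
heterogeneous (2+0 absent from one sample), a homogeneous gain (2+1) and
balanced segments; one sample's segmentation is split mid-segment to
exercise region refinement. SNP depth is 50 (the depth at which the
classification simulations are defined) at ~1 SNP per 250 kb; mutations
are read at depth 100 (typical exome coverage), with clonal mutations in
every tumour sample at VAF ≈ purity/2, subclonal mutations confined to
tissue, and 1–2-read artefact sites recurring across patients' cfDNA for
the threshold sweep.

Two deliberate idealisations: segment BAFs are emitted as the *model*
folded expectation rather than a noisy data median, so the "all segment
BAFs equal 0.5 ⇒ unphased" rule is exact on balanced segments; and depth
is constant per table. Real data add segmentation error, GC and mappability
waves, overdispersed depth, genotyping error at presumed-heterozygous
sites, and subclonal copy-number mixtures. Passing the end-to-end tests
therefore demonstrates correctness of the statistical machinery under its
own model, not performance on real sequencing data.

```{r, eval = FALSE}
co <- generate_cohort(seed = 42, dir = "demo_cohort")
meta <- read_sample_meta(co$paths[["meta"]])
segments <- read_segments(co$paths[["segments"]])
snps <- read_snp_table(co$paths[["snps"]])
pm <- meta[meta$patient_id == "P1", ]
res <- analyze_patient(segments[segments$sample_id %in% pm$sample_id, ],
                       snps[snps$sample_id %in% pm$sample_id, ],
                       pm, seed = 7)
res$classification[, c("region_id", "class", "reference_sample")]
```

## Problem sizes and reproducibility

All simulation-backed decisions draw per-cell seeds derived
deterministically from one root seed, so any cell reproduces in isolation
and reruns are byte-identical. The test suite runs the full sensitivity
grid (2,000 replicates per cell, 10,000 for the deepest cell) and the
complete synthetic-cohort analyses; the vignette and README examples use
the same code paths at the same sizes.

## Known limitations

* Phase is BAF-derived only; no population-panel or read-backed phasing,
  so regions balanced in *every* sample are invisible by construction.
* Detection is binary (imbalance / mirrored imbalance); integer allele
  copy numbers are not re-estimated for low-purity samples.
* Fixed per-test thresholds mean family-wise error grows with the number
  of regions × samples tested.
* The purity model assumes clonal mutations sit in copy-number-neutral
  context; heavy aneuploidy at clonal loci biases the calibration.
* Confident absence inherits the simulation model's idealisations
  (constant depth, binomial reads).
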