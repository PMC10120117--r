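# haplocna

Haplotype-phased detection of somatic copy-number alterations (SCNAs) in
very low-purity tumour samples — above all, cell-free DNA.

## The problem

Allele-specific copy-number callers need roughly ≥ 5% tumour content; most
cfDNA samples fall far below that, so their SCNAs go unseen. But SCNAs put
heterozygous SNPs into allelic imbalance, and a paired *high*-purity sample
of the same patient (tissue biopsy, PDX, or a high-purity cfDNA draw)
reveals which parental haplotype each SNP's counted allele sits on: SNPs
with B-allele frequency (BAF) above 0.5 in the most imbalanced sample lie
on the major allele A, those below on allele B. Carrying those phase labels
into a low-purity sample turns a hopeless per-SNP problem into a powerful
two-sample one — compare the BAF *distributions* of the two phased groups.

For a sample of purity *p* with allele-specific copy numbers (CN_a, CN_b),
the expected BAF of an allele-B SNP is

    BAF_e = (1 − p + p·CN_b) / (2 − 2p + p·(CN_a + CN_b))

Per patient, the package refines all usable segmentations into minimum
consistent regions, phases each region from its most imbalanced sample,
and then, in every sample:

* **allelic imbalance (AI)** — two-sided rank-sum test on the phased BAF
  groups, strict p < 0.005 (exact null for small untied groups, tie- and
  continuity-corrected normal approximation otherwise);
* **mirrored subclonal allelic imbalance (MSAI)** — one-sided test that
  allele-A BAFs are *lower* than allele-B BAFs, p < 0.01: the opposite
  parental allele is imbalanced, evidence of parallel evolution;
* **confident absence** — 100 simulations at the sample's purity and SNP
  count (depth 50) decide whether a non-detection is meaningful;
* **classification** — each region becomes `msai`, `heterogeneous`,
  `homogeneous` or `no_scna_detected` across the patient's samples.

Around the core sit a binomial BAF simulation engine with sensitivity-grid
experiments, count-level tumour/germline mixing, patient-informed mutation
rescue with a cross-patient threshold sweep, tumour-fraction estimation
from mean clonal VAF, and a synthetic multi-sample cohort generator with
ground truth.

## Worked example

```r
library(haplocna)

co <- generate_cohort(seed = 42, dir = "demo")   # 2 synthetic patients
meta     <- read_sample_meta(co$paths[["meta"]])
segments <- read_segments(co$paths[["segments"]])
snps     <- read_snp_table(co$paths[["snps"]])

pm  <- meta[meta$patient_id == "P1", ]
res <- analyze_patient(segments[segments$sample_id %in% pm$sample_id, ],
                       snps[snps$sample_id %in% pm$sample_id, ],
                       pm, seed = 7)
res$classification[, c("region_id", "class", "reference_sample", "n_snps")]
#>             region_id            class reference_sample n_snps
#>          1:0-25000000      homogeneous           P1_pdx    100
#>   1:25000000-50000000      homogeneous           P1_pdx    100
#>  1:50000000-100000000 no_scna_detected             <NA>    200
#>          2:0-60000000             msai           P1_pdx    240
#>  2:60000000-100000000 no_scna_detected             <NA>    160
#>          3:0-40000000    heterogeneous           P1_pdx    160
#>  3:40000000-100000000 no_scna_detected             <NA>    240
#>         4:0-100000000      homogeneous           P1_pdx    400
#>         5:0-100000000 no_scna_detected             <NA>    400
res$phased_fraction          # 0.5  -- fraction of the genome phased
res$heterogeneity_fraction   # 0.4  -- of the imbalanced genome, length-
                             #         weighted heterogeneous + MSAI share
```

The planted events are recovered exactly: copy-neutral LOH shared by all
samples is `homogeneous`, the segment lost from one cfDNA sample is
`heterogeneous`, balanced segments stay `no_scna_detected`, and the region
where the *other* parental allele was lost in cfDNA is flagged `msai`.
Zooming into that region shows why:

```r
res$results[res$results$region_id == "2:0-60000000",
            c("sample_id", "p_ai", "ai_detected", "major_allele", "p_msai", "msai")]
#>    sample_id     p_ai ai_detected major_allele   p_msai  msai
#>    P1_cfdna1 5.38e-41        TRUE            B 2.69e-41  TRUE
#>    P1_cfdna2 1.14e-11        TRUE            A 1.00e+00 FALSE
#>  P1_germline 7.51e-01       FALSE         none 3.75e-01 FALSE
#>       P1_met 5.10e-41        TRUE            A 1.00e+00 FALSE
#>       P1_pdx 1.34e-41        TRUE            A 1.00e+00 FALSE
```

The cfDNA sample at 8% purity (`P1_cfdna2`) — far too impure for de novo
copy-number calling — still shows the imbalance at p ≈ 10⁻¹¹ through the
phased test, while `P1_cfdna1` carries the mirror image (major allele B)
and the germline sample stays flat.

A YAML-driven end-to-end run over on-disk tables, including mutation
filtering and rescue, is available via `run_pipeline()`; a thin CLI wrapper
lives at `inst/cli/haplocna.R`.

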