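Package: haplocna
Title: Haplotype-Phased Detection of Allelic Imbalance in Low-Purity Tumour Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic copy-number alterations in very low-purity tumour
    samples, such as cell-free DNA, by borrowing SNP phase from a paired
    high-purity sample of the same patient (for example a patient-derived
    xenograft or tissue biopsy). Per-sample allele-specific segmentations are
    harmonised into minimum consistent genomic regions, heterozygous SNPs are
    phased into parental alleles from the most allelically imbalanced sample,
    and rank-sum tests on the phased B-allele frequency distributions detect
    allelic imbalance and mirrored subclonal allelic imbalance in every other
    sample. Includes a binomial B-allele-frequency simulation engine with
    sensitivity-grid experiments, a simulation-backed classification of
    copy-number heterogeneity across samples, tumour-fraction estimation from
    mean clonal variant allele frequency, patient-informed mutation rescue
    with a cross-patient threshold sweep, and a synthetic multi-sample cohort
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
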