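Package: modscreen
Title: Screening Genetic and Transcriptomic Modifiers of Cancer Onset and
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate-SNP association screening for cancer age-of-onset and
    repeated-split survival screening of gene-expression modifiers of tumour
    progression. Implements a GWAS-catalog-restricted discovery/validation/
    replication cascade built on exact and approximate Mann-Whitney and
    Kruskal-Wallis rank tests with direction-consistency and Bonferroni
    control; SNP panel quality control (minor-allele frequency, call rate,
    chromosome and duplicate filters, Hardy-Weinberg exact test); local
    linkage-disequilibrium proxy expansion from phased haplotypes (r-squared,
    distance, MAF, HWE and call-rate criteria); Kaplan-Meier, Mantel-Haenszel
    log-rank and maximally-selected-rank-statistic cut-point estimation; and
    resampled 50:50 discovery/validation expression screens with hit calling.
    A synthetic-cohort generator plants known genotype-onset effects,
    expression hazard effects and haplotype block structure so that the whole
    pipeline can be exercised and power-tested without access to restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
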