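Package: rvburden
Title: Rare-Variant Collapsing Burden Analysis for Case/Control Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for gene-level rare-variant collapsing burden
    analysis in biobank-scale case/control exome cohorts. Classifies samples
    into congenital heart disease cases and controls from diagnostic codes
    (including an age-conditional inferred bicuspid-aortic-valve rule),
    applies per-genotype quality-control thresholds, selects ultra-rare
    potentially pathogenic qualifying variants by consequence impact,
    population allele frequency and deleteriousness score, prunes related
    samples and ancestry outliers, and scans genes with a two-sided Fisher
    exact test on carrier counts, reporting odds ratios with Wald and
    conditional-exact confidence intervals, Bonferroni adjustment, and
    QQ-plot/genomic-inflation calibration. Includes a seeded synthetic-cohort
    generator with optional spiked risk genes so the whole pipeline is
    testable without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
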