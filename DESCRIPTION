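Package: wgdma
Title: Whole-Genome Duplication, Aneuploidy and LOH Analysis for Yeast
    Mutation-Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for mutation-accumulation (MA) experiments in
    yeast crosses and hybrids: ploidy inference and whole-genome duplication
    (WGD) detection from flow-cytometry DNA-content distributions, chromosome
    copy-number and aneuploidy calling from windowed read depth, segmentation
    of loss-of-heterozygosity (LOH) tracts from parental allele frequencies,
    maximum growth-rate estimation from optical-density time series, and the
    summary statistics and nonparametric tests that turn per-line calls into
    per-cross rates. A seeded synthetic-cohort simulator generates fluorescence
    samples, depth tracks, marker tracks and growth curves with known ground
    truth so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
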