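Package: paneldx
Title: Targeted Gene-Panel Molecular Diagnostics: Variant Ranking and
    Read-Depth Deletion Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for molecular diagnosis from targeted gene-panel
    sequencing of heterogeneous Mendelian disease cohorts, modeled on
    neuromuscular-disorder panel practice. Builds capture targets from gene
    models (coding exons plus intronic flanks), applies strand-aware variant
    validity filters and an allele-fraction zygosity caller, scores and ranks
    candidate variants by mutation-category severity with
    conservation/protein-effect/splice modulation and compound-heterozygote
    aggregation under recessive segregation, matches candidates against a
    gene-to-disease-class-and-inheritance table, detects multi-exon deletions
    from fixed-width window read counts compared against reference samples
    with off-target-read breakpoint refinement and chrX-based sex inference,
    and simulates complete synthetic patients (panel, variants, pileup
    evidence, annotations, coverage, truth manifest) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
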