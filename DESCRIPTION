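Package: phasekit
Title: Quality Control and Haplotype Comparison for Phased Diploid Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accounting statistics and comparison procedures for phased
    (haplotype-resolved) diploid genome assemblies: gap and telomere scanning,
    telomere-to-telomere status, NX curves, consensus-quality conversion and
    anchoring rates; read-depth based detection of collapsed regions with
    collapse-corrected chromosome lengths and ZW sex-chromosome candidate
    ranking; classification of structural variants (inversions, translocations,
    duplications, insertions, deletions) from haplotype-to-haplotype alignment
    blocks; coexpression-module mining of enzyme-family candidate genes against
    a known biosynthesis pathway; sex-biased expression scans in nonhomologous
    regions; and geometric filtering of docked ligand poses. A synthetic-data
    generator plants ground truth (structural variants, collapsed intervals,
    a length-asymmetric chromosome pair, a coexpression module) so that every
    stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    cluster,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
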