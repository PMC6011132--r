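Package: ssrkit
Title: Microsatellite Marker Discovery and Evaluation from Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for developing simple sequence repeat (SSR) markers from
    transcriptome assemblies and evaluating them in diploid populations.
    Mines maximal perfect microsatellites from FASTA sequences under
    per-motif-length minimum-repeat thresholds, groups motifs into canonical
    classes (rotation plus reverse complement), tabulates repeat-type and
    motif-class frequency matrices, screens primer candidates flanking a
    repeat under product-size, length, GC and melting-temperature
    constraints, and computes per-locus marker statistics (allele number,
    observed and unbiased expected heterozygosity, polymorphic information
    content), Hardy-Weinberg exact tests on the Levene conditional
    distribution, and genotypic linkage-disequilibrium permutation tests
    from GENEPOP genotype files.  Includes seeded simulators for transcript
    sets with implanted repeats and for diploid genotype samples with
    controlled allele frequencies and inbreeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
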