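#' Published SSR motif-class counts for the nipa palm hispid beetle
#'
#' Loci counts per canonical motif class and repeat-unit bin from a
#' published transcriptome SSR survey of *Octodonta nipae* (1274 loci from
#' 49,919 unigenes, mined with minimum repeat numbers 12/6/5/5/4/4 for
#' mono- through hexanucleotide motifs).  Counts in the open-ended top bin
#' (12 or more units; all mononucleotide loci fall there) are recorded with
#' `repeats = 12`.  Useful as a reference input for the tabulation
#' functions: `expand_locus_counts()` turns it into a locus multiset.
#'
#' @return Tibble with columns `motif` (representative motif: the left part
#'   of the class label), `repeats` (repeat-unit bin value) and `n` (locus
#'   count).
#' @examples
#' freq <- tabulate_frequencies(expand_locus_counts(onipae_ssr_counts()))
#' freq$grand_total  # 1274
#' @export
onipae_ssr_counts <- function() {
  tbl <- list(
    # motif, then counts per repeat-unit bin
    list("A",      c(`12` = 525)),
    list("C",      c(`12` = 30)),
    list("AC",     c(`6` = 28, `7` = 17, `8` = 14, `9` = 5, `10` = 4, `11` = 2)),
    list("AG",     c(`6` = 28, `7` = 9, `8` = 10, `9` = 4, `10` = 4, `11` = 6)),
    list("AT",     c(`6` = 103, `7` = 45, `8` = 19, `9` = 9, `10` = 12, `11` = 14)),
    list("AAC",    c(`5` = 33, `6` = 9, `7` = 1, `8` = 1)),
    list("AAG",    c(`5` = 63, `6` = 23, `7` = 6, `8` = 5)),
    list("AAT",    c(`5` = 70, `6` = 17, `7` = 2, `8` = 3)),
    list("ACC",    c(`5` = 28, `6` = 9, `7` = 3)),
    list("ACG",    c(`5` = 2, `6` = 1, `7` = 1)),
    list("ACT",    c(`5` = 8, `6` = 2, `7` = 1, `8` = 2)),
    list("AGC",    c(`5` = 14, `6` = 5, `7` = 1)),
    list("AGG",    c(`5` = 11, `6` = 1)),
    list("ATC",    c(`5` = 24, `6` = 7)),
    list("CCG",    c(`5` = 2, `6` = 4)),
    list("AAAC",   c(`5` = 1)),
    list("AAAG",   c(`5` = 1)),
    list("AAAT",   c(`5` = 6)),
    list("AACC",   c(`5` = 3)),
    list("AAGT",   c(`5` = 1, `6` = 1)),
    list("AATC",   c(`5` = 1)),
    list("ACTG",   c(`6` = 2)),
    list("AGAT",   c(`5` = 1)),
    list("AAAAT",  c(`4` = 3)),
    list("AAACT",  c(`4` = 1)),
    list("AACCT",  c(`4` = 1)),
    list("AATGT",  c(`4` = 1)),
    list("AAATTC", c(`4` = 2)),
    list("AATGGG", c(`4` = 1)),
    list("AGCGGC", c(`4` = 1))
  )
  purrr::map_dfr(tbl, function(row) {
    tibble::tibble(motif = row[[1]],
                   repeats = as.integer(names(row[[2]])),
                   n = as.integer(unname(row[[2]])))
  })
}

#' Published marker-panel statistics for the nipa palm hispid beetle
#'
#' Per-locus statistics of the nine polymorphic microsatellite markers
#' (On1-On9) genotyped in 12 individuals from each of two Fujian
#' populations of *Octodonta nipae* (Zhangzhou and Fuzhou), as printed in
#' the source survey: number of alleles (`na`), expected and observed
#' heterozygosity (`he`, `ho`), polymorphic information content (`pic`)
#' and the Hardy-Weinberg exact-test p-value (`hwe_p`; `NA` where the
#' survey prints a dash).  Note the printed PIC of 0.001 for the two
#' monomorphic Fuzhou loci (On4, On6), where the formula gives exactly 0 —
#' kept as printed.
#'
#' @return Tibble with columns `locus`, `motif`, `population`, `n`, `na`,
#'   `he`, `ho`, `pic`, `hwe_p`.
#' @export
onipae_marker_panel <- function() {
  zz <- tibble::tribble(
    ~locus, ~motif, ~na, ~he,   ~ho,   ~pic,  ~hwe_p,
    "On1",  "TA",   2L,  0.083, 0.083, 0.077, NA_real_,
    "On2",  "GT",   3L,  0.681, 0.667, 0.579, 0.398,
    "On3",  "CA",   3L,  0.678, 0.750, 0.584, 0.015,
    "On4",  "AT",   2L,  0.159, 0.167, 0.141, 1.000,
    "On5",  "GT",   3L,  0.562, 0.583, 0.432, 1.000,
    "On6",  "AT",   2L,  0.159, 0.167, 0.141, 1.000,
    "On7",  "CT",   3L,  0.663, 0.417, 0.561, 0.065,
    "On8",  "AAG",  3L,  0.344, 0.417, 0.275, 0.001,
    "On9",  "CAA",  2L,  0.663, 0.167, 0.561, 1.000
  )
  fz <- tibble::tribble(
    ~locus, ~motif, ~na, ~he,   ~ho,   ~pic,  ~hwe_p,
    "On1",  "TA",   2L,  0.344, 0.250, 0.275, 0.404,
    "On2",  "GT",   3L,  0.591, 0.250, 0.501, 0.002,
    "On3",  "CA",   3L,  0.359, 0.417, 0.307, 1.000,
    "On4",  "AT",   2L,  0.000, 0.000, 0.001, NA_real_,
    "On5",  "GT",   3L,  0.522, 0.333, 0.375, 0.282,
    "On6",  "AT",   2L,  0.000, 0.000, 0.001, NA_real_,
    "On7",  "CT",   3L,  0.453, 0.417, 0.369, 1.000,
    "On8",  "AAG",  3L,  0.431, 0.583, 0.328, 1.000,
    "On9",  "CAA",  2L,  0.163, 0.167, 0.150, 0.487
  )
  dplyr::bind_rows(
    dplyr::mutate(zz, population = "Zhangzhou", .after = "motif"),
    dplyr::mutate(fz, population = "Fuzhou", .after = "motif")
  ) |>
    dplyr::mutate(n = 12L, .after = "population")
}
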