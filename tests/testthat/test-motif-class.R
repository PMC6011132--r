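test_that("canonical labels match the conventional published forms", {
  expect_equal(canonical_motif_class("CTT")$label, "AAG/CTT")
  expect_equal(canonical_motif_class("GAC")$label, "ACG/CGT")
  expect_equal(canonical_motif_class("TA")$label, "AT/TA")
  expect_equal(canonical_motif_class("T")$label, "A/T")
  expect_equal(canonical_motif_class("G")$label, "C/G")
  expect_error(canonical_motif_class("ATAT"), "primitive")
  expect_error(canonical_motif_class("AXT"), "A/C/G/T")
})

test_that("class key is invariant under rotation and reverse complement", {
  bases <- c("A", "C", "G", "T")
  words <- unlist(lapply(1:6, function(k) {
    apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = "")
  }))
  primitive <- words[vapply(words, ssrkit:::is_primitive, logical(1))]
  keys <- vapply(primitive, \(m) canonical_motif_class(m)$key, character(1))
  labels <- vapply(primitive, \(m) canonical_motif_class(m)$label,
                   character(1))
  for (m in sample(primitive, 300)) {
    for (r in ssrkit:::rotations(m)) {
      expect_identical(keys[[r]], keys[[m]])
      expect_identical(labels[[r]], labels[[m]])
    }
    rc <- ssrkit:::revcomp(m)
    expect_identical(keys[[rc]], keys[[m]])
  }
  # the class inventory has the known sizes for di- and trinucleotides
  expect_equal(length(unique(keys[nchar(primitive) == 2])), 4L)
  expect_equal(length(unique(keys[nchar(primitive) == 3])), 10L)
})

test_that("frequency tabulation reproduces the reference survey margins", {
  loci <- expand_locus_counts(onipae_ssr_counts())
  freq <- tabulate_frequencies(loci)
  expect_equal(freq$grand_total, 1274L)
  by_type <- freq$by_repeat_type
  expect_equal(by_type$total, c(555L, 333L, 359L, 17L, 6L, 4L))
  expect_equal(by_type$percentage,
               c(43.56, 26.14, 28.18, 1.33, 0.47, 0.31))
  by_class <- freq$by_motif_class
  at <- by_class[by_class$motif_class == "A/T", ]
  expect_equal(at$total, 525L)
  expect_equal(at$percentage, 41.21)
  atta <- by_class[by_class$motif_class == "AT/TA", ]
  expect_equal(atta$total, 202L)
  expect_equal(atta$percentage, 15.86)
  # dinucleotide row binning matches the class-level counts
  expect_equal(unlist(by_type[2, paste0("rep_", 6:11)], use.names = FALSE),
               c(159L, 71L, 43L, 18L, 20L, 22L))
})

test_that("class-matrix row totals partition the repeat-type totals", {
  set.seed(31)
  loci <- dplyr::bind_rows(
    find_perfect_ssrs(random_repeat_rich_seq(200), "a",
                      ssr_thresholds(c(8, 4, 3, 3, 2, 2))),
    find_perfect_ssrs(random_repeat_rich_seq(200), "b",
                      ssr_thresholds(c(8, 4, 3, 3, 2, 2))))
  freq <- tabulate_frequencies(loci)
  by_len <- freq$by_motif_class |>
    dplyr::group_by(motif_length) |>
    dplyr::summarise(total = sum(total))
  for (k in by_len$motif_length) {
    expect_equal(by_len$total[by_len$motif_length == k],
                 freq$by_repeat_type$total[k])
  }
  expect_equal(sum(freq$by_repeat_type$total), freq$grand_total)
})

test_that("empty input yields an all-zero matrix", {
  freq <- tabulate_frequencies(find_perfect_ssrs("ACGT"))
  expect_equal(freq$grand_total, 0L)
  expect_equal(freq$by_repeat_type$total, rep(0L, 6))
  expect_equal(freq$by_repeat_type$percentage, rep(0, 6))
})

test_that("high-repeat locus counting sums the upper bins", {
  freq <- tabulate_frequencies(expand_locus_counts(onipae_ssr_counts()))
  expect_equal(count_high_repeat_loci(freq, 2, 8), 103L)
  expect_equal(count_high_repeat_loci(freq, 3, 8), 11L)
  expect_equal(count_high_repeat_loci(freq, 2, 13), 0L)
  expect_error(count_high_repeat_loci(freq, 2, 3), "smallest")
})
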