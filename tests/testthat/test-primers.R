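# fixed template: SSR in the middle of unique A/T-balanced flanks
primer_fixture <- function(seed = 123, flank = 220L) {
  withr::with_seed(seed, {
    repeat {
      bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
      s <- paste0(bg(flank), strrep("AG", 8), bg(flank))
      loci <- find_perfect_ssrs(s)
      if (nrow(loci) == 1L && loci$motif == "AG") {
        return(list(seq = s, locus = loci))
      }
    }
  })
}

test_that("melting temperature matches an independent nearest-neighbor\n  implementation at fixed conditions", {
  # constants computed with a second implementation of the same unified
  # parameter table (50 mM Na+, 25 nM per strand, entropic salt correction)
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT"), 53.09667,
               tolerance = 1e-6)
  expect_equal(melting_temperature("AATTAATTAATTAATTAATT"), 30.71069,
               tolerance = 1e-6)
  expect_equal(melting_temperature("GGGGCCCCGGGGCCCCGG"), 69.17970,
               tolerance = 1e-6)
  expect_equal(melting_temperature("ACGATCGATCGTAGCTAGCT"), 52.47665,
               tolerance = 1e-6)
  expect_error(melting_temperature("ACGTNACGT"), "A/C/G/T")
  expect_error(melting_temperature("ACGT"), "shorter")
})

test_that("Tm is reverse-complement invariant and GC-appending increases it", {
  set.seed(14)
  for (i in 1:50) {
    p <- paste(sample(c("A", "C", "G", "T"), sample(12:28, 1), TRUE),
               collapse = "")
    expect_equal(melting_temperature(p),
                 melting_temperature(ssrkit:::revcomp(p)),
                 tolerance = 1e-9)
    expect_gte(melting_temperature(paste0(p, "GC")),
               melting_temperature(p))
  }
})

test_that("every returned candidate satisfies every hard constraint", {
  fx <- primer_fixture()
  cn <- primer_constraints()
  cand <- screen_primer_pairs(fx$seq, fx$locus, cn, top_k = 25)
  expect_gt(nrow(cand), 0)
  expect_true(all(nchar(cand$forward_seq) >= cn$primer_min))
  expect_true(all(nchar(cand$forward_seq) <= cn$primer_max))
  expect_true(all(nchar(cand$reverse_seq) >= cn$primer_min))
  expect_true(all(nchar(cand$reverse_seq) <= cn$primer_max))
  expect_true(all(cand$product_size >= cn$product_min))
  expect_true(all(cand$product_size <= cn$product_max))
  expect_true(all(cand$gc_forward >= cn$gc_min & cand$gc_forward <= cn$gc_max))
  expect_true(all(cand$tm_forward >= cn$tm_min & cand$tm_forward <= cn$tm_max))
  expect_true(all(abs(cand$tm_forward - cand$tm_reverse) <= cn$max_tm_diff))
  # product spans the repeat completely
  expect_true(all(cand$forward_start + nchar(cand$forward_seq) - 1 <
                    fx$locus$start))
  expect_true(all(cand$reverse_end - nchar(cand$reverse_seq) + 1 >
                    fx$locus$end))
  expect_equal(cand$product_size, cand$reverse_end - cand$forward_start + 1L)
  # penalties ranked ascending
  expect_true(!is.unsorted(cand$penalty))
})

test_that("length bounds and product bounds exclude candidates", {
  fx <- primer_fixture()
  short <- primer_constraints(primer_min = 24, primer_max = 26,
                              primer_opt = 25)
  cand <- screen_primer_pairs(fx$seq, fx$locus, short, top_k = 10)
  expect_true(all(nchar(cand$forward_seq) >= 24))

  narrow <- primer_constraints(product_min = 100, product_max = 110)
  cand2 <- screen_primer_pairs(fx$seq, fx$locus, narrow, top_k = 10)
  expect_true(all(cand2$product_size <= 110))
})

test_that("the penalty prefers optimum-length primers, ties broken stably", {
  fx <- primer_fixture()
  # with the Tm and GC terms weighted out, penalty is the pure length term,
  # so the top pair must sit closest to the 23/23 optimum
  lengths_only <- primer_constraints(w_tm = 0, w_gc = 0)
  cand <- screen_primer_pairs(fx$seq, fx$locus, lengths_only, top_k = 50)
  opt_gap <- abs(nchar(cand$forward_seq) - 23) +
    abs(nchar(cand$reverse_seq) - 23)
  expect_equal(cand$penalty, opt_gap)
  expect_equal(opt_gap[1], min(opt_gap))
  # ties broken by leftmost forward start, then smallest product
  ties <- which(cand$penalty == cand$penalty[1])
  expect_true(!is.unsorted(cand$forward_start[ties]))
  # determinism of the full ranking
  cand2 <- screen_primer_pairs(fx$seq, fx$locus, lengths_only, top_k = 50)
  expect_identical(cand, cand2)
})

test_that("mononucleotide loci and impossible flanks return structured\n  empties", {
  mono <- find_perfect_ssrs(paste0(strrep("G", 4), strrep("A", 14),
                                   strrep("C", 4)))
  out <- screen_primer_pairs(paste0(strrep("G", 4), strrep("A", 14),
                                    strrep("C", 4)), mono, top_k = 3)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "reason"), "mononucleotide_excluded")

  tiny <- paste0("GCGC", strrep("AT", 8), "GCGC")
  loc <- find_perfect_ssrs(tiny)
  out2 <- screen_primer_pairs(tiny, loc, top_k = 3)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "reason"), "no_candidates")

  expect_error(screen_primer_pairs("ACGT", tibble::tibble(
    motif = "AT", start = 10L, end = 20L), top_k = 1), "outside")
})
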