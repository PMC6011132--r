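test_that("implanted transcripts are recovered exactly by the miner", {
  implants <- tibble::tibble(motif = c("AT", "CTT"), repeats = c(8L, 6L),
                             count = c(6L, 4L))
  sim <- simulate_transcripts_with_ssrs(12, c(300L, 500L), implants,
                                        seed = 101)
  expect_equal(nrow(sim$records), 12L)
  expect_equal(nrow(sim$truth), 10L)
  tf <- tempfile(fileext = ".fa")
  write_fasta(sim$records, tf)
  mined <- mine_fasta(tf)$loci
  # 100% recall and 100% precision against the truth table
  expect_equal(mined[, c("seq_id", "motif", "repeats", "start", "end")],
               sim$truth[, c("seq_id", "motif", "repeats", "start", "end")])
})

test_that("zero implants yield repeat-free background", {
  sim <- simulate_transcripts_with_ssrs(8, c(200L, 300L), seed = 5)
  expect_equal(nrow(sim$truth), 0L)
  for (i in seq_len(8)) {
    expect_equal(nrow(find_perfect_ssrs(sim$records$seq[[i]])), 0L)
  }
})

test_that("transcript simulation is deterministic under a fixed seed", {
  implants <- tibble::tibble(motif = "AC", repeats = 7L, count = 2L)
  s1 <- simulate_transcripts_with_ssrs(4, c(250L, 350L), implants, seed = 77)
  s2 <- simulate_transcripts_with_ssrs(4, c(250L, 350L), implants, seed = 77)
  expect_identical(s1, s2)
  expect_error(simulate_transcripts_with_ssrs(2, c(100, 200),
                                              tibble::tibble(motif = "AT",
                                                             repeats = 6,
                                                             count = 3),
                                              seed = 1),
               "more implants")
})

test_that("genotype simulation respects the autozygosity mixture model", {
  # F = 1: every call homozygous
  g1 <- simulate_genotypes(list(L = c(0.5, 0.5)), n = 200, inbreeding = 1,
                           seed = 31)
  expect_true(all(g1$a1 == g1$a2))

  # F = 0, p = q = 0.5: Ho within 3 SE of 0.5
  g0 <- simulate_genotypes(list(L = c(0.5, 0.5)), n = 10000, seed = 32)
  ho0 <- mean(g0$a1 != g0$a2)
  expect_lt(abs(ho0 - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))

  # F = 0.5: expected Ho = (1 - F) 2pq = 0.25
  gh <- simulate_genotypes(list(L = c(0.5, 0.5)), n = 10000,
                           inbreeding = 0.5, seed = 33)
  hoh <- mean(gh$a1 != gh$a2)
  expect_lt(abs(hoh - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("expected heterozygosity follows (1 - F)(1 - sum p^2)", {
  p <- c(0.6, 0.3, 0.1)
  for (f in c(0, 0.4, 0.9)) {
    g <- simulate_genotypes(list(L = p), n = 10000, inbreeding = f,
                            seed = 100 + round(10 * f))
    target <- (1 - f) * (1 - sum(p^2))
    expect_lt(abs(mean(g$a1 != g$a2) - target),
              3 * sqrt(target * (1 - target) / 10000) + 1e-6)
  }
})

test_that("missing-rate masking and input validation work", {
  g <- simulate_genotypes(list(L = c(0.5, 0.5)), n = 5000,
                          missing_rate = 0.2, seed = 44)
  miss <- mean(is.na(g$a1))
  expect_lt(abs(miss - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  expect_true(all(is.na(g$a1) == is.na(g$a2)))
  expect_error(simulate_genotypes(list(L = c(0.5, 0.4)), n = 5, seed = 1),
               "sum to 1")
  expect_error(simulate_genotypes(list(L = c(0.5, 0.5)), n = 5),
               "seed")
})

test_that("allele codes are assigned in descending frequency order", {
  g <- simulate_genotypes(list(L = c(0.1, 0.9)), n = 3000, seed = 55)
  af <- allele_frequencies(g, "L")
  expect_equal(af$allele, c(1L, 2L))
  expect_gt(af$freq[1], af$freq[2])
})
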