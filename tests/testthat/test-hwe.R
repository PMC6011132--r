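test_that("hand-enumerated two-configuration example gives p = 1/9", {
  # alleles 8 x A, 2 x B in 5 diploids: only {AA:4, BB:1} (P = 1/9) and
  # {AA:3, AB:2} (P = 8/9) are possible
  res <- hwe_test_counts(a1 = c(1, 1, 1, 1, 2), a2 = c(1, 1, 1, 1, 2))
  expect_equal(res$method, "enumeration")
  expect_equal(res$n_configurations, 2L)
  expect_equal(res$p_probability, 1 / 9, tolerance = 1e-12)
  expect_equal(res$p_deficit, 1 / 9, tolerance = 1e-12)
  expect_equal(res$p_excess, 1, tolerance = 1e-12)
})

test_that("a singleton allele admits a single configuration with p = 1", {
  res <- hwe_test_counts(a1 = rep(1L, 12), a2 = c(rep(1L, 11), 2L))
  expect_equal(res$n_configurations, 1L)
  expect_equal(res$p_probability, 1)
})

test_that("monomorphic loci are reported as not applicable", {
  g <- make_genotypes("1/1" = 12)
  res <- hwe_exact_test(g, "L1")
  expect_equal(res$method, "not_applicable")
  expect_true(is.na(res$p_probability))
})

test_that("enumeration probabilities sum to 1 for all n <= 12, NA <= 3", {
  for (n in 2:12) {
    for (m in allele_count_partitions(2L * n, 3L)) {
      if (length(m) < 2L) next
      dist <- ssrkit:::enumerate_levene(m)
      expect_equal(sum(exp(dist$logp)), 1, tolerance = 1e-9)
    }
  }
})

test_that("Monte-Carlo sampling agrees with enumeration within 3 SE", {
  res <- hwe_test_counts(a1 = c(1, 1, 1, 1, 2), a2 = c(1, 1, 1, 1, 2),
                         method = "monte_carlo", n_samples = 20000,
                         seed = 9)
  expect_equal(res$method, "monte_carlo")
  se <- sqrt((1 / 9) * (8 / 9) / 20000)
  expect_lt(abs(res$p_probability - 1 / 9), 3 * se)
  # and the seeded sampler is reproducible
  res2 <- hwe_test_counts(a1 = c(1, 1, 1, 1, 2), a2 = c(1, 1, 1, 1, 2),
                          method = "monte_carlo", n_samples = 20000,
                          seed = 9)
  expect_identical(res$p_probability, res2$p_probability)
})

test_that("one-sided p-values obey the provable ordering relations", {
  set.seed(12)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    g <- simulate_genotypes(list(L = {
      f <- stats::runif(k) + 0.2
      f / sum(f)
    }), n = 12, seed = 1000 + i)
    res <- hwe_exact_test(g, "L")
    if (res$method != "enumeration") next
    dist <- ssrkit:::levene_distribution(
      table(c(g$a1, g$a2)))
    pmin_cfg <- min(exp(dist$logp))
    expect_gte(res$p_deficit, pmin_cfg - 1e-12)
    expect_gte(res$p_excess, pmin_cfg - 1e-12)
    # the two tails share the observed heterozygote class
    expect_gte(res$p_deficit + res$p_excess, 1 - 1e-12)
    expect_true(all(c(res$p_probability, res$p_deficit, res$p_excess) <= 1))
  }
})

test_that("the exact test is conservative under HWE at n = 12", {
  freqs <- c(rep(list(c(0.5, 0.5)), 250), rep(list(c(0.7, 0.3)), 250),
             rep(list(c(0.5, 0.3, 0.2)), 250),
             rep(list(c(0.8, 0.2)), 250))
  names(freqs) <- sprintf("L%04d", seq_along(freqs))
  g <- simulate_genotypes(freqs, n = 12, seed = 515)
  res <- hwe_test_all(g)
  p <- res$p_probability[res$method == "enumeration"]
  expect_gt(length(p), 900)
  expect_lte(mean(p <= 0.05), 0.05)
})

test_that("power against inbreeding exceeds the null rejection rate", {
  n_loci <- 150
  freqs <- stats::setNames(rep(list(c(0.5, 0.5)), n_loci),
                           sprintf("L%03d", seq_len(n_loci)))
  g_null <- simulate_genotypes(freqs, n = 50, inbreeding = 0, seed = 61)
  g_inbred <- simulate_genotypes(freqs, n = 50, inbreeding = 0.8, seed = 62)
  rate <- function(g) {
    res <- hwe_test_all(g)
    mean(res$p_probability <= 0.05, na.rm = TRUE)
  }
  expect_gt(rate(g_inbred), rate(g_null))
  expect_gt(rate(g_inbred), 0.5)
})
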