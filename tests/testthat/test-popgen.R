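test_that("allele_frequencies counts copies after dropping missing calls", {
  g <- make_genotypes("1/1" = 11, "1/2" = 1)
  af <- allele_frequencies(g, "L1")
  expect_equal(af$allele, c(1L, 2L))
  expect_equal(af$count, c(23L, 1L))
  expect_equal(af$n, c(12L, 12L))

  half <- make_genotypes("1/1" = 6, "2/2" = 6)
  expect_equal(allele_frequencies(half, "L1")$freq, c(0.5, 0.5))

  mono <- make_genotypes("1/1" = 12)
  expect_equal(allele_frequencies(mono, "L1")$freq, 1)

  miss <- make_genotypes("1/2" = 2)
  miss$a1[1] <- NA
  miss$a2[1] <- NA
  expect_equal(allele_frequencies(miss, "L1")$n, c(1L, 1L))
  miss$a1 <- NA_integer_
  expect_error(allele_frequencies(miss, "L1"), "no data")
})

test_that("summarize_locus reproduces reference single-locus statistics", {
  r3 <- function(x) round_half_up(x, 3)
  s1 <- summarize_locus(make_genotypes("1/1" = 11, "1/2" = 1), "L1")
  expect_equal(s1$na, 2L)
  expect_equal(r3(c(s1$ho, s1$he, s1$pic)), c(0.083, 0.083, 0.077))

  s2 <- summarize_locus(make_genotypes("1/1" = 10, "1/2" = 2), "L1")
  expect_equal(r3(c(s2$ho, s2$he, s2$pic)), c(0.167, 0.159, 0.141))

  mono <- summarize_locus(make_genotypes("1/1" = 12), "L1")
  expect_equal(mono$na, 1L)
  expect_equal(c(mono$ho, mono$he, mono$pic), c(0, 0, 0))
})

test_that("PIC <= 1 - sum(p^2) <= He on random spectra", {
  set.seed(5)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    n <- sample(4:30, 1)
    g <- simulate_genotypes(list(L = rep(1 / k, k)), n = n, seed = i)
    s <- summarize_loci(g)
    af <- allele_frequencies(g, "L")
    gene_div <- 1 - sum(af$freq^2)
    expect_lte(s$pic, gene_div + 1e-9)
    expect_lte(gene_div, s$he + 1e-9)
    expect_true(all(c(s$ho, s$he, s$pic) >= 0 & c(s$ho, s$he, s$pic) <= 1))
  }
})

test_that("the unbiased He estimator is unbiased at n = 12", {
  p <- c(0.6, 0.3, 0.1)
  target <- 1 - sum(p^2)
  freqs <- stats::setNames(rep(list(p), 10000), sprintf("L%05d", 1:10000))
  g <- simulate_genotypes(freqs, n = 12, seed = 202)
  he <- summarize_loci(g)$he
  expect_lt(abs(mean(he) - target), 3 * stats::sd(he) / sqrt(length(he)))
})

test_that("equal-frequency k-allele He approaches 1 - 1/k at large n", {
  k <- 4
  g <- simulate_genotypes(list(L = rep(1 / k, k)), n = 10000, seed = 303)
  expect_lt(abs(summarize_loci(g)$he - (1 - 1 / k)), 1e-3)
})

test_that("summarize_loci recovers generating frequencies within error", {
  p <- c(0.7, 0.2, 0.1)
  g <- simulate_genotypes(list(L = p), n = 5000, seed = 404)
  af <- allele_frequencies(g, "L")
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(af$freq - p) < 4 * se))
})

test_that("panel summary returns per-locus rows, means and pooled NA", {
  freqs <- list(L1 = c(0.5, 0.5), L2 = c(0.6, 0.3, 0.1), L3 = c(0.9, 0.1))
  g <- dplyr::bind_rows(
    simulate_genotypes(freqs, n = 12, seed = 1, pop = "ZZ"),
    simulate_genotypes(freqs, n = 12, seed = 2, pop = "FZ"))
  panel <- summarize_panel(g)
  expect_s3_class(panel, "ssr_panel")
  expect_equal(nrow(panel$summaries), 6L)
  expect_equal(sort(panel$means$population), c("FZ", "ZZ"))
  expect_equal(nrow(panel$pooled_na), 3L)
  expect_identical(tidy(panel), panel$summaries)
  expect_identical(glance(panel), panel$means)

  single <- summarize_panel(simulate_genotypes(freqs[1], n = 12, seed = 3))
  expect_equal(single$means$mean_pic, single$summaries$pic)
  expect_equal(single$means$mean_na, as.numeric(single$summaries$na))
})

test_that("panel means reproduce the reference survey averages", {
  m <- panel_means(onipae_marker_panel())
  r2 <- function(x) round_half_up(x, 2)
  r3 <- function(x) round_half_up(x, 3)
  expect_equal(r2(m$mean_na), c(2.56, 2.56))
  zz <- m[m$population == "Zhangzhou", ]
  fz <- m[m$population == "Fuzhou", ]
  expect_equal(r3(zz$mean_pic), 0.372)
  expect_equal(r3(fz$mean_pic), 0.256)
})

test_that("genotype reconstruction finds the unique matching configuration", {
  r1 <- reconstruct_genotype_configuration(12, 2, 0.083, 0.083,
                                           tolerance = 5e-4)
  expect_equal(nrow(r1), 1L)
  expect_equal(unname(r1$counts[[1]]), c(11L, 0L, 1L))
  expect_equal(round_half_up(r1$pic, 3), 0.077)

  r2 <- reconstruct_genotype_configuration(12, 2, 0.167, 0.159,
                                           tolerance = 5e-4)
  expect_equal(nrow(r2), 1L)
  expect_equal(unname(r2$counts[[1]]), c(10L, 0L, 2L))
  expect_equal(round_half_up(r2$pic, 3), 0.141)

  # the alternative heterozygote split {9, 2, 1} implies He 0.290, excluded
  r2wide <- reconstruct_genotype_configuration(12, 2, 0.167, 0.290,
                                               tolerance = 5e-4)
  expect_equal(unname(r2wide$counts[[1]]), c(9L, 1L, 2L))

  mono <- reconstruct_genotype_configuration(12, 1, 0, 0)
  expect_equal(nrow(mono), 1L)
  expect_equal(unname(mono$counts[[1]]), 12L)

  none <- reconstruct_genotype_configuration(12, 2, 0.5, 0.01,
                                             tolerance = 1e-4)
  expect_equal(nrow(none), 0L)
})

test_that("reconstructed configurations round-trip through summarize_locus", {
  cfg <- reconstruct_genotype_configuration(12, 2, 0.083, 0.083)$counts[[1]]
  g <- make_genotypes("1/1" = cfg[["1/1"]], "2/2" = cfg[["2/2"]],
                      "1/2" = cfg[["1/2"]])
  s <- summarize_locus(g, "L1")
  expect_equal(round_half_up(s$he, 3), 0.083)
  expect_equal(round_half_up(s$pic, 3), 0.077)
})
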