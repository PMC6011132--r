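# Hardy-Weinberg exact tests on the Levene conditional distribution.
#
# Conditional on the observed allele counts m_i, a genotype-count
# configuration {n_ij} with h heterozygotes has probability
#   P = n! * prod_i m_i! * 2^h / ((2n)! * prod_{i<=j} n_ij!).
# The probability test sums P over configurations no more probable than
# the observed one; the deficit/excess tests sum the tails ordered by
# heterozygote count.

.levene_cache <- new.env(parent = emptyenv())

# enumerate all genotype-count configurations for allele-count vector m;
# returns list(h = integer, logp = numeric) or NULL if more than
# max_configs configurations exist
enumerate_levene <- function(m, max_configs = 1e5) {
  k <- length(m)
  n <- sum(m) / 2
  if (sum(m) %% 2 != 0) stop_ssrkit("allele counts must sum to an even number")
  base_log <- lfactorial(n) + sum(lfactorial(m)) - lfactorial(2 * n)
  hs <- integer(0)
  lps <- numeric(0)
  count <- 0L
  aborted <- FALSE

  # recurse over alleles; for allele i choose n_ii then distribute the
  # remaining copies among heterozygote cells (i, j > i)
  rec <- function(i, rem, h, lf_cells) {
    if (aborted) return(invisible())
    if (i == k) {
      if (rem[k] %% 2 != 0) return(invisible())
      n_kk <- rem[k] %/% 2
      count <<- count + 1L
      if (count > max_configs) {
        aborted <<- TRUE
        return(invisible())
      }
      hs[count] <<- h
      lps[count] <<- base_log + h * log(2) - (lf_cells + lfactorial(n_kk))
      return(invisible())
    }
    for (n_ii in 0:(rem[i] %/% 2)) {
      d <- rem[i] - 2L * n_ii
      distribute(i, i + 1L, d, rem, h, lf_cells + lfactorial(n_ii))
    }
  }
  distribute <- function(i, j, d, rem, h, lf_cells) {
    if (aborted) return(invisible())
    if (j > k) {
      if (d == 0L) {
        rem[i] <- 0L
        rec(i + 1L, rem, h, lf_cells)
      }
      return(invisible())
    }
    if (j == k) {
      if (d <= rem[k]) {
        rem2 <- rem
        rem2[i] <- 0L
        rem2[k] <- rem2[k] - d
        rec(i + 1L, rem2, h + d, lf_cells + lfactorial(d))
      }
      return(invisible())
    }
    for (n_ij in 0:min(d, rem[j])) {
      rem2 <- rem
      rem2[j] <- rem2[j] - n_ij
      distribute(i, j + 1L, d - n_ij, rem2, h + n_ij,
                 lf_cells + lfactorial(n_ij))
    }
  }
  rec(1L, as.integer(m), 0L, 0)
  if (aborted) return(NULL)
  list(h = hs[seq_len(count)], logp = lps[seq_len(count)])
}

levene_distribution <- function(m, max_configs = 1e5) {
  key <- paste(sort(as.integer(m)), collapse = ",")
  hit <- .levene_cache[[key]]
  if (!is.null(hit)) return(hit)
  dist <- enumerate_levene(sort(as.integer(m)), max_configs)
  if (!is.null(dist)) .levene_cache[[key]] <- dist
  dist
}

# log-probability of one observed configuration
levene_logp <- function(n, m, cell_counts, h) {
  lfactorial(n) + sum(lfactorial(m)) - lfactorial(2 * n) +
    h * log(2) - sum(lfactorial(cell_counts))
}

#' Hardy-Weinberg exact test for one locus
#'
#' Exact test conditional on allele counts (Levene's distribution): the
#' two-sided probability test sums the probabilities of all genotype
#' configurations no more probable than the observed one (ties within a
#' relative 1e-12 are included), and one-sided deficit/excess p-values sum
#' the tails of configurations with no more (respectively no fewer)
#' heterozygotes than observed.  The conditional distribution is
#' enumerated completely when it has at most `max_configs` configurations;
#' beyond that a seeded Monte-Carlo sample of the distribution (random
#' pairings of the observed allele copies) is used and a standard error is
#' reported.
#'
#' @inheritParams allele_frequencies
#' @param method `"auto"` (enumerate if feasible, else Monte-Carlo),
#'   `"enumeration"`, or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Seed for the Monte-Carlo sampler (required for
#'   reproducibility when MC is used).
#' @param max_configs Enumeration cap for `method = "auto"`.
#' @return One-row tibble: `pop`, `locus`, `n`, `na`, `het_obs`,
#'   `p_probability`, `p_deficit`, `p_excess`, `method`
#'   (`"enumeration"`, `"monte_carlo"` or `"not_applicable"`),
#'   `n_configurations`, `n_samples`, `mc_se`, `seed`.  Monomorphic loci
#'   give a `"not_applicable"` row with `NA` p-values.
#' @export
hwe_exact_test <- function(genotypes, locus, pop = NULL,
                           method = c("auto", "enumeration", "monte_carlo"),
                           n_samples = 1e6, seed = NULL,
                           max_configs = 1e5) {
  method <- match.arg(method)
  sub <- genotype_subset(genotypes, locus, pop)
  complete <- sub[!is.na(sub$a1) & !is.na(sub$a2), ]
  if (nrow(complete) == 0L) stop_ssrkit("no data at locus '", locus, "'")
  hwe_test_counts(complete$a1, complete$a2, method = method,
                  n_samples = n_samples, seed = seed,
                  max_configs = max_configs,
                  pop = complete$pop[[1]], locus = locus)
}

#' Hardy-Weinberg exact test from raw allele calls
#'
#' Lower-level interface to [hwe_exact_test()] taking the two allele-call
#' vectors directly.
#'
#' @param a1,a2 Integer allele codes of the two alleles per individual
#'   (complete calls only).
#' @inheritParams hwe_exact_test
#' @return As [hwe_exact_test()].
#' @export
hwe_test_counts <- function(a1, a2,
                            method = c("auto", "enumeration", "monte_carlo"),
                            n_samples = 1e6, seed = NULL, max_configs = 1e5,
                            pop = NA_character_, locus = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(a1) == length(a2), !anyNA(a1), !anyNA(a2))
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  row <- tibble::tibble(pop = pop, locus = locus, n = n, na = k,
                        het_obs = NA_integer_, p_probability = NA_real_,
                        p_deficit = NA_real_, p_excess = NA_real_,
                        method = "not_applicable",
                        n_configurations = NA_integer_,
                        n_samples = NA_integer_, mc_se = NA_real_,
                        seed = seed %||% NA_integer_)
  if (k < 2L || n < 2L) return(row)

  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  h_obs <- sum(lo != hi)
  m <- tabulate(c(i1, i2), nbins = k)
  cell <- (lo - 1L) * k + hi
  cell_counts <- as.integer(table(cell))
  logp_obs <- levene_logp(n, m, cell_counts, h_obs)
  row$het_obs <- h_obs
  tie_tol <- 1e-12

  dist <- if (method != "monte_carlo") levene_distribution(m, max_configs)
          else NULL
  if (method == "enumeration" && is.null(dist)) {
    stop_ssrkit("more than max_configs configurations; ",
                "use method = 'monte_carlo'")
  }
  if (!is.null(dist)) {
    p <- exp(dist$logp)
    row$p_probability <- min(1, sum(p[dist$logp <= logp_obs + tie_tol]))
    row$p_deficit <- min(1, sum(p[dist$h <= h_obs]))
    row$p_excess <- min(1, sum(p[dist$h >= h_obs]))
    row$method <- "enumeration"
    row$n_configurations <- length(p)
    return(row)
  }

  # Monte-Carlo: resample random pairings of the observed allele copies
  run_mc <- function() {
    copies <- rep.int(seq_len(k), m)
    hits_p <- 0L
    hits_def <- 0L
    hits_exc <- 0L
    for (b in seq_len(n_samples)) {
      perm <- sample(copies)
      s1 <- perm[seq(1L, 2L * n, by = 2L)]
      s2 <- perm[seq(2L, 2L * n, by = 2L)]
      plo <- pmin(s1, s2)
      phi <- pmax(s1, s2)
      h <- sum(plo != phi)
      cc <- tabulate((plo - 1L) * k + phi, nbins = k * k)
      lp <- levene_logp(n, m, cc[cc > 0L], h)
      if (lp <= logp_obs + tie_tol) hits_p <- hits_p + 1L
      if (h <= h_obs) hits_def <- hits_def + 1L
      if (h >= h_obs) hits_exc <- hits_exc + 1L
    }
    c(hits_p, hits_def, hits_exc)
  }
  hits <- if (!is.null(seed)) withr::with_seed(seed, run_mc()) else run_mc()
  row$p_probability <- hits[1] / n_samples
  row$p_deficit <- hits[2] / n_samples
  row$p_excess <- hits[3] / n_samples
  row$method <- "monte_carlo"
  row$n_samples <- as.integer(n_samples)
  row$mc_se <- sqrt(row$p_probability * (1 - row$p_probability) / n_samples)
  row
}

#' Hardy-Weinberg exact tests for all loci and populations
#'
#' Maps [hwe_exact_test()] over every population x locus combination.
#'
#' @inheritParams hwe_exact_test
#' @param genotypes Long genotype tibble.
#' @return Tibble with one row per combination (see [hwe_exact_test()]).
#' @export
hwe_test_all <- function(genotypes, method = "auto", n_samples = 1e6,
                         seed = NULL, max_configs = 1e5) {
  combos <- dplyr::distinct(genotypes, .data$pop, .data$locus)
  purrr::pmap(combos, function(pop, locus) {
    hwe_exact_test(genotypes, locus, pop, method = method,
                   n_samples = n_samples, seed = seed,
                   max_configs = max_configs)
  }) |>
    dplyr::bind_rows()
}
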