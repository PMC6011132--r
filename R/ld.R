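#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests non-independence of the genotypes at two loci without assuming
#' phase: the log-likelihood-ratio statistic G is computed on the joint
#' genotype x genotype contingency table over complete cases, and its null
#' distribution is obtained by permuting one locus's genotype column among
#' individuals.  The p-value uses the add-one permutation estimator
#' p = (1 + #\{G_perm >= G_obs\}) / (1 + n_permutations).
#'
#' @param genotypes Long genotype tibble for a single population.
#' @param locus_a,locus_b Locus names.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param pop Population name; may be omitted when only one is present.
#' @return One-row tibble: `pop`, `locus_a`, `locus_b`, `n`, `g`,
#'   `p_value`, `n_permutations`, `seed`, `method` (`"permutation"` or
#'   `"not_applicable"` when either locus is monomorphic among complete
#'   cases).
#' @export
genotypic_ld_test <- function(genotypes, locus_a, locus_b,
                              n_permutations = 1000, seed = NULL,
                              pop = NULL) {
  stopifnot(n_permutations >= 100)
  ga <- genotype_subset(genotypes, locus_a, pop)
  gb <- genotype_subset(genotypes, locus_b, pop)
  merged <- dplyr::inner_join(ga, gb, by = c("pop", "ind"),
                              suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$a1_a), !is.na(.data$a2_a),
                  !is.na(.data$a1_b), !is.na(.data$a2_b))
  row <- tibble::tibble(pop = if (nrow(merged)) merged$pop[[1]] else NA,
                        locus_a = locus_a, locus_b = locus_b,
                        n = nrow(merged), g = NA_real_, p_value = NA_real_,
                        n_permutations = as.integer(n_permutations),
                        seed = seed %||% NA_integer_,
                        method = "not_applicable")
  if (nrow(merged) < 2L) return(row)
  geno_a <- paste(pmin(merged$a1_a, merged$a2_a),
                  pmax(merged$a1_a, merged$a2_a), sep = "/")
  geno_b <- paste(pmin(merged$a1_b, merged$a2_b),
                  pmax(merged$a1_b, merged$a2_b), sep = "/")
  if (length(unique(geno_a)) < 2L || length(unique(geno_b)) < 2L) {
    return(row)
  }
  fa <- factor(geno_a)
  fb <- factor(geno_b)
  g_obs <- g_statistic(fa, fb)
  run_perms <- function() {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (g_statistic(fa, sample(fb)) >= g_obs - 1e-12) hits <- hits + 1L
    }
    hits
  }
  hits <- if (!is.null(seed)) withr::with_seed(seed, run_perms())
          else run_perms()
  row$g <- g_obs
  row$p_value <- (1 + hits) / (1 + n_permutations)
  row$method <- "permutation"
  row
}

# log-likelihood-ratio statistic on a two-way table of factors
g_statistic <- function(fa, fb) {
  tab <- table(fa, fb)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  obs <- as.numeric(tab)
  exp <- as.numeric(expected)
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / exp[keep]))
}

#' Genotypic LD tests for all locus pairs
#'
#' Runs [genotypic_ld_test()] for every unordered locus pair within each
#' population.
#'
#' @inheritParams genotypic_ld_test
#' @return Tibble with one row per population x locus pair.
#' @export
ld_test_all <- function(genotypes, n_permutations = 1000, seed = NULL) {
  pops <- unique(genotypes$pop)
  out <- list()
  for (p in pops) {
    sub <- genotypes[genotypes$pop == p, ]
    loci <- unique(sub$locus)
    if (length(loci) < 2L) next
    pairs <- utils::combn(loci, 2)
    for (j in seq_len(ncol(pairs))) {
      out[[length(out) + 1L]] <- genotypic_ld_test(
        sub, pairs[1, j], pairs[2, j],
        n_permutations = n_permutations,
        seed = if (is.null(seed)) NULL else seed + j)
    }
  }
  dplyr::bind_rows(out)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] exposing the three standard
#' corrections used for batches of HWE / LD tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed for
#'   not-applicable tests and passed through).
#' @param method `"bonferroni"`, `"holm"` or `"bh"`
#'   (Benjamini-Hochberg FDR).
#' @return Adjusted p-values, clipped to 1, same length and order.
#' @examples
#' multiple_test_adjust(c(0.01, 0.02, 0.03), "bonferroni")
#' @export
multiple_test_adjust <- function(p_values,
                                 method = c("bonferroni", "holm", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_ssrkit("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = c(bonferroni = "bonferroni",
                                       holm = "holm", bh = "BH")[[method]])
}
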