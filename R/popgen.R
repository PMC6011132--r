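#' Allele frequency spectrum at one locus
#'
#' Drops missing calls and counts allele copies among the remaining `2n`
#' chromosomes of one population.
#'
#' @param genotypes Long genotype tibble (`pop`, `ind`, `locus`, `a1`,
#'   `a2`), as from [read_genepop()] or [simulate_genotypes()].
#' @param locus Locus name.
#' @param pop Population name; may be omitted when the tibble holds a
#'   single population.
#' @return Tibble with columns `pop`, `locus`, `allele`, `count`, `freq`,
#'   `n` (diploid sample size after removing missing calls).
#' @export
allele_frequencies <- function(genotypes, locus, pop = NULL) {
  sub <- genotype_subset(genotypes, locus, pop)
  complete <- sub[!is.na(sub$a1) & !is.na(sub$a2), ]
  if (nrow(complete) == 0L) {
    stop_ssrkit("no data at locus '", locus, "'",
                if (!is.null(pop)) paste0(" in population '", pop, "'"))
  }
  n <- nrow(complete)
  counts <- table(c(complete$a1, complete$a2))
  tibble::tibble(
    pop = complete$pop[[1]], locus = locus,
    allele = as.integer(names(counts)),
    count = as.integer(counts),
    freq = as.integer(counts) / (2 * n),
    n = n
  )
}

genotype_subset <- function(genotypes, locus, pop = NULL) {
  stopifnot(all(c("pop", "ind", "locus", "a1", "a2") %in% names(genotypes)))
  sub <- genotypes[genotypes$locus == locus, , drop = FALSE]
  if (!is.null(pop)) sub <- sub[sub$pop == pop, , drop = FALSE]
  if (nrow(sub) == 0L) stop_ssrkit("locus '", locus, "' not found")
  if (length(unique(sub$pop)) > 1L) {
    stop_ssrkit("multiple populations present; supply `pop`")
  }
  sub
}

#' Per-locus marker statistics
#'
#' Computes, for one locus in one population: the number of distinct
#' alleles (NA), observed heterozygosity Ho (fraction of heterozygous
#' individuals), Nei's unbiased expected heterozygosity
#' He = (2n/(2n-1)) (1 - sum p_i^2), and the polymorphic information
#' content PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2 (Botstein).
#' Missing calls are dropped locus-wise.  Values are returned at full
#' precision; round at report time.
#'
#' @inheritParams allele_frequencies
#' @return One-row tibble: `pop`, `locus`, `n`, `na`, `ho`, `he`, `pic`.
#' @examples
#' g <- tibble::tibble(pop = "P", ind = sprintf("i%02d", 1:12),
#'                     locus = "L1", a1 = 1L,
#'                     a2 = c(rep(1L, 11), 2L))
#' summarize_locus(g, "L1")  # He 0.083, PIC 0.077 at 3 d.p.
#' @export
summarize_locus <- function(genotypes, locus, pop = NULL) {
  sub <- genotype_subset(genotypes, locus, pop)
  summarize_loci(sub)
}

#' Marker statistics for every population x locus combination
#'
#' Vectorised form of [summarize_locus()] over all populations and loci in
#' the tibble.
#'
#' @param genotypes Long genotype tibble.
#' @return Tibble with one row per `pop` x `locus`: `pop`, `locus`, `n`,
#'   `na`, `ho`, `he`, `pic`.  Combinations with no complete calls are
#'   dropped.
#' @export
summarize_loci <- function(genotypes) {
  stopifnot(all(c("pop", "ind", "locus", "a1", "a2") %in% names(genotypes)))
  complete <- genotypes[!is.na(genotypes$a1) & !is.na(genotypes$a2), ]
  ind_stats <- complete |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(n = dplyr::n(), ho = mean(.data$a1 != .data$a2),
                     .groups = "drop")
  freq_stats <- complete |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::count(.data$pop, .data$locus, .data$allele) |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(
      na = dplyr::n(),
      sum_p2 = sum((.data$n / sum(.data$n))^2),
      sum_p4 = sum((.data$n / sum(.data$n))^4),
      .groups = "drop")
  ind_stats |>
    dplyr::inner_join(freq_stats, by = c("pop", "locus")) |>
    dplyr::mutate(
      he = 2 * .data$n / (2 * .data$n - 1) * (1 - .data$sum_p2),
      pic = 1 - .data$sum_p2 - (.data$sum_p2^2 - .data$sum_p4)) |>
    dplyr::select("pop", "locus", "n", "na", "ho", "he", "pic")
}

#' Evaluate a marker panel across populations
#'
#' Per-locus statistics for every population (see [summarize_loci()]),
#' arithmetic means of NA, Ho, He and PIC across loci within each
#' population, and pooled allele counts per locus (union of alleles across
#' populations).
#'
#' @param genotypes Long genotype tibble covering one or more populations
#'   typed at a shared locus set.
#' @return An object of class `ssr_panel`: list with `summaries`
#'   (per pop x locus tibble), `means` (per population), and `pooled_na`
#'   (per locus).  Use [generics::tidy()] / [generics::glance()] to
#'   extract the tables.
#' @export
summarize_panel <- function(genotypes) {
  shared <- genotypes |>
    dplyr::distinct(.data$pop, .data$locus) |>
    dplyr::count(.data$locus) |>
    dplyr::filter(.data$n == length(unique(genotypes$pop)))
  if (nrow(shared) == 0L) stop_ssrkit("populations share no loci")
  summaries <- summarize_loci(genotypes)
  means <- summaries |>
    dplyr::group_by(population = .data$pop) |>
    dplyr::summarise(n_loci = dplyr::n(),
                     mean_na = mean(.data$na), mean_ho = mean(.data$ho),
                     mean_he = mean(.data$he), mean_pic = mean(.data$pic))
  pooled <- genotypes |>
    dplyr::filter(!is.na(.data$a1) & !is.na(.data$a2)) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::distinct(.data$locus, .data$allele) |>
    dplyr::count(.data$locus, name = "na_pooled")
  structure(list(summaries = summaries, means = means, pooled_na = pooled),
            class = "ssr_panel")
}

#' Column means of a per-locus marker table
#'
#' Arithmetic means of NA, Ho, He and PIC across loci, per population, for
#' any per-locus statistics table — computed (e.g. [summarize_loci()]
#' output) or transcribed from a published report
#' (e.g. [onipae_marker_panel()]).
#'
#' @param summary_tbl Tibble with a population column (`pop` or
#'   `population`) and columns `na` and `pic` (optionally `ho`, `he`).
#' @return Tibble with one row per population: `population`, `n_loci`,
#'   `mean_na`, `mean_pic` and, when available, `mean_ho`, `mean_he`.
#' @export
panel_means <- function(summary_tbl) {
  popcol <- intersect(c("population", "pop"), names(summary_tbl))[1]
  if (is.na(popcol)) stop_ssrkit("no population column found")
  stopifnot(all(c("na", "pic") %in% names(summary_tbl)))
  summary_tbl |>
    dplyr::group_by(population = .data[[popcol]]) |>
    dplyr::summarise(n_loci = dplyr::n(),
                     dplyr::across(dplyr::any_of(c("na", "ho", "he", "pic")),
                                   mean, .names = "mean_{.col}"))
}

#' @export
print.ssr_panel <- function(x, ...) {
  cat("Marker panel evaluation\n\nPer-locus statistics:\n")
  print(x$summaries, n = Inf)
  cat("\nPer-population means:\n")
  print(x$means)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ssr_panel <- function(x, ...) x$summaries

#' @export
glance.ssr_panel <- function(x, ...) x$means

#' Reconstruct genotype configurations from summary statistics
#'
#' Given the published summary of a locus (sample size `n`, allele number
#' `na`, observed heterozygosity `ho`, unbiased expected heterozygosity
#' `he`) but not the raw genotypes, exhaustively enumerates every
#' genotype-count configuration over `na` alleles with `n` individuals
#' whose heterozygote count equals `round(ho * n)` and whose computed He
#' lies within `tolerance` of the target.  Used to validate printed
#' statistics when raw genotypes are unavailable: a unique surviving
#' configuration pins down the data, and its implied PIC can be checked
#' against the printed value.
#'
#' @param n Diploid sample size (<= 50).
#' @param na Number of distinct alleles (<= 4).
#' @param ho Target observed heterozygosity.
#' @param he Target unbiased expected heterozygosity.
#' @param tolerance Absolute tolerance on He (default 5e-4, i.e. printed
#'   3-decimal precision).
#' @return Tibble with one row per matching configuration: `config`,
#'   `counts` (list column: named genotype counts such as `1/1`, `1/2`),
#'   `ho`, `he`, `pic` (implied values at full precision).  Zero rows when
#'   nothing matches.
#' @export
reconstruct_genotype_configuration <- function(n, na, ho, he,
                                               tolerance = 5e-4) {
  stopifnot(n >= 1, n <= 50, na >= 1, na <= 4)
  h <- as.integer(round(ho * n))
  hom_names <- sprintf("%d/%d", seq_len(na), seq_len(na))
  het_pairs <- if (na > 1) utils::combn(seq_len(na), 2) else
    matrix(integer(), nrow = 2)
  het_names <- if (ncol(het_pairs)) sprintf("%d/%d", het_pairs[1, ],
                                            het_pairs[2, ]) else character()
  hom_comp <- compositions(n - h, na)
  het_comp <- compositions(h, max(1L, ncol(het_pairs)))
  if (ncol(het_pairs) == 0L) het_comp <- matrix(0L, nrow = 1, ncol = 0)
  if (nrow(hom_comp) * nrow(het_comp) > 5e6) {
    stop_ssrkit("configuration space too large to enumerate")
  }
  out <- list()
  for (i in seq_len(nrow(hom_comp))) {
    homs <- hom_comp[i, ]
    m_hom <- 2L * homs
    for (j in seq_len(nrow(het_comp))) {
      hets <- het_comp[j, ]
      m <- m_hom
      for (col in seq_along(het_names)) {
        m[het_pairs[1, col]] <- m[het_pairs[1, col]] + hets[col]
        m[het_pairs[2, col]] <- m[het_pairs[2, col]] + hets[col]
      }
      if (any(m == 0L)) next  # every allele must be observed
      p <- m / (2 * n)
      he_val <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
      if (abs(he_val - he) > tolerance) next
      sum_p2 <- sum(p^2)
      pic_val <- 1 - sum_p2 - (sum_p2^2 - sum(p^4))
      canon <- canonical_config(homs, hets, het_pairs, na)
      counts <- stats::setNames(canon, c(hom_names, het_names))
      out[[length(out) + 1L]] <- tibble::tibble(
        signature = paste(canon, collapse = ","),
        counts = list(counts), ho = h / n, he = he_val, pic = pic_val)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(config = integer(), counts = list(),
                          ho = numeric(), he = numeric(), pic = numeric()))
  }
  # configurations that differ only by allele relabeling are one solution
  res <- dplyr::distinct(res, .data$signature, .keep_all = TRUE) |>
    dplyr::select(-"signature")
  tibble::add_column(res, config = seq_len(nrow(res)), .before = 1)
}

# canonical representative of a genotype-count configuration under
# relabeling of alleles: the lexicographically largest count vector over
# all allele permutations (so the most common homozygote is allele 1)
canonical_config <- function(homs, hets, het_pairs, na) {
  if (na == 1L) return(homs)
  perms <- all_permutations(na)
  best <- NULL
  for (pi in perms) {
    new_homs <- homs
    new_homs[pi] <- homs
    new_hets <- hets
    if (ncol(het_pairs) > 0L) {
      for (col in seq_len(ncol(het_pairs))) {
        a <- sort(pi[het_pairs[, col]])
        # index of pair (a[1], a[2]) in the canonical het ordering
        idx <- which(het_pairs[1, ] == a[1] & het_pairs[2, ] == a[2])
        new_hets[idx] <- hets[col]
      }
    }
    v <- c(new_homs, new_hets)
    if (is.null(best) || vector_gt(v, best)) best <- v
  }
  best
}

vector_gt <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1]] > 0
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_permutations(k - 1L)) {
      v <- integer(k)
      v[1] <- i
      v[-1] <- ifelse(rest >= i, rest + 1L, rest)
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

# all nonnegative integer vectors of length k summing to s
compositions <- function(s, k) {
  if (k == 1L) return(matrix(as.integer(s), ncol = 1))
  parts <- lapply(0:s, function(first) {
    rest <- compositions(s - first, k - 1L)
    cbind(as.integer(first), rest)
  })
  do.call(rbind, parts)
}
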