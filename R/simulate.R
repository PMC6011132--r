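#' Simulate transcript sequences with implanted microsatellites
#'
#' Generates a desk-scale stand-in for a transcriptome assembly: background
#' sequences drawn i.i.d. from a base composition and rejection-filtered
#' against the miner itself so that no unintended repeat meets the mining
#' thresholds, with perfect SSRs implanted at recorded coordinates.  The
#' returned truth table has the same schema as [find_perfect_ssrs()]
#' output, so miner recall and precision can be scored exactly.
#'
#' Each implant occupies its own sequence (at most one per sequence);
#' sequences beyond the implant count are pure background.  After
#' implanting, a sequence is accepted only if mining it returns exactly
#' the implanted locus, so junction artefacts cannot silently corrupt the
#' truth table.
#'
#' @param n_seqs Number of sequences.
#' @param length_bounds Length range (bp), inclusive.
#' @param implants Tibble with columns `motif`, `repeats`, `count`:
#'   how many sequences receive an implant of each kind.
#' @param base_composition Named weights for A, C, G, T.  The default is
#'   mildly A/T-rich, as insect transcriptomes typically are.
#' @param seed RNG seed (required: output is part of reproducible
#'   pipelines).
#' @param thresholds Mining thresholds used for the rejection filter and
#'   the truth check.
#' @param max_attempts Rejection-sampling attempts per sequence before
#'   giving up.
#' @return List with `records` (tibble `id`, `seq`) and `truth` (tibble
#'   `seq_id`, `motif`, `repeats`, `start`, `end`, `length_bp`).
#' @export
simulate_transcripts_with_ssrs <- function(n_seqs,
                                           length_bounds = c(400L, 800L),
                                           implants = NULL,
                                           base_composition = c(A = 0.3,
                                                                C = 0.2,
                                                                G = 0.2,
                                                                T = 0.3),
                                           seed,
                                           thresholds = ssr_thresholds(),
                                           max_attempts = 50L) {
  stopifnot(length(length_bounds) == 2L,
            all(c("A", "C", "G", "T") %in% names(base_composition)))
  if (missing(seed)) stop_ssrkit("a seed is required")
  implants <- implants %||%
    tibble::tibble(motif = character(), repeats = integer(),
                   count = integer())
  stopifnot(all(c("motif", "repeats", "count") %in% names(implants)))
  plan <- tidyr::uncount(implants[c("motif", "repeats", "count")],
                         weights = .data$count)
  if (nrow(plan) > n_seqs) {
    stop_ssrkit("more implants (", nrow(plan), ") than sequences (",
                n_seqs, ")")
  }
  bases <- c("A", "C", "G", "T")
  w <- base_composition[bases] / sum(base_composition[bases])

  withr::with_seed(seed, {
    records <- vector("list", n_seqs)
    truth <- vector("list", n_seqs)
    for (i in seq_len(n_seqs)) {
      id <- sprintf("tx%04d", i)
      implant <- if (i <= nrow(plan)) plan[i, ] else NULL
      got <- NULL
      for (attempt in seq_len(max_attempts)) {
        L <- sample(length_bounds[1]:length_bounds[2], 1L)
        if (is.null(implant)) {
          s <- paste(sample(bases, L, replace = TRUE, prob = w),
                     collapse = "")
          if (nrow(find_perfect_ssrs(s, id, thresholds)) == 0L) {
            got <- list(seq = s, truth = NULL)
            break
          }
        } else {
          ins <- strrep(implant$motif, implant$repeats)
          bg_len <- L - nchar(ins)
          if (bg_len < 2L) {
            stop_ssrkit("implant longer than the sequence bounds allow")
          }
          bg <- sample(bases, bg_len, replace = TRUE, prob = w)
          cut <- sample(seq_len(bg_len - 1L), 1L)
          s <- paste0(paste(bg[seq_len(cut)], collapse = ""), ins,
                      paste(bg[(cut + 1L):bg_len], collapse = ""))
          found <- find_perfect_ssrs(s, id, thresholds)
          expected <- tibble::tibble(
            seq_id = id, motif = implant$motif,
            repeats = as.integer(implant$repeats),
            start = cut + 1L,
            end = cut + nchar(ins),
            length_bp = nchar(ins))
          if (nrow(found) == 1L && identical(
            as.list(found[1, c("motif", "repeats", "start", "end")]),
            as.list(expected[1, c("motif", "repeats", "start", "end")]))) {
            got <- list(seq = s, truth = expected)
            break
          }
        }
      }
      if (is.null(got)) {
        stop_ssrkit("could not generate a repeat-free background after ",
                    max_attempts, " attempts; use a less biased ",
                    "base_composition")
      }
      records[[i]] <- tibble::tibble(id = id, seq = got$seq)
      truth[[i]] <- got$truth
    }
    list(records = dplyr::bind_rows(records),
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate diploid genotypes under a mixture of random mating and
#' autozygosity
#'
#' For each individual at each locus: with probability `inbreeding` the
#' individual is autozygous (one allele drawn from the locus frequencies
#' and doubled), otherwise the two alleles are drawn independently.
#' Expected heterozygosity is therefore
#' `(1 - F) * (1 - sum p_i^2)`.  Allele codes are assigned 1..k in
#' descending frequency order.  Calls are masked (both alleles `NA`) at
#' `missing_rate`.
#'
#' @param allele_freqs Named list: one numeric frequency vector per locus
#'   (each summing to 1).
#' @param n Number of diploid individuals.
#' @param inbreeding Autozygosity probability F in \[0, 1\].
#' @param missing_rate Probability a call is masked as missing.
#' @param seed RNG seed (required).
#' @param pop Population label (also prefixes individual ids).
#' @return Long genotype tibble: `pop`, `ind`, `locus`, `a1`, `a2`.
#' @examples
#' g <- simulate_genotypes(list(L1 = c(0.5, 0.5)), n = 10, seed = 1)
#' @export
simulate_genotypes <- function(allele_freqs, n, inbreeding = 0,
                               missing_rate = 0, seed, pop = "sim") {
  if (missing(seed)) stop_ssrkit("a seed is required")
  stopifnot(is.list(allele_freqs), length(allele_freqs) > 0,
            inbreeding >= 0, inbreeding <= 1,
            missing_rate >= 0, missing_rate < 1, n >= 1)
  loci <- names(allele_freqs) %||% sprintf("L%d", seq_along(allele_freqs))
  if (is.null(names(allele_freqs))) names(allele_freqs) <- loci
  for (nm in loci) {
    f <- allele_freqs[[nm]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop_ssrkit("allele frequencies for locus '", nm,
                  "' must be nonnegative and sum to 1")
    }
  }
  inds <- sprintf("%s_%03d", pop, seq_len(n))
  withr::with_seed(seed, {
    out <- purrr::map(loci, function(nm) {
      f <- sort(allele_freqs[[nm]], decreasing = TRUE)
      k <- length(f)
      auto <- stats::runif(n) < inbreeding
      a1 <- sample.int(k, n, replace = TRUE, prob = f)
      a2 <- ifelse(auto, a1, sample.int(k, n, replace = TRUE, prob = f))
      miss <- stats::runif(n) < missing_rate
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
      tibble::tibble(pop = pop, ind = inds, locus = nm,
                     a1 = as.integer(a1), a2 = as.integer(a2))
    })
    dplyr::bind_rows(out) |>
      dplyr::arrange(match(.data$ind, inds), match(.data$locus, loci))
  })
}
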