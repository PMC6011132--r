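#' Primer design constraints
#'
#' Hard bounds and scoring weights for SSR primer screening.  Defaults
#' follow common marker-development practice: amplicon 100-400 bp, primer
#' 18-28 bp with a 23 bp optimum, GC between 30 and 70 percent, Tm between
#' 50 and 65 degrees C with at most 5 degrees difference within a pair.
#'
#' @param product_min,product_max Amplicon size bounds (bp).
#' @param primer_min,primer_max,primer_opt Primer length bounds and
#'   optimum (bp).
#' @param gc_min,gc_max Hard GC-content bounds (fractions).
#' @param tm_min,tm_max Hard melting-temperature bounds (degrees C).
#' @param max_tm_diff Maximum |Tm_forward - Tm_reverse| (degrees C).
#' @param w_tm Penalty weight per degree of Tm difference.
#' @param w_gc Penalty weight per unit of GC distance outside the
#'   preferred band \[0.45, 0.55\].
#' @param max_complement_run A candidate is rejected when two primers of
#'   the pair (or a primer with itself) share a perfectly complementary
#'   run of at least this many bases.
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(product_min = 100L, product_max = 400L,
                               primer_min = 18L, primer_max = 28L,
                               primer_opt = 23L,
                               gc_min = 0.30, gc_max = 0.70,
                               tm_min = 50, tm_max = 65, max_tm_diff = 5,
                               w_tm = 1.0, w_gc = 10.0,
                               max_complement_run = 8L) {
  stopifnot(primer_min <= primer_opt, primer_opt <= primer_max,
            product_min > 2 * primer_min, product_min <= product_max,
            gc_min <= gc_max, tm_min <= tm_max)
  structure(list(product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 primer_min = as.integer(primer_min),
                 primer_max = as.integer(primer_max),
                 primer_opt = as.integer(primer_opt),
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 max_tm_diff = max_tm_diff, w_tm = w_tm, w_gc = w_gc,
                 max_complement_run = as.integer(max_complement_run)),
            class = "primer_constraints")
}

# nearest-neighbor parameters (SantaLucia & Hicks 2004 unified set):
# delta-H (kcal/mol) and delta-S (cal/mol K) per stacked dinucleotide
nn_params <- function() {
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  list(dh = dh, ds = ds)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' from the unified nearest-neighbor thermodynamic parameter set
#' (SantaLucia & Hicks 2004) with terminal A/T and G/C initiation
#' corrections, 50 mM monovalent cation (entropic salt correction
#' 0.368 (N-1) ln\[Na+\]) and 25 nM of each strand.  Deterministic; all
#' conditions are fixed so results are directly comparable across runs.
#'
#' @param primer Nucleotide word over A/C/G/T, length >= 8.
#' @return Melting temperature in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(primer) {
  stopifnot(is.character(primer), length(primer) == 1L)
  if (grepl("[^ACGT]", primer)) {
    stop_ssrkit("primer must contain only A/C/G/T: ", primer)
  }
  n <- nchar(primer)
  if (n < 8L) stop_ssrkit("primer shorter than 8 bases")
  pars <- nn_params()
  pairs <- substring(primer, seq_len(n - 1L), 2:n)
  dh <- sum(pars$dh[pairs])
  ds <- sum(pars$ds[pairs])
  for (terminal in c(substr(primer, 1L, 1L), substr(primer, n, n))) {
    if (terminal %in% c("A", "T")) {
      dh <- dh + 2.3
      ds <- ds + 4.1
    } else {
      dh <- dh + 0.1
      ds <- ds - 2.8
    }
  }
  na_molar <- 0.05
  # primer binds the template strand: effective duplex concentration is
  # [primer] - [template]/2 with 25 nM of each strand
  k <- 12.5e-9
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# TRUE when p1 and p2 share a perfectly complementary run of >= k bases
# (p2 = p1 checks self-dimerisation / hairpin stems)
has_complement_run <- function(p1, p2, k) {
  n <- nchar(p1)
  if (n < k || nchar(p2) < k) return(FALSE)
  rc2 <- revcomp(p2)
  for (i in seq_len(n - k + 1L)) {
    if (grepl(substr(p1, i, i + k - 1L), rc2, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Screen primer pairs flanking an SSR locus
#'
#' Enumerates all primer placements in the flanks of a repeat locus such
#' that the amplicon contains the full repeat and every hard constraint
#' holds (product size, primer lengths, GC, Tm, Tm difference, no
#' complementary run of `max_complement_run` bases within or between the
#' primers), then ranks candidates by the explicit penalty
#' `|len_f - opt| + |len_r - opt| + w_tm |Tm_f - Tm_r| + w_gc * gc_dist`,
#' where `gc_dist` sums each primer's GC distance outside \[0.45, 0.55\].
#' This transparent score stands in for the undocumented ranking of
#' commercial design suites; it is deterministic, with ties broken by
#' leftmost forward start, then smallest product.
#'
#' Mononucleotide-repeat loci are excluded by default (`exclude_mono`),
#' the usual practice since single-base runs genotype poorly.
#'
#' @param seq Template sequence (uppercase A/C/G/T/N string).
#' @param locus One-row tibble describing the repeat (as from
#'   [find_perfect_ssrs()]): needs columns `motif`, `start`, `end`.
#' @param constraints A [primer_constraints()] object.
#' @param top_k Maximum number of candidates returned.
#' @param exclude_mono Refuse mononucleotide-repeat loci.
#' @return Tibble of ranked candidates: `forward_seq`, `reverse_seq`,
#'   `forward_start`, `reverse_end`, `product_size`, `tm_forward`,
#'   `tm_reverse`, `gc_forward`, `gc_reverse`, `penalty`.  When no
#'   placement is legal the tibble has zero rows and a `reason` attribute
#'   (`"no_candidates"` or `"mononucleotide_excluded"`).
#' @export
screen_primer_pairs <- function(seq, locus,
                                constraints = primer_constraints(),
                                top_k = 3L, exclude_mono = TRUE) {
  stopifnot(inherits(constraints, "primer_constraints"))
  L <- nchar(seq)
  if (locus$start < 1L || locus$end > L || locus$start > locus$end) {
    stop_ssrkit("locus [", locus$start, ", ", locus$end,
                "] outside the template (length ", L, ")")
  }
  empty <- function(reason) {
    out <- tibble::tibble(forward_seq = character(),
                          reverse_seq = character(),
                          forward_start = integer(),
                          reverse_end = integer(),
                          product_size = integer(),
                          tm_forward = numeric(), tm_reverse = numeric(),
                          gc_forward = numeric(), gc_reverse = numeric(),
                          penalty = numeric())
    attr(out, "reason") <- reason
    out
  }
  if (exclude_mono && nchar(locus$motif) == 1L) {
    return(empty("mononucleotide_excluded"))
  }
  cn <- constraints
  fwd <- enumerate_primers(seq, 1L, locus$start - 1L, cn, reverse = FALSE)
  rev <- enumerate_primers(seq, locus$end + 1L, L, cn, reverse = TRUE)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty("no_candidates"))

  pairs <- tidyr::crossing(fwd |> dplyr::rename_with(\(x) paste0("f_", x)),
                           rev |> dplyr::rename_with(\(x) paste0("r_", x))) |>
    dplyr::mutate(product_size = .data$r_end - .data$f_start + 1L) |>
    dplyr::filter(.data$product_size >= cn$product_min,
                  .data$product_size <= cn$product_max,
                  abs(.data$f_tm - .data$r_tm) <= cn$max_tm_diff)
  if (nrow(pairs) == 0L) return(empty("no_candidates"))

  # preferred GC band is fixed at [0.45, 0.55]; distance outside it is the
  # soft part of the score (hard bounds gc_min/gc_max already applied)
  gc_out <- function(gc) pmax(0, 0.45 - gc) + pmax(0, gc - 0.55)
  pairs <- pairs |>
    dplyr::mutate(
      penalty = abs(.data$f_len - cn$primer_opt) +
        abs(.data$r_len - cn$primer_opt) +
        cn$w_tm * abs(.data$f_tm - .data$r_tm) +
        cn$w_gc * (gc_out(.data$f_gc) + gc_out(.data$r_gc))) |>
    dplyr::arrange(.data$penalty, .data$f_start, .data$product_size)

  # cross-dimer check only down the ranking, until top_k survive
  keep <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    if (!has_complement_run(pairs$f_seq[[i]], pairs$r_seq[[i]],
                            cn$max_complement_run)) {
      keep <- c(keep, i)
      if (length(keep) >= top_k) break
    }
  }
  if (length(keep) == 0L) return(empty("no_candidates"))
  pairs[keep, ] |>
    dplyr::transmute(forward_seq = .data$f_seq, reverse_seq = .data$r_seq,
                     forward_start = .data$f_start,
                     reverse_end = .data$r_end,
                     product_size = .data$product_size,
                     tm_forward = .data$f_tm, tm_reverse = .data$r_tm,
                     gc_forward = .data$f_gc, gc_reverse = .data$r_gc,
                     penalty = .data$penalty)
}

# all primers within template window [lo, hi] passing per-primer hard
# constraints; reverse primers are reported 5'->3' on the opposite strand
enumerate_primers <- function(seq, lo, hi, cn, reverse) {
  if (hi - lo + 1L < cn$primer_min) {
    return(tibble::tibble(seq = character(), start = integer(),
                          end = integer(), len = integer(), gc = numeric(),
                          tm = numeric()))
  }
  grid <- tidyr::crossing(start = lo:hi,
                          len = cn$primer_min:cn$primer_max) |>
    dplyr::mutate(end = .data$start + .data$len - 1L) |>
    dplyr::filter(.data$end <= hi)
  if (nrow(grid) == 0L) return(tibble::tibble(seq = character(),
                                              start = integer(),
                                              end = integer(),
                                              len = integer(),
                                              gc = numeric(),
                                              tm = numeric()))
  grid$seq <- substring(seq, grid$start, grid$end)
  grid <- grid[!grepl("[^ACGT]", grid$seq), , drop = FALSE]
  if (reverse) grid$seq <- revcomp(grid$seq)
  if (nrow(grid) == 0L) return(tibble::tibble(seq = character(),
                                              start = integer(),
                                              end = integer(),
                                              len = integer(),
                                              gc = numeric(),
                                              tm = numeric()))
  grid$gc <- gc_fraction(grid$seq)
  grid <- grid[grid$gc >= cn$gc_min & grid$gc <= cn$gc_max, , drop = FALSE]
  grid$tm <- vapply(grid$seq, melting_temperature, numeric(1),
                    USE.NAMES = FALSE)
  grid <- grid[grid$tm >= cn$tm_min & grid$tm <= cn$tm_max, , drop = FALSE]
  if (nrow(grid) > 0L) {
    selfok <- !vapply(grid$seq,
                      \(p) has_complement_run(p, p, cn$max_complement_run),
                      logical(1))
    grid <- grid[selfok, , drop = FALSE]
  }
  tibble::as_tibble(grid[c("seq", "start", "end", "len", "gc", "tm")])
}
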