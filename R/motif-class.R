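#' Canonical motif class of an SSR motif
#'
#' Two motifs describe the same repeat if one is a cyclic rotation of the
#' other or of its reverse complement (a CTT repeat read on the opposite
#' strand is an AAG repeat; within a run, AAC, ACA and CAA are the same
#' repeat in different phase).  The canonical class collapses all of these.
#'
#' The class `key` is the lexicographically smallest word among all
#' rotations of the motif and of its reverse complement.  The display
#' `label` is `"m/r"` where `m` is the smallest rotation on the motif's
#' strand and `r` the smallest rotation of the reverse complement, ordered
#' lexicographically (so both strands yield the same label).  For
#' self-reverse-complement classes such as AT, where the two sides
#' coincide, the right-hand part is the second-smallest rotation, giving
#' the conventional "AT/TA" form.
#'
#' @param motif A primitive nucleotide word over A/C/G/T, length 1-6.
#' @return A list with elements `key` and `label`.
#' @examples
#' canonical_motif_class("CTT")$label   # "AAG/CTT"
#' canonical_motif_class("TA")$label    # "AT/TA"
#' canonical_motif_class("T")$label     # "A/T"
#' @export
canonical_motif_class <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop_ssrkit("motif must be a single nonempty string")
  }
  if (grepl("[^ACGT]", motif)) stop_ssrkit("motif must be over A/C/G/T: ", motif)
  if (nchar(motif) > 6L) stop_ssrkit("motif longer than 6 bp: ", motif)
  if (!is_primitive(motif)) {
    stop_ssrkit("motif is not primitive: ", motif)
  }
  fwd <- sort(rotations(motif))
  rev <- sort(rotations(revcomp(motif)))
  m <- fwd[[1]]
  r <- rev[[1]]
  if (m == r) {
    # self-reverse-complement class: use the second rotation on the right
    all_rot <- sort(unique(c(fwd, rev)))
    right <- if (length(all_rot) > 1L) all_rot[[2]] else all_rot[[1]]
    label <- paste0(m, "/", right)
  } else {
    pair <- sort(c(m, r))
    label <- paste0(pair[[1]], "/", pair[[2]])
  }
  list(key = min(c(m, r)), label = label)
}

repeat_bins <- function() c(4:11, 12L)  # last bin is ">=12"

bin_labels <- function() c(as.character(4:11), "ge12")

repeat_type_names <- function() {
  c("Mononucleotide", "Dinucleotide", "Trinucleotide", "Tetranucleotide",
    "Pentanucleotide", "Hexanucleotide")
}

#' Tabulate SSR frequencies by repeat type and motif class
#'
#' Builds the two standard summary matrices of a transcriptome SSR survey:
#' counts of loci binned by number of full repeat units (bins 4-11 and
#' >= 12) with rows by repeat type (motif length 1-6), and the same binning
#' with rows by canonical motif class.  Row totals and percentages of the
#' grand total (rounded half-up to 2 decimals) are appended.
#'
#' @param loci Tibble of SSR loci with at least columns `motif` and
#'   `repeats` (as from [find_perfect_ssrs()] or [expand_locus_counts()]).
#' @return An object of class `ssr_freq`: a list with tibbles
#'   `by_repeat_type` (columns `repeat_type`, `motif_length`, `rep_4` ..
#'   `rep_11`, `rep_ge12`, `total`, `percentage`) and `by_motif_class`
#'   (columns `motif_class`, `motif_length`, same bins, `total`,
#'   `percentage`), plus `grand_total`.
#' @export
tabulate_frequencies <- function(loci) {
  stopifnot(all(c("motif", "repeats") %in% names(loci)))
  grand <- nrow(loci)
  if (grand > 0L) {
    binned <- tibble::tibble(
      motif_length = nchar(loci$motif),
      bin = pmin(pmax(loci$repeats, 4L), 12L),
      class_label = vapply(loci$motif,
                           \(m) canonical_motif_class(m)$label, character(1),
                           USE.NAMES = FALSE),
      class_key = vapply(loci$motif,
                         \(m) canonical_motif_class(m)$key, character(1),
                         USE.NAMES = FALSE)
    )
  } else {
    binned <- tibble::tibble(motif_length = integer(), bin = integer(),
                             class_label = character(),
                             class_key = character())
  }

  by_type <- tidyr::crossing(motif_length = 1:6, bin = repeat_bins()) |>
    dplyr::left_join(dplyr::count(binned, .data$motif_length, .data$bin),
                     by = c("motif_length", "bin")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n",
                       names_prefix = "rep_") |>
    dplyr::rename(rep_ge12 = "rep_12") |>
    dplyr::mutate(repeat_type = repeat_type_names()[.data$motif_length],
                  .before = 1)

  by_class <- if (grand == 0L) {
    empty <- tibble::tibble(motif_class = character(),
                            motif_length = integer())
    for (b in bin_labels()) empty[[paste0("rep_", b)]] <- integer()
    empty
  } else binned |>
    dplyr::count(.data$class_key, .data$class_label, .data$motif_length,
                 .data$bin) |>
    tidyr::complete(tidyr::nesting(class_key, class_label, motif_length),
                    bin = repeat_bins(), fill = list(n = 0L)) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n",
                       names_prefix = "rep_") |>
    dplyr::rename(rep_ge12 = "rep_12") |>
    dplyr::arrange(.data$motif_length, .data$class_key) |>
    dplyr::select(motif_class = "class_label", "motif_length",
                  dplyr::starts_with("rep_"))

  add_margins <- function(tb) {
    bins <- dplyr::select(tb, dplyr::starts_with("rep_"))
    tb$total <- as.integer(rowSums(bins))
    tb$percentage <- if (grand > 0L) {
      round_half_up(tb$total / grand * 100, 2)
    } else {
      rep(0, nrow(tb))
    }
    tb
  }

  structure(list(by_repeat_type = add_margins(by_type),
                 by_motif_class = add_margins(by_class),
                 grand_total = grand),
            class = "ssr_freq")
}

#' @export
print.ssr_freq <- function(x, ...) {
  cat("SSR frequency tables (", x$grand_total, " loci)\n", sep = "")
  cat("\nBy repeat type:\n")
  print(x$by_repeat_type, n = Inf)
  cat("\nBy motif class:\n")
  print(x$by_motif_class, n = Inf)
  invisible(x)
}

#' Count loci at or above a repeat-unit cutoff
#'
#' Sums the repeat-count bins of a frequency matrix row at or above
#' `min_units`, e.g. to count the dinucleotide loci with 8 or more repeat
#' units (the length range where polymorphism is expected to be highest).
#'
#' @param freq An `ssr_freq` object from [tabulate_frequencies()].
#' @param motif_len Motif length (row) to sum, 1-6.
#' @param min_units Minimum number of repeat units; must be >= 4 (the
#'   smallest bin).  Values above all bins give 0.
#' @return Integer count.
#' @examples
#' loci <- expand_locus_counts(onipae_ssr_counts())
#' count_high_repeat_loci(tabulate_frequencies(loci), 2, 8)
#' @export
count_high_repeat_loci <- function(freq, motif_len, min_units) {
  stopifnot(inherits(freq, "ssr_freq"), motif_len %in% 1:6)
  if (min_units < 4L) {
    stop_ssrkit("min_units below the smallest tabulated bin (4)")
  }
  if (min_units > 12L) return(0L)
  row <- freq$by_repeat_type[freq$by_repeat_type$motif_length == motif_len, ]
  keep <- bin_labels()[repeat_bins() >= min_units]
  sum(unlist(row[paste0("rep_", keep)]))
}

#' Expand a motif x repeat-count table into a locus multiset
#'
#' Published SSR surveys report counts of loci per motif (or motif class)
#' and repeat number rather than individual loci.  This helper expands such
#' a count table into one row per locus so it can be fed to
#' [tabulate_frequencies()].
#'
#' @param counts Tibble with columns `motif`, `repeats`, `n`.
#' @return Tibble of `n`-weighted locus rows with columns `seq_id`
#'   (synthesised), `motif`, `repeats`.
#' @export
expand_locus_counts <- function(counts) {
  stopifnot(all(c("motif", "repeats", "n") %in% names(counts)))
  out <- tidyr::uncount(counts[c("motif", "repeats", "n")], weights = .data$n)
  tibble::tibble(seq_id = sprintf("locus_%05d", seq_len(nrow(out))),
                 motif = out$motif, repeats = out$repeats)
}
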