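#' Minimum-repeat thresholds for SSR mining
#'
#' Default minimum numbers of full motif copies for a run to be reported,
#' by motif length 1-6: 12, 6, 5, 5, 4, 4 (the conventional settings for
#' transcriptome SSR surveys).
#'
#' @param min_repeats Integer vector of length 6: minimum full-copy counts
#'   for motif lengths 1 through 6.  All values must be >= 2.
#' @return A named integer vector (names "1".."6") of class
#'   `ssr_thresholds`.
#' @examples
#' ssr_thresholds()
#' ssr_thresholds(c(10, 6, 5, 5, 4, 4))
#' @export
ssr_thresholds <- function(min_repeats = c(12L, 6L, 5L, 5L, 4L, 4L)) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || anyNA(min_repeats) ||
      any(min_repeats < 2L)) {
    stop_ssrkit("min_repeats must be 6 integers, all >= 2")
  }
  structure(stats::setNames(min_repeats, as.character(1:6)),
            class = "ssr_thresholds")
}

#' Find maximal perfect microsatellites in one sequence
#'
#' Scans a nucleotide sequence for maximal perfect tandem repeats of
#' primitive motifs of length 1-6 whose number of full copies meets the
#' per-length threshold.  Each repeat run is reported exactly once, under
#' its shortest primitive period (a poly-A run is never additionally
#' reported as an AA or AAA repeat).  Partial trailing motif copies are
#' truncated: they count neither toward `repeats` nor toward the reported
#' interval.  Characters other than A, C, G, T (including N) break runs;
#' the fragments on either side are scored independently.  Only the given
#' strand is scanned.
#'
#' @param seq A single uppercase nucleotide string.
#' @param seq_id Identifier to attach to the output rows.
#' @param thresholds An [ssr_thresholds()] vector.
#' @return A tibble with one row per detected locus, ordered by `start`:
#'   columns `seq_id`, `motif`, `repeats`, `start`, `end`, `length_bp`
#'   (coordinates 1-based inclusive).
#' @examples
#' find_perfect_ssrs("TTACGACGACGACGACGAA")
#' @export
find_perfect_ssrs <- function(seq, seq_id = "seq",
                              thresholds = ssr_thresholds()) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (!inherits(thresholds, "ssr_thresholds")) {
    thresholds <- ssr_thresholds(thresholds)
  }
  if (nchar(seq) == 0L) return(empty_ssr_tbl())
  if (seq != toupper(seq)) stop_ssrkit("sequence must be uppercase")

  # split into ACGT-only segments; anything else breaks runs
  segs <- gregexpr("[ACGT]+", seq)[[1]]
  if (segs[1] == -1L) return(empty_ssr_tbl())
  starts <- as.integer(segs)
  lens <- attr(segs, "match.length")

  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    frag <- substr(seq, starts[i], starts[i] + lens[i] - 1L)
    out[[i]] <- scan_fragment(frag, offset = starts[i] - 1L,
                              thresholds = thresholds)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_ssr_tbl())
  res$seq_id <- seq_id
  res |>
    dplyr::arrange(.data$start, .data$end) |>
    dplyr::select("seq_id", "motif", "repeats", "start", "end", "length_bp")
}

empty_ssr_tbl <- function() {
  tibble::tibble(seq_id = character(), motif = character(),
                 repeats = integer(), start = integer(), end = integer(),
                 length_bp = integer())
}

# core scanner for an ACGT-only fragment; offset shifts coordinates back
# to the parent sequence
scan_fragment <- function(frag, offset, thresholds) {
  L <- nchar(frag)
  chars <- strsplit(frag, "", fixed = TRUE)[[1]]
  hits <- list()
  for (k in 1:6) {
    thr <- thresholds[[k]]
    if (L < k * thr) next
    eq <- chars[seq_len(L - k)] == chars[(k + 1L):L]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      run_start <- pos[j]
      region_len <- r$lengths[j] + k     # matched lag-k run spans this many bp
      copies <- region_len %/% k
      if (copies < thr) next
      motif <- substr(frag, run_start, run_start + k - 1L)
      if (!is_primitive(motif)) next
      hits[[length(hits) + 1L]] <- list(
        motif = motif, repeats = copies,
        start = run_start + offset,
        end = run_start + copies * k - 1L + offset,
        length_bp = copies * k
      )
    }
  }
  if (length(hits) == 0L) return(empty_ssr_tbl()[, -1])
  dplyr::bind_rows(lapply(hits, tibble::as_tibble))
}

#' Mine a FASTA file for perfect microsatellites
#'
#' Batch wrapper around [find_perfect_ssrs()]: scans every record of a
#' FASTA file, annotates each locus with its canonical motif class, and
#' returns the concatenated locus table plus a per-motif-length tally.
#'
#' @param path FASTA file path.
#' @param thresholds An [ssr_thresholds()] vector.
#' @return A list with elements `loci` (tibble: `seq_id`, `motif`,
#'   `canonical_class`, `repeats`, `start`, `end`, `length_bp`) and
#'   `tally` (tibble: `motif_length`, `n_loci`).
#' @export
mine_fasta <- function(path, thresholds = ssr_thresholds()) {
  records <- read_fasta(path)
  loci <- purrr::map2(records$seq, records$id,
                      \(s, id) find_perfect_ssrs(s, id, thresholds)) |>
    dplyr::bind_rows()
  loci <- annotate_motif_class(loci)
  tally <- tibble::tibble(motif_length = 1:6) |>
    dplyr::left_join(
      loci |>
        dplyr::count(motif_length = nchar(.data$motif), name = "n_loci"),
      by = "motif_length") |>
    dplyr::mutate(n_loci = tidyr::replace_na(.data$n_loci, 0L))
  list(loci = loci, tally = tally)
}

# attach canonical_class column after motif (classification is a display /
# tabulation concern; detection stays strand-literal)
annotate_motif_class <- function(loci) {
  if (nrow(loci) == 0L) {
    return(tibble::add_column(loci, canonical_class = character(),
                              .after = "motif"))
  }
  classes <- vapply(unique(loci$motif),
                    function(m) canonical_motif_class(m)$label, character(1))
  tibble::add_column(loci,
                     canonical_class = unname(classes[loci$motif]),
                     .after = "motif")
}
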