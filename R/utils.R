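#' Round half away from zero
#'
#' Standard commercial rounding (0.005 -> 0.01), as used in the printed
#' report tables; base [round()] rounds half to even, which disagrees with
#' typical published tables on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exact halves after
  # decimal arithmetic (e.g. 43.555000000000007) still round up
  trunc(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

# reverse complement of an ACGT word (vectorised)
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# all cyclic rotations of a word
rotations <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  doubled <- paste0(motif, motif)
  unique(vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
                character(1)))
}

# TRUE if the word is not a whole-number repetition of a shorter word
is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k <= 1L) return(k == 1L)
  divs <- seq_len(k - 1L)
  divs <- divs[k %% divs == 0L]
  for (d in divs) {
    unit <- substr(motif, 1L, d)
    if (strrep(unit, k %/% d) == motif) return(FALSE)
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ssrkit <- function(...) stop(..., call. = FALSE)
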