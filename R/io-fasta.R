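#' Read a FASTA file into a tibble of sequence records
#'
#' Parses a (multi-record, wrapped or unwrapped) nucleotide FASTA file and
#' returns one row per record.  Sequences are uppercased on ingest; line
#' folding and whitespace are removed.  Record identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' Ambiguity codes (IUPAC) are accepted; anything outside the IUPAC
#' nucleotide alphabet is rejected with the offending position.  Downstream
#' repeat mining treats any character other than A, C, G, T as a run
#' breaker.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   uppercase).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acg", "tt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ssrkit("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_ssrkit("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop_ssrkit("empty sequence id in FASTA file: ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_ssrkit("duplicate sequence id in FASTA file: ",
                paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  iupac <- "ACGTNRYSWKMBDHV"
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", iupac), seqs[[i]])
    if (bad > 0L) {
      stop_ssrkit("non-IUPAC character '", substr(seqs[[i]], bad, bad),
                  "' in sequence '", ids[[i]], "' at position ", bad)
    }
    if (nchar(seqs[[i]]) == 0L) {
      stop_ssrkit("zero-length sequence: '", ids[[i]], "'")
    }
  }
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
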