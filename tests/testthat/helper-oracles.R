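# Independent brute-force oracle for perfect-SSR detection.
#
# For every start position and period, extends by whole-motif substring
# comparison (not the lag-k character scan the package uses), keeps runs
# whose primitive motif meets the threshold, and keeps only left-maximal
# starts (the position one base left must not continue the periodicity).
brute_force_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  L <- nchar(seq)
  rows <- list()
  for (a in seq_len(L)) {
    for (k in 1:6) {
      if (a + k - 1L > L) next
      motif <- substr(seq, a, a + k - 1L)
      if (grepl("[^ACGT]", motif)) next
      if (!ssrkit:::is_primitive(motif)) next
      m <- 1L
      while (a + (m + 1L) * k - 1L <= L &&
             substr(seq, a + m * k, a + (m + 1L) * k - 1L) == motif) {
        m <- m + 1L
      }
      if (m < thresholds[[k]]) next
      # left-maximality: s[a-1] must not extend the period-k run
      if (a > 1L &&
          substr(seq, a - 1L, a - 1L) == substr(seq, a + k - 1L, a + k - 1L)) {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, repeats = m, start = a, end = a + m * k - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer())
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# random test sequences with enough repeat structure to exercise the miner:
# uniform ACGT stretches interleaved with short tandem expansions
random_repeat_rich_seq <- function(max_len = 200L) {
  pieces <- character(0)
  len <- 0L
  target <- sample(20:max_len, 1L)
  bases <- c("A", "C", "G", "T")
  while (len < target) {
    if (stats::runif(1) < 0.5) {
      w <- sample(5:20, 1L)
      pieces <- c(pieces, paste(sample(bases, w, replace = TRUE,
                                       prob = c(0.35, 0.15, 0.15, 0.35)),
                                collapse = ""))
    } else {
      k <- sample(1:6, 1L)
      motif <- paste(sample(bases, k, replace = TRUE), collapse = "")
      reps <- sample(2:13, 1L)
      pieces <- c(pieces, strrep(motif, reps))
    }
    len <- sum(nchar(pieces))
  }
  substr(paste(pieces, collapse = ""), 1L, target)
}

# build a one-locus genotype tibble from genotype counts, e.g.
# make_genotypes("1/1" = 11, "1/2" = 1)
make_genotypes <- function(..., pop = "P", locus = "L1") {
  counts <- c(...)
  a1 <- integer(0)
  a2 <- integer(0)
  for (nm in names(counts)) {
    pair <- as.integer(strsplit(nm, "/", fixed = TRUE)[[1]])
    a1 <- c(a1, rep(pair[1], counts[[nm]]))
    a2 <- c(a2, rep(pair[2], counts[[nm]]))
  }
  tibble::tibble(pop = pop, ind = sprintf("%s_%03d", pop, seq_along(a1)),
                 locus = locus, a1 = a1, a2 = a2)
}

# all distinct allele-count multisets {m_1 >= ... >= m_k >= 1} summing to s
allele_count_partitions <- function(s, max_parts) {
  rec <- function(s, max_part, parts_left) {
    if (s == 0L) return(list(integer(0)))
    if (parts_left == 0L) return(list())
    out <- list()
    for (first in seq_len(min(s, max_part))) {
      for (rest in rec(s - first, first, parts_left - 1L)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  rec(s, s, max_parts)
}
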