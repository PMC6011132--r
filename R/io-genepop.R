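#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP text dialect: a title line, one locus name per
#' line (or a single comma-separated line), then one block per population
#' introduced by a line equal to `Pop` (case-insensitive).  Individual lines
#' are `id , g1 g2 ...` with one fixed-width genotype field per locus; the
#' allele-code width (2- or 3-digit) is auto-detected from the field width
#' (4 characters = 2-digit codes, 6 characters = 3-digit codes).  Allele
#' code 0 (`00`/`000`) marks a missing allele; a call containing a 0 is
#' treated as missing.
#'
#' By GENEPOP convention each population is named after the id of the last
#' individual in its block; supply `pop_names` to override.
#'
#' @param path Path to a GENEPOP file.
#' @param pop_names Optional character vector naming the populations in
#'   file order (overrides the last-individual-id convention).
#' @return A long tibble with one row per individual x locus: columns
#'   `pop`, `ind`, `locus`, `a1`, `a2` (integer allele codes, `NA` for
#'   missing calls).  Row order follows the file; `a1 <= a2` is not
#'   enforced (codes are kept as written).
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop_ssrkit("GENEPOP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) < 3L) stop_ssrkit("GENEPOP file too short: ", path)
  lines <- lines[nonblank]

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop_ssrkit("no 'Pop' line found after the locus list in ", path)
  }
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- if (length(locus_lines) == 1L && grepl(",", locus_lines)) {
    trimws(strsplit(locus_lines, ",")[[1]])
  } else {
    locus_lines
  }
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop_ssrkit("duplicate locus names in ", path)
  n_loci <- length(loci)

  blocks <- cumsum(is_pop)
  ind_idx <- which(blocks > 0L & !is_pop)
  if (length(ind_idx) == 0L) stop_ssrkit("no individuals in ", path)

  width <- NA_integer_
  rows <- vector("list", length(ind_idx))
  for (j in seq_along(ind_idx)) {
    i <- ind_idx[[j]]
    line <- lines[[i]]
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop_ssrkit("line ", nonblank[i], ": expected 'id , genotypes'")
    }
    id <- trimws(parts[[1]])
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[ \t]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != n_loci) {
      stop_ssrkit("line ", nonblank[i], ": individual '", id, "' has ",
                  length(fields), " genotype fields, expected ", n_loci)
    }
    w <- unique(nchar(fields))
    if (length(w) != 1L || !w %in% c(4L, 6L)) {
      stop_ssrkit("line ", nonblank[i], ": genotype field width ",
                  paste(w, collapse = "/"),
                  " not a fixed 4 or 6 characters")
    }
    if (is.na(width)) width <- w
    if (w != width) {
      stop_ssrkit("line ", nonblank[i],
                  ": mixed allele-code widths within one file")
    }
    if (any(!grepl("^[0-9]+$", fields))) {
      stop_ssrkit("line ", nonblank[i], ": non-numeric genotype field")
    }
    half <- width %/% 2L
    a1 <- as.integer(substr(fields, 1L, half))
    a2 <- as.integer(substr(fields, half + 1L, width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    rows[[j]] <- tibble::tibble(block = blocks[[i]], ind = id,
                                locus = loci, a1 = a1, a2 = a2)
  }
  out <- dplyr::bind_rows(rows)

  last_ids <- out |>
    dplyr::distinct(.data$block, .data$ind) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(name = dplyr::last(.data$ind), .groups = "drop")
  if (!is.null(pop_names)) {
    if (length(pop_names) != nrow(last_ids)) {
      stop_ssrkit("pop_names has length ", length(pop_names), " but file has ",
                  nrow(last_ids), " populations")
    }
    last_ids$name <- pop_names
  }
  out |>
    dplyr::left_join(last_ids, by = "block") |>
    dplyr::transmute(pop = .data$name, ind = .data$ind, locus = .data$locus,
                     a1 = .data$a1, a2 = .data$a2)
}

#' Write genotypes to a GENEPOP file
#'
#' Emits 3-digit allele codes (`000000` for missing calls), one locus name
#' per line, and one `Pop` block per population in order of first
#' appearance.
#'
#' @param genotypes Long tibble with columns `pop`, `ind`, `locus`, `a1`,
#'   `a2` (as from [read_genepop()] or [simulate_genotypes()]).
#' @param path Output path.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path, title = "ssrkit genotypes") {
  stopifnot(all(c("pop", "ind", "locus", "a1", "a2") %in% names(genotypes)))
  codes <- c(genotypes$a1, genotypes$a2)
  if (any(codes > 999L, na.rm = TRUE)) {
    stop_ssrkit("allele code > 999 cannot be represented in GENEPOP")
  }
  loci <- unique(genotypes$locus)
  pops <- unique(genotypes$pop)
  enc <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (p in pops) {
    writeLines("Pop", con)
    sub <- genotypes[genotypes$pop == p, , drop = FALSE]
    for (id in unique(sub$ind)) {
      g <- sub[sub$ind == id, , drop = FALSE]
      g <- g[match(loci, g$locus), , drop = FALSE]
      if (anyNA(g$locus)) {
        stop_ssrkit("individual '", id, "' lacks calls for some loci")
      }
      fields <- paste0(enc(g$a1), enc(g$a2))
      writeLines(paste0(id, " ,  ", paste(fields, collapse = " ")), con)
    }
  }
  invisible(path)
}
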