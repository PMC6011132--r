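#' Pipeline run configuration
#'
#' Bundles every tunable of the discovery and evaluation pipelines:
#' mining thresholds, primer constraints, test settings and output
#' location.  Serialises losslessly to a flat `key=value` text file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param thresholds An [ssr_thresholds()] vector.
#' @param constraints A [primer_constraints()] list.
#' @param n_permutations Permutations for the LD test.
#' @param seed Master RNG seed for seeded stages.
#' @param adjust_method Multiple-testing correction for batched tests.
#' @param top_k Primer candidates kept per locus.
#' @param out_dir Output directory for report bundles.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = ssr_thresholds(),
                       constraints = primer_constraints(),
                       n_permutations = 1000L, seed = 1L,
                       adjust_method = c("bonferroni", "holm", "bh"),
                       top_k = 3L, out_dir = ".", log_level = "info") {
  adjust_method <- match.arg(adjust_method)
  structure(list(thresholds = thresholds, constraints = constraints,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), adjust_method = adjust_method,
                 top_k = as.integer(top_k), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Write a run configuration as flat key=value text
#'
#' @param config A [run_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cn <- config$constraints
  kv <- c(
    min_repeats = paste(unclass(config$thresholds), collapse = ","),
    product_min = cn$product_min, product_max = cn$product_max,
    primer_min = cn$primer_min, primer_max = cn$primer_max,
    primer_opt = cn$primer_opt,
    gc_min = cn$gc_min, gc_max = cn$gc_max,
    tm_min = cn$tm_min, tm_max = cn$tm_max,
    max_tm_diff = cn$max_tm_diff, w_tm = cn$w_tm, w_gc = cn$w_gc,
    max_complement_run = cn$max_complement_run,
    n_permutations = config$n_permutations, seed = config$seed,
    adjust_method = config$adjust_method, top_k = config$top_k,
    out_dir = config$out_dir, log_level = config$log_level)
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' Read a run configuration from flat key=value text
#'
#' @param path Path written by [write_run_config()].
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
  num <- function(key) as.numeric(vals[[key]])
  int <- function(key) as.integer(vals[[key]])
  run_config(
    thresholds = ssr_thresholds(
      as.integer(strsplit(vals[["min_repeats"]], ",")[[1]])),
    constraints = primer_constraints(
      product_min = int("product_min"), product_max = int("product_max"),
      primer_min = int("primer_min"), primer_max = int("primer_max"),
      primer_opt = int("primer_opt"), gc_min = num("gc_min"),
      gc_max = num("gc_max"), tm_min = num("tm_min"),
      tm_max = num("tm_max"), max_tm_diff = num("max_tm_diff"),
      w_tm = num("w_tm"), w_gc = num("w_gc"),
      max_complement_run = int("max_complement_run")),
    n_permutations = int("n_permutations"), seed = int("seed"),
    adjust_method = vals[["adjust_method"]], top_k = int("top_k"),
    out_dir = vals[["out_dir"]], log_level = vals[["log_level"]])
}

config_hash <- function(config) {
  # hash the scientific settings only: where the bundle lands and how
  # chatty the run is do not change the results
  norm <- config
  norm$out_dir <- ""
  norm$log_level <- "info"
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf))
  write_run_config(norm, tf)
  unname(tools::md5sum(tf))
}

# every report file starts with a comment naming the config hash and seed
write_report_tsv <- function(tbl, path, hash, seed) {
  writeLines(sprintf("# ssrkit config_hash=%s seed=%d", hash, seed), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline report TSV
#'
#' @param path A TSV written by the pipeline (leading `#` comment lines
#'   carry the config hash and seed).
#' @return Tibble.
#' @export
read_report_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

pipeline_log <- function(config, lines, file) {
  if (identical(config$log_level, "quiet")) return(invisible())
  cat(lines, sep = "\n", file = file, append = TRUE)
  invisible()
}

#' Run the marker-discovery pipeline
#'
#' mine -> classify -> primers: scans a FASTA file for perfect
#' microsatellites, tabulates the repeat-type and motif-class frequency
#' matrices, screens primer candidates for every non-mononucleotide locus,
#' and writes the four report files plus a run log into
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param fasta Path to the input FASTA.
#' @return Invisibly, a list with the output `paths` and the computed
#'   tibbles (`loci`, `freq`, `primers`).
#' @export
run_marker_discovery <- function(config, fasta) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_file <- file.path(config$out_dir, "discovery_log.txt")
  if (file.exists(log_file)) unlink(log_file)
  pipeline_log(config, c(
    sprintf("ssrkit %s marker discovery", as.character(utils::packageVersion("ssrkit"))),
    sprintf("R %s", getRversion()),
    sprintf("config_hash=%s seed=%d", hash, config$seed),
    sprintf("fasta=%s", fasta),
    sprintf("min_repeats=%s", paste(unclass(config$thresholds),
                                    collapse = ","))), log_file)

  mined <- tryCatch(mine_fasta(fasta, config$thresholds),
                    error = function(e) {
                      stop_ssrkit("mine stage failed: ",
                                  conditionMessage(e))
                    })
  records <- read_fasta(fasta)
  freq <- tabulate_frequencies(mined$loci)

  primer_rows <- list()
  loci <- mined$loci
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    if (nchar(lc$motif) == 1L) next
    seq <- records$seq[records$id == lc$seq_id][[1]]
    cand <- screen_primer_pairs(seq, lc, config$constraints,
                                top_k = config$top_k)
    if (nrow(cand) > 0L) {
      primer_rows[[length(primer_rows) + 1L]] <- tibble::add_column(
        cand, seq_id = lc$seq_id, motif = lc$motif,
        ssr_start = lc$start, ssr_end = lc$end, .before = 1)
    }
  }
  primers <- dplyr::bind_rows(primer_rows)
  if (nrow(primers) == 0L) {
    primers <- tibble::tibble(seq_id = character(), motif = character(),
                              ssr_start = integer(), ssr_end = integer())
  }

  paths <- c(
    loci = write_report_tsv(mined$loci,
                            file.path(config$out_dir, "ssr_loci.tsv"),
                            hash, config$seed),
    by_repeat_type = write_report_tsv(
      freq$by_repeat_type,
      file.path(config$out_dir, "freq_by_repeat_type.tsv"), hash,
      config$seed),
    by_motif_class = write_report_tsv(
      freq$by_motif_class,
      file.path(config$out_dir, "freq_by_motif_class.tsv"), hash,
      config$seed),
    primers = write_report_tsv(primers,
                               file.path(config$out_dir, "primers.tsv"),
                               hash, config$seed))
  pipeline_log(config, sprintf("loci=%d primers=%d", nrow(mined$loci),
                               nrow(primers)), log_file)
  invisible(list(paths = paths, loci = mined$loci, freq = freq,
                 primers = primers))
}

#' Run the marker-evaluation pipeline
#'
#' genepop -> summary statistics -> HWE -> LD: reads a GENEPOP genotype
#' file, computes per-locus marker statistics and panel means, runs
#' Hardy-Weinberg exact tests per locus and genotypic LD permutation
#' tests per locus pair (with adjusted p-value columns), and writes the
#' report files into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param genepop Path to the input GENEPOP file.
#' @return Invisibly, a list with the output `paths` and the computed
#'   tibbles (`panel`, `hwe`, `ld`).
#' @export
run_marker_evaluation <- function(config, genepop) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_file <- file.path(config$out_dir, "evaluation_log.txt")
  if (file.exists(log_file)) unlink(log_file)
  pipeline_log(config, c(
    sprintf("ssrkit %s marker evaluation", as.character(utils::packageVersion("ssrkit"))),
    sprintf("config_hash=%s seed=%d", hash, config$seed),
    sprintf("genepop=%s adjust=%s permutations=%d", genepop,
            config$adjust_method, config$n_permutations)), log_file)

  genotypes <- tryCatch(read_genepop(genepop),
                        error = function(e) {
                          stop_ssrkit("genepop stage failed: ",
                                      conditionMessage(e))
                        })
  panel <- summarize_panel(genotypes)
  hwe <- hwe_test_all(genotypes, seed = config$seed)
  hwe$p_adjusted <- multiple_test_adjust(hwe$p_probability,
                                         config$adjust_method)
  ld <- ld_test_all(genotypes, n_permutations = config$n_permutations,
                    seed = config$seed)
  if (nrow(ld) > 0L) {
    ld$p_adjusted <- multiple_test_adjust(ld$p_value, config$adjust_method)
  }

  summary_out <- panel$summaries |>
    dplyr::mutate(dplyr::across(c("ho", "he", "pic"),
                                \(x) round_half_up(x, 3))) |>
    dplyr::left_join(hwe |> dplyr::select("pop", "locus", "p_probability"),
                     by = c("pop", "locus")) |>
    dplyr::rename(hwe_p = "p_probability")

  paths <- c(
    summary = write_report_tsv(summary_out,
                               file.path(config$out_dir,
                                         "locus_summary.tsv"),
                               hash, config$seed),
    means = write_report_tsv(panel$means,
                             file.path(config$out_dir, "panel_means.tsv"),
                             hash, config$seed),
    hwe = write_report_tsv(hwe, file.path(config$out_dir, "hwe.tsv"),
                           hash, config$seed),
    ld = write_report_tsv(ld, file.path(config$out_dir, "ld.tsv"),
                          hash, config$seed))
  invisible(list(paths = paths, panel = panel, hwe = hwe, ld = ld))
}
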