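#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV or CSV file whose first column holds gene identifiers and
#' whose header row names the samples (gzip is handled transparently).
#' Ingest applies the package's cleaning rules: duplicated gene rows are
#' collapsed by their mean (with a warning), negative values -- which can
#' arise from background-subtracted microarray intensities -- are floored
#' at zero (with a warning), and empty cells or duplicated sample names are
#' errors.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  df <- suppressWarnings(
    reader(path, col_types = readr::cols(.default = readr::col_character()),
           name_repair = "minimal", progress = FALSE)
  )
  if (ncol(df) < 2L) abort(sprintf("%s: need a gene column plus at least one sample column.", path))
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) {
    abort(sprintf("%s: duplicated sample identifier(s): %s", path,
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  genes <- df[[1L]]
  vals <- lapply(seq_along(samples), function(j) {
    col <- df[[j + 1L]]
    blank <- which(is.na(col) | col == "")
    if (length(blank)) {
      abort(sprintf("%s: empty cell in column '%s' at data line %d.",
                    path, samples[j], blank[1L]))
    }
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value '%s' in column '%s' at data line %d.",
                    path, col[bad[1L]], samples[j], bad[1L]))
    }
    num
  })
  m <- do.call(cbind, vals)
  colnames(m) <- samples
  rownames(m) <- genes
  clean_expression(m, context = path)
}

# Shared cleaning: collapse duplicate gene rows by mean, floor negatives at 0.
clean_expression <- function(m, context = "input") {
  if (any(!is.finite(m))) abort(sprintf("%s: non-finite expression values.", context))
  genes <- rownames(m)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn(sprintf("%s: %d duplicated gene identifier(s) collapsed by mean (e.g. %s).",
                 context, length(dup), dup[1L]))
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  if (any(m < 0)) {
    warn(sprintf("%s: %d negative value(s) floored at 0.", context, sum(m < 0)))
    m[m < 0] <- 0
  }
  expr_tibble(m)
}

#' Read a sample-to-lineage replicate map
#'
#' Two-column TSV (`sample_id`, `lineage_id`) assigning every reference
#' sample to the lineage (cell type) it replicates.
#'
#' @param path Path to the file.
#' @return A tibble with columns `sample` and `lineage`.
#' @export
read_replicate_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("%s: expected two columns (sample, lineage).", path))
  out <- tibble(sample = df[[1L]], lineage = df[[2L]])
  if (anyNA(out$sample) || anyNA(out$lineage)) abort(sprintf("%s: missing entries.", path))
  if (anyDuplicated(out$sample)) {
    abort(sprintf("%s: sample(s) mapped more than once: %s", path,
                  paste(unique(out$sample[duplicated(out$sample)]), collapse = ", ")))
  }
  out
}

#' Write enrichment results to an output directory
#'
#' Writes the standard result bundle: `enrichment_long.tsv` (one row per
#' sample x lineage), `normalized_or_matrix.tsv` (samples x lineages,
#' heatmap-ready), `run_config.json` (the scoring settings), `config_digest.txt`
#' (MD5 of the config file) and `run_log.txt`. Output is deterministic:
#' identical results produce byte-identical files.
#'
#' @param results A `ct_result` object from [score_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  if (!inherits(results, "ct_result") || nrow(results) == 0L) {
    abort("`results` must be a non-empty ct_result from score_cohort().")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  long_path <- file.path(out_dir, "enrichment_long.tsv")
  wide_path <- file.path(out_dir, "normalized_or_matrix.tsv")
  cfg_path <- file.path(out_dir, "run_config.json")
  dig_path <- file.path(out_dir, "config_digest.txt")
  log_path <- file.path(out_dir, "run_log.txt")

  long <- dplyr::select(as_tibble(results), dplyr::all_of(c(
    "sample", "lineage", "n_hits", "null_mean", "p_value",
    "odds_ratio", "norm_odds_ratio")))
  readr::write_tsv(long, long_path)

  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(results), dplyr::all_of(c("sample", "lineage", "norm_odds_ratio"))),
    names_from = "lineage", values_from = "norm_odds_ratio")
  readr::write_tsv(wide, wide_path)

  settings <- attr(results, "settings")
  jsonlite::write_json(settings, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  digest <- unname(tools::md5sum(cfg_path))
  writeLines(digest, dig_path)
  writeLines(c(
    "ctenrich scoring run",
    sprintf("samples: %d", length(unique(long$sample))),
    sprintf("lineages: %d", length(unique(long$lineage))),
    sprintf("config digest: %s", digest)
  ), log_path)
  invisible(c(long_path, wide_path, cfg_path, dig_path, log_path))
}

#' Write a signature map to TSV
#'
#' Columns: `lineage`, `rank` (1-based, most specific first), `gene`,
#' `specificity_index`, `relative_expression`.
#'
#' @param signatures A `ct_signatures` object from [build_signatures()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signatures <- function(signatures, path) {
  if (!inherits(signatures, "ct_signatures")) {
    abort("`signatures` must come from build_signatures().")
  }
  out <- tibble(lineage = signatures$lineage, rank = signatures$rank,
                gene = signatures$gene,
                specificity_index = signatures$specificity,
                relative_expression = signatures$rel_expr)
  readr::write_tsv(out, path)
  invisible(path)
}
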