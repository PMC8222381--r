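# Internal helpers shared across the package.

# Convert a gene-by-sample tibble (first column = gene identifier, remaining
# columns numeric) into a numeric matrix with gene rownames.
expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort(sprintf("`%s` matrix must have gene rownames.", arg))
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame (gene column first) or a matrix.", arg))
  }
  if (ncol(x) < 2L) abort(sprintf("`%s` needs a gene column plus at least one sample column.", arg))
  genes <- as.character(x[[1L]])
  if (anyDuplicated(genes)) {
    abort(sprintf("`%s` contains duplicated gene identifiers; collapse them first (see read_expression_matrix()).", arg))
  }
  vals <- x[-1L]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(bad)) {
    abort(sprintf("Non-numeric sample column(s) in `%s`: %s", arg, paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# Back-convert to the canonical tibble layout.
expr_tibble <- function(m, gene_col = "gene") {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(!!gene_col := rownames(m)), out)
}

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

check_count <- function(x, arg, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

check_fraction <- function(x, arg) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", arg))
  }
  as.numeric(x)
}
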