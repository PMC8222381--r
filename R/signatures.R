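#' Relative expression of genes across lineages
#'
#' For each gene g and lineage l, the relative expression is
#' `p(l|g) = x(g,l) / sum_l' x(g,l')`, the share of the gene's total atlas
#' expression found in lineage l. Genes whose atlas row sums to zero have
#' undefined relative expression and are flagged (`defined = FALSE`); they
#' are excluded from signature candidacy.
#'
#' @param atlas A `ct_atlas` from [average_replicates()] (or any gene x
#'   lineage tibble / matrix).
#' @param genes Optional character vector restricting the output; unknown
#'   genes are an error.
#' @return A long tibble with columns `gene`, `lineage`, `rel_expr`,
#'   `defined`.
#' @export
relative_expression <- function(atlas, genes = NULL) {
  m <- expr_matrix(atlas, "atlas")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(sprintf("Gene(s) not in the atlas: %s", paste(missing, collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  rs <- rowSums(m)
  p <- m / ifelse(rs > 0, rs, 1)
  p[rs == 0, ] <- NA_real_
  tibble(
    gene = rep(rownames(m), times = ncol(m)),
    lineage = rep(colnames(m), each = nrow(m)),
    rel_expr = as.vector(p),
    defined = rep(rs > 0, times = ncol(m))
  )
}

#' Entropy-based specificity index
#'
#' Given a gene's relative-expression vector p over N lineages, the
#' specificity index of the gene for lineage l is
#' `S(l|g) = H(g) - log2 p(l|g)`, where `H(g) = -sum_l p log2 p` is the
#' Shannon entropy of the gene's expression distribution (with
#' `0 * log2(0) := 0`). S is 0 if and only if the gene is expressed
#' exclusively in lineage l (`p(l|g) = 1`), equals `2 * log2(N)` for every
#' lineage when expression is uniform, and is `+Inf` where `p(l|g) = 0`.
#' Smaller S means more specific.
#'
#' @param p Numeric probability vector (non-negative, sums to 1 within
#'   1e-9).
#' @param lineage Optional index or name selecting a single lineage;
#'   default returns S for every lineage.
#' @return Numeric vector of specificity indices (length of `p`, or 1 if
#'   `lineage` is given).
#' @examples
#' specificity_index(c(1, 0, 0))            # 0, Inf, Inf
#' specificity_index(rep(0.25, 4))          # all 4 = 2*log2(4)
#' @export
specificity_index <- function(p, lineage = NULL) {
  if (!is.numeric(p) || length(p) < 2L) abort("`p` must be a numeric vector of length >= 2.")
  if (anyNA(p) || any(p < 0)) abort("`p` must be non-negative with no missing values.")
  if (abs(sum(p) - 1) > 1e-9) abort("`p` must sum to 1 (tolerance 1e-9).")
  terms <- ifelse(p > 0, p * log2(p), 0)
  H <- -sum(terms)
  S <- H - log2(p)   # +Inf where p == 0
  names(S) <- names(p)
  if (!is.null(lineage)) {
    if (is.character(lineage)) {
      if (!lineage %in% names(p)) abort(sprintf("Unknown lineage '%s'.", lineage))
      return(S[[lineage]])
    }
    return(S[[lineage]])
  }
  S
}

#' Build per-lineage marker signatures from a reference atlas
#'
#' For every lineage, ranks all genes by the specificity index and retains
#' the `signature_size` most specific ones (ascending S; a lineage-exclusive
#' gene has S = 0). Ties are broken deterministically by higher expression
#' in the lineage, then lexicographic gene identifier. Genes with zero
#' atlas row sum are excluded from candidacy. `rank_by = "descending"` is
#' available for completeness but selects the least specific genes.
#'
#' @param atlas A `ct_atlas` from [average_replicates()].
#' @param signature_size Number of marker genes per lineage (default 80).
#' @param rank_by `"ascending"` (most specific first, the default) or
#'   `"descending"`.
#' @return A `ct_signatures` tibble with columns `lineage`, `rank`, `gene`,
#'   `specificity`, `rel_expr`; the atlas gene list is attached as the
#'   default scoring universe.
#' @export
build_signatures <- function(atlas, signature_size = 80,
                             rank_by = c("ascending", "descending")) {
  rank_by <- match.arg(rank_by)
  m <- expr_matrix(atlas, "atlas")
  signature_size <- check_count(signature_size, "signature_size", min = 1L)
  rs <- rowSums(m)
  candidates <- m[rs > 0, , drop = FALSE]
  if (nrow(candidates) < signature_size) {
    abort(sprintf(
      "Only %d gene(s) have defined relative expression; %d needed (short by %d).",
      nrow(candidates), signature_size, signature_size - nrow(candidates)))
  }
  p <- candidates / rowSums(candidates)
  H <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  genes <- rownames(candidates)
  per_lineage <- lapply(colnames(m), function(l) {
    S <- H - log2(p[, l])
    key_s <- if (rank_by == "ascending") S else -S
    ord <- order(key_s, -candidates[, l], genes, method = "radix")
    top <- ord[seq_len(signature_size)]
    tibble(lineage = l, rank = seq_len(signature_size),
           gene = genes[top], specificity = unname(S[top]),
           rel_expr = unname(p[top, l]))
  })
  out <- dplyr::bind_rows(per_lineage)
  attr(out, "signature_size") <- signature_size
  attr(out, "rank_by") <- rank_by
  attr(out, "universe") <- rownames(m)
  class(out) <- c("ct_signatures", class(out))
  out
}

#' @export
print.ct_signatures <- function(x, ...) {
  cat(sprintf("<ct_signatures> %d lineages x %d marker genes\n",
              length(unique(x$lineage)), attr(x, "signature_size")))
  NextMethod()
}

signature_gene_sets <- function(signatures) {
  split(signatures$gene, signatures$lineage)
}
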