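#' Average technical replicates into a reference atlas
#'
#' Collapses a gene-by-sample reference expression matrix into one column
#' per lineage (cell type) by taking the arithmetic mean of each lineage's
#' technical replicates. The result is the reference atlas from which
#' marker signatures are derived.
#'
#' @param expr Expression data: a tibble whose first column is the gene
#'   identifier and whose remaining columns are reference samples (the
#'   layout returned by [read_expression_matrix()]), or a numeric matrix
#'   with gene rownames.
#' @param replicate_map A data frame with columns `sample` and `lineage`
#'   assigning every sample column of `expr` to a lineage.
#' @return A `ct_atlas`: a tibble with a `gene` column and one numeric
#'   column per lineage, carrying the replicate map as an attribute.
#' @examples
#' expr <- tibble::tibble(gene = c("g1", "g2"),
#'                        s1 = c(2, 0), s2 = c(4, 0), s3 = c(1, 5))
#' rep_map <- tibble::tibble(sample = c("s1", "s2", "s3"),
#'                           lineage = c("A", "A", "B"))
#' average_replicates(expr, rep_map)
#' @export
average_replicates <- function(expr, replicate_map) {
  m <- expr_matrix(expr, "expr")
  if (!is.data.frame(replicate_map) || !all(c("sample", "lineage") %in% names(replicate_map))) {
    abort("`replicate_map` must have columns `sample` and `lineage`.")
  }
  rm_ <- tibble(sample = as.character(replicate_map$sample),
                lineage = as.character(replicate_map$lineage))
  if (anyDuplicated(rm_$sample)) abort("`replicate_map` assigns a sample to more than one lineage.")
  unmapped <- setdiff(colnames(m), rm_$sample)
  if (length(unmapped)) {
    abort(sprintf("Sample(s) without a lineage assignment: %s",
                  paste(unmapped, collapse = ", ")))
  }
  rm_ <- rm_[rm_$sample %in% colnames(m), , drop = FALSE]
  lineages <- unique(rm_$lineage)
  if (length(lineages) < 2L) abort("At least 2 lineages are required.")
  avg <- vapply(lineages, function(l) {
    cols <- rm_$sample[rm_$lineage == l]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(avg) <- rownames(m)
  out <- expr_tibble(avg)
  attr(out, "replicate_map") <- rm_
  class(out) <- c("ct_atlas", class(out))
  out
}

atlas_matrix <- function(atlas) {
  expr_matrix(atlas, "atlas")
}

#' Extract one lineage's expression profile from an atlas
#'
#' @param atlas A `ct_atlas` (or any gene x lineage tibble).
#' @param lineage Lineage (column) name.
#' @return A tibble with columns `gene` and `value`, e.g. for use as a
#'   spike-in profile in [spike_transcriptome()].
#' @export
lineage_profile <- function(atlas, lineage) {
  m <- expr_matrix(atlas, "atlas")
  if (!lineage %in% colnames(m)) {
    abort(sprintf("Lineage '%s' not found in the atlas.", lineage))
  }
  tibble(gene = rownames(m), value = m[, lineage])
}

#' @export
print.ct_atlas <- function(x, ...) {
  cat(sprintf("<ct_atlas> %d genes x %d lineages\n", nrow(x), ncol(x) - 1L))
  NextMethod()
}
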