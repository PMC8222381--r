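#' Simulate a reference expression atlas with planted markers
#'
#' Generates a seeded synthetic atlas with known ground truth so the whole
#' estimation pipeline can be validated without external reference data.
#' Each gene gets a baseline expression level drawn from a log-normal
#' distribution (`meanlog = 3`, `sdlog = 1`, emulating right-skewed
#' intensity data); each lineage is assigned `markers_per_lineage`
#' exclusive marker genes whose expected expression is `fold_change` times
#' baseline in that lineage only. Technical replicates receive independent
#' multiplicative log-normal noise with `sdlog = sigma` and unit mean
#' (`meanlog = -sigma^2/2`), so planted expectations are exact.
#'
#' @param n_lineages Number of lineages N (default 6).
#' @param n_genes Number of genes G (default 5000).
#' @param markers_per_lineage Planted marker genes per lineage (default
#'   120; `markers_per_lineage * n_lineages <= n_genes`).
#' @param replicates Technical replicates per lineage (default 3).
#' @param fold_change Marker fold change over baseline (> 1; default 20).
#' @param sigma Replicate noise sdlog (default 0.3).
#' @param baseline_meanlog,baseline_sdlog Baseline log-normal parameters.
#' @param seed Integer seed (default 1).
#' @return A `ct_sim_atlas` list: `expression` (gene x replicate tibble),
#'   `replicate_map`, `markers` (ground-truth marker genes per lineage),
#'   `means` (noiseless gene x lineage expectation matrix, plus a
#'   marker-free `background` column usable as a tissue profile in
#'   [simulate_mixture()]), and the generating parameters.
#' @export
simulate_atlas <- function(n_lineages = 6, n_genes = 5000,
                           markers_per_lineage = 120, replicates = 3,
                           fold_change = 20, sigma = 0.3,
                           baseline_meanlog = 3, baseline_sdlog = 1,
                           seed = 1) {
  n_lineages <- check_count(n_lineages, "n_lineages", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  markers_per_lineage <- check_count(markers_per_lineage, "markers_per_lineage", min = 1L)
  replicates <- check_count(replicates, "replicates", min = 1L)
  if (markers_per_lineage * n_lineages > n_genes) {
    abort("Infeasible: markers_per_lineage * n_lineages exceeds n_genes.")
  }
  if (!is.numeric(fold_change) || fold_change <= 1) abort("`fold_change` must exceed 1.")
  if (!is.numeric(sigma) || sigma < 0) abort("`sigma` must be >= 0.")
  seed <- check_count(seed, "seed")
  set.seed(seed)

  genes <- sprintf("g%05d", seq_len(n_genes))
  lineages <- paste0("L", seq_len(n_lineages))
  baseline <- stats::rlnorm(n_genes, meanlog = baseline_meanlog, sdlog = baseline_sdlog)

  marker_idx <- split(seq_len(markers_per_lineage * n_lineages),
                      rep(seq_len(n_lineages), each = markers_per_lineage))
  means <- matrix(baseline, nrow = n_genes, ncol = n_lineages,
                  dimnames = list(genes, lineages))
  for (l in seq_len(n_lineages)) {
    means[marker_idx[[l]], l] <- means[marker_idx[[l]], l] * fold_change
  }

  sample_ids <- as.vector(t(outer(lineages, seq_len(replicates),
                                  function(l, r) paste0(l, "_rep", r))))
  expr <- matrix(0, nrow = n_genes, ncol = length(sample_ids),
                 dimnames = list(genes, sample_ids))
  for (l in seq_len(n_lineages)) {
    for (r in seq_len(replicates)) {
      noise <- if (sigma > 0) {
        stats::rlnorm(n_genes, meanlog = -sigma^2 / 2, sdlog = sigma)
      } else rep(1, n_genes)
      expr[, (l - 1L) * replicates + r] <- means[, l] * noise
    }
  }

  structure(list(
    expression = expr_tibble(expr),
    replicate_map = tibble(sample = sample_ids,
                           lineage = rep(lineages, each = replicates)),
    markers = setNames(lapply(marker_idx, function(i) genes[i]), lineages),
    means = cbind(means, background = baseline),
    params = list(n_lineages = n_lineages, n_genes = n_genes,
                  markers_per_lineage = markers_per_lineage,
                  replicates = replicates, fold_change = fold_change,
                  sigma = sigma, baseline_meanlog = baseline_meanlog,
                  baseline_sdlog = baseline_sdlog, seed = seed)
  ), class = "ct_sim_atlas")
}

#' @export
print.ct_sim_atlas <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ct_sim_atlas> %d genes x %d lineages x %d replicates (markers %d, fold %.1f, sigma %.2f, seed %d)\n",
    p$n_genes, p$n_lineages, p$replicates, p$markers_per_lineage,
    p$fold_change, p$sigma, p$seed))
  invisible(x)
}

#' Simulate query bulk mixtures with known composition
#'
#' Builds query samples as weighted mixtures of the synthetic atlas's
#' noiseless lineage mean profiles (each first normalized to sum 1), scaled
#' to a sequencing-depth total T, with one round of multiplicative
#' log-normal noise (unit mean) at the sample level -- so the ground-truth
#' weights are exact in expectation. The pseudo-lineage `"background"`
#' (the marker-free baseline profile) can carry weight to emulate bulk
#' tissue whose dominant content is not represented by any atlas lineage.
#'
#' @param sim A `ct_sim_atlas` from [simulate_atlas()].
#' @param weights Named non-negative weights over the atlas lineages (and
#'   optionally `"background"`), summing to 1 within 1e-9. Either a single
#'   vector recycled for all samples, or a matrix/data frame with one row
#'   per sample.
#' @param n_samples Number of samples (default 1; ignored when `weights`
#'   has rows).
#' @param total Sequencing-depth total T (default 1e6).
#' @param sigma Sample-level noise sdlog (default 0.3).
#' @param seed Integer seed (default 1).
#' @param sample_prefix Prefix for generated sample names.
#' @return A gene x sample tibble of query expression.
#' @export
simulate_mixture <- function(sim, weights, n_samples = 1, total = 1e6,
                             sigma = 0.3, seed = 1, sample_prefix = "mix") {
  if (!inherits(sim, "ct_sim_atlas")) abort("`sim` must come from simulate_atlas().")
  profiles <- sim$means
  profiles <- sweep(profiles, 2L, colSums(profiles), "/")
  if (is.data.frame(weights)) weights <- as.matrix(weights)
  if (is.matrix(weights)) {
    W <- weights
    n_samples <- nrow(W)
  } else {
    n_samples <- check_count(n_samples, "n_samples", min = 1L)
    W <- matrix(weights, nrow = n_samples, ncol = length(weights), byrow = TRUE,
                dimnames = list(NULL, names(weights)))
  }
  if (is.null(colnames(W))) abort("`weights` must be named by lineage.")
  unknown <- setdiff(colnames(W), colnames(profiles))
  if (length(unknown)) {
    abort(sprintf("Weight name(s) not matching an atlas lineage (or 'background'): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(W < 0) || any(abs(rowSums(W) - 1) > 1e-9)) {
    abort("Each weight vector must be non-negative and sum to 1 (tolerance 1e-9).")
  }
  seed <- check_count(seed, "seed")
  set.seed(seed)
  expected <- profiles[, colnames(W), drop = FALSE] %*% t(W) * total
  if (sigma > 0) {
    noise <- matrix(stats::rlnorm(length(expected), meanlog = -sigma^2 / 2, sdlog = sigma),
                    nrow = nrow(expected))
    expected <- expected * noise
  }
  colnames(expected) <- sprintf("%s%02d", sample_prefix, seq_len(n_samples))
  expr_tibble(expected)
}
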