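#' Mix a reference cell-type profile into background transcriptomes
#'
#' In-silico spike-in: both the background sample(s) and the spike profile
#' are first renormalized to a common total `total` over the union of
#' their genes (genes absent from one side count as 0), then mixed
#' linearly, `mixed = (1 - fraction) * background + fraction * spike`.
#' The fraction is an RNA-mass fraction; the mixed sample's total equals
#' `total` exactly.
#'
#' @param background Background expression: tibble with gene column first
#'   and one or more sample columns, or a matrix with gene rownames. Every
#'   sample column is spiked.
#' @param spike_profile The cell-type profile to spike in: a two-column
#'   (gene, value) data frame such as [lineage_profile()] returns, or a
#'   named numeric vector.
#' @param fraction Spike fraction f in `[0, 1]`.
#' @param total Normalization total T (default 1e6, i.e. TPM-like).
#' @return A tibble in the same gene-by-sample layout covering the gene
#'   union, with every column summing to `total`.
#' @export
spike_transcriptome <- function(background, spike_profile, fraction, total = 1e6) {
  fraction <- check_fraction(fraction, "fraction")
  if (length(total) != 1L || !is.numeric(total) || total <= 0) {
    abort("`total` must be a single positive number.")
  }
  bg <- expr_matrix(background, "background")
  if (is.numeric(spike_profile) && !is.null(names(spike_profile))) {
    sp <- spike_profile
  } else if (is.data.frame(spike_profile) && ncol(spike_profile) >= 2L) {
    sp <- spike_profile[[2L]]
    names(sp) <- as.character(spike_profile[[1L]])
  } else {
    abort("`spike_profile` must be a (gene, value) data frame or a named numeric vector.")
  }
  if (any(bg < 0) || any(sp < 0)) abort("Expression values must be non-negative.")
  genes <- union(rownames(bg), names(sp))
  bg_full <- matrix(0, nrow = length(genes), ncol = ncol(bg),
                    dimnames = list(genes, colnames(bg)))
  bg_full[rownames(bg), ] <- bg
  sp_full <- setNames(numeric(length(genes)), genes)
  sp_full[names(sp)] <- sp
  bg_tot <- colSums(bg_full)
  if (any(bg_tot == 0)) abort("A background sample has zero total expression.")
  if (sum(sp_full) == 0) abort("The spike profile has zero total expression.")
  bg_norm <- sweep(bg_full, 2L, bg_tot / total, "/")
  sp_norm <- sp_full / sum(sp_full) * total
  mixed <- (1 - fraction) * bg_norm + fraction * sp_norm
  expr_tibble(mixed)
}

#' Spike-in limit-of-detection curve
#'
#' Emulates the in-silico spike-in experiment that measures how small a
#' cell-type fraction the enrichment score can resolve. The background
#' cohort is scored as-is (after normalization to `total`) and again with
#' the target cell type's profile spiked in at each fraction of the grid,
#' using identical settings and the same seed so the comparison is paired
#' per sample. Per fraction, a two-tailed paired Student's t-test compares
#' the target lineage's odds ratios with vs without spike-in. The limit of
#' detection is the smallest fraction whose p-value falls below `alpha`.
#' At f = 0 all paired differences are zero and p is 1 by convention.
#'
#' @param background Background cohort (gene x sample tibble or matrix),
#'   n >= 2 samples.
#' @param spike_profile Target cell-type profile, as in
#'   [spike_transcriptome()].
#' @param signatures A `ct_signatures` object.
#' @param target The lineage (cell type) whose detectability is measured.
#' @param fractions Ascending grid of spike fractions in `[0, 1]`.
#' @param alpha Significance level for the limit of detection (default
#'   0.05).
#' @param total Normalization total for mixing (default 1e6).
#' @inheritParams score_cohort
#' @return A `ct_detection` tibble with columns `cell_type`, `fraction`,
#'   `statistic`, `p_value`, `neglog10_p`, `significant`; the limit of
#'   detection (or NA if not reached) and `alpha` are attached as
#'   attributes and reported by [glance.ct_detection()].
#' @export
detection_limit_curve <- function(background, spike_profile, signatures, target,
                                  fractions, alpha = 0.05, total = 1e6,
                                  universe = NULL, threshold = 0.5,
                                  mode = "quantile", n_lists = 1000, seed = 42) {
  if (!inherits(signatures, "ct_signatures")) {
    abort("`signatures` must come from build_signatures().")
  }
  if (!target %in% unique(signatures$lineage)) {
    abort(sprintf("Target lineage '%s' has no signature.", target))
  }
  if (!is.numeric(fractions) || length(fractions) == 0L ||
      any(fractions < 0) || any(fractions > 1)) {
    abort("`fractions` must be numeric values in [0, 1].")
  }
  fractions <- sort(unique(fractions))
  alpha <- check_fraction(alpha, "alpha")
  bg <- expr_matrix(background, "background")
  if (ncol(bg) < 2L) abort("The background cohort needs at least 2 samples.")

  # f = 0 spike is exactly the renormalized background: the unspiked arm.
  base <- spike_transcriptome(bg, spike_profile, fraction = 0, total = total)
  score_target <- function(x) {
    res <- score_cohort(x, signatures, universe = universe, threshold = threshold,
                        mode = mode, n_lists = n_lists, seed = seed,
                        lineages = target, normalize = FALSE)
    setNames(res$odds_ratio, res$sample)
  }
  or_base <- score_target(base)
  rows <- lapply(fractions, function(f) {
    or_spiked <- if (f == 0) or_base else {
      score_target(spike_transcriptome(bg, spike_profile, fraction = f, total = total))
    }
    tt <- students_t_test(or_spiked[names(or_base)], or_base, paired = TRUE)
    tibble(cell_type = target, fraction = f,
           statistic = tt$statistic, p_value = tt$p_value,
           neglog10_p = -log10(tt$p_value))
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < alpha
  lod <- if (any(out$significant)) min(out$fraction[out$significant]) else NA_real_
  attr(out, "alpha") <- alpha
  attr(out, "lod") <- lod
  attr(out, "n_samples") <- ncol(bg)
  class(out) <- c("ct_detection", class(out))
  out
}

#' @export
print.ct_detection <- function(x, ...) {
  lod <- attr(x, "lod")
  cat(sprintf("<ct_detection> '%s' over %d fractions (n = %d): limit of detection %s\n",
              x$cell_type[1L], nrow(x), attr(x, "n_samples"),
              if (is.na(lod)) "not reached" else format(lod)))
  NextMethod()
}
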