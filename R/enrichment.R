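#' Expressed genes of a query sample
#'
#' Applies the expressed-gene threshold t that gates which genes count as
#' present in a sample. In `"absolute"` mode, genes with value strictly
#' greater than `threshold` are expressed (suits TPM-like data; default
#' t = 1). In `"quantile"` mode, `threshold` is a probability in (0, 1) and
#' genes strictly above the per-sample quantile are expressed (suits
#' arbitrary-scale intensity data; t = 0.5 keeps the upper half).
#'
#' @param values Named numeric vector of gene expression values, or a
#'   two-column data frame (gene, value).
#' @param threshold Threshold t (>= 0 in absolute mode; in (0, 1) in
#'   quantile mode).
#' @param mode `"absolute"` or `"quantile"`.
#' @return Character vector of expressed gene identifiers.
#' @export
expressed_genes <- function(values, threshold = 1, mode = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  if (is.data.frame(values)) {
    v <- values[[2L]]
    names(v) <- as.character(values[[1L]])
    values <- v
  }
  if (!is.numeric(values) || is.null(names(values))) {
    abort("`values` must be a named numeric vector or a (gene, value) data frame.")
  }
  if (length(threshold) != 1L || !is.numeric(threshold) || is.na(threshold)) {
    abort("`threshold` must be a single number.")
  }
  cut <- switch(mode,
    absolute = {
      if (threshold < 0) abort("Absolute threshold must be >= 0.")
      threshold
    },
    quantile = {
      if (threshold <= 0 || threshold >= 1) abort("Quantile threshold must lie in (0, 1).")
      unname(quantile(values, threshold))
    })
  names(values)[values > cut]
}

#' Count signature genes among the expressed genes
#'
#' @param signature_genes Character vector of a lineage's marker genes.
#' @param expressed Character vector of expressed genes.
#' @return Integer overlap `|signature ∩ expressed|`.
#' @export
count_signature_hits <- function(signature_genes, expressed) {
  length(intersect(signature_genes, expressed))
}

#' Monte-Carlo random-gene-list null model
#'
#' Draws `n_lists` random gene lists of length `size` uniformly without
#' replacement from the gene universe and counts how many members of each
#' list are expressed in the sample. The mean count is the
#' chance-enrichment baseline against which signature hits are tested.
#' The analytic (hypergeometric) mean `size * |E ∩ U| / |U|` is attached
#' for validation.
#'
#' @param universe Character vector of universe genes (|U| >= `size`).
#' @param expressed Character vector of expressed genes.
#' @param n_lists Number of random lists (default 1000).
#' @param size List length, matching the signature size (default 80).
#' @param seed Optional integer seed for reproducibility.
#' @return A `ct_null` list: `hits` (per-list counts), `mean`, `mean_int`
#'   (rounded half up, for the contingency table), `analytic_mean`, and the
#'   settings.
#' @export
build_null_model <- function(universe, expressed, n_lists = 1000, size = 80,
                             seed = NULL) {
  n_lists <- check_count(n_lists, "n_lists", min = 1L)
  size <- check_count(size, "size", min = 1L)
  universe <- unique(as.character(universe))
  if (length(universe) < size) {
    abort(sprintf("Universe has %d genes; at least %d required.", length(universe), size))
  }
  if (!is.null(seed)) set.seed(seed)
  e <- universe %in% expressed
  hits <- null_hit_counts(e, n_lists, size)
  structure(list(
    hits = hits,
    mean = mean(hits),
    mean_int = as.integer(round_half_up(mean(hits))),
    analytic_mean = size * sum(e) / length(universe),
    n_lists = n_lists, size = size, universe_size = length(universe),
    n_expressed_in_universe = sum(e)
  ), class = "ct_null")
}

# Draw n_lists index sets of `size` from the current RNG stream and count
# how many land on expressed genes (e is a logical over the universe).
null_hit_counts <- function(e, n_lists, size) {
  n_u <- length(e)
  vapply(seq_len(n_lists),
         function(i) sum(e[sample.int(n_u, size)]),
         integer(1L))
}

#' @export
print.ct_null <- function(x, ...) {
  cat(sprintf(
    "<ct_null> %d lists of %d genes from a %d-gene universe\n  mean hits %.3f (analytic %.3f)\n",
    x$n_lists, x$size, x$universe_size, x$mean, x$analytic_mean))
  invisible(x)
}

#' Fisher enrichment of observed vs null signature hits
#'
#' Builds the 2x2 table `[[k_obs, m - k_obs], [k_null, m - k_null]]`
#' (observed signature hits vs the integerized null mean, each against its
#' complement out of the signature size m) and applies the two-sided
#' Fisher's exact test of [fisher_exact()]. The odds ratio is the
#' cross-product ratio with Haldane-Anscombe correction for zero cells.
#'
#' @param k_obs Observed signature hits (0..m).
#' @param k_null Integerized null mean hits (0..m).
#' @param m Signature size.
#' @return A one-row tibble with `p_value` and `odds_ratio`.
#' @export
fisher_enrichment <- function(k_obs, k_null, m) {
  m <- check_count(m, "m", min = 1L)
  k_obs <- check_count(k_obs, "k_obs")
  k_null <- check_count(k_null, "k_null")
  if (k_obs > m || k_null > m) abort("Counts cannot exceed the signature size `m`.")
  fisher_exact(matrix(c(k_obs, m - k_obs, k_null, m - k_null), nrow = 2L, byrow = TRUE))
}

#' Score a cohort of query transcriptomes against marker signatures
#'
#' The core estimator. For every sample: (1) the expressed-gene set is
#' determined by the threshold rule; (2) one Monte-Carlo null model is
#' built for the sample (`n_lists` random `m`-gene lists from the
#' universe); (3) for every lineage, the observed signature hits are
#' tested against the integerized null mean with the two-sided Fisher's
#' exact test. Odds ratios are then min-max normalized per lineage across
#' the cohort (see [normalize_odds_ratios()]). Given a seed, the full run
#' is deterministic.
#'
#' @param query Query expression: tibble with a gene column first and one
#'   numeric column per sample (the [read_expression_matrix()] layout), or
#'   a matrix with gene rownames.
#' @param signatures A `ct_signatures` object from [build_signatures()].
#' @param universe Scoring universe: `NULL` (default) uses the atlas gene
#'   list carried by `signatures`; `"query"` restricts to genes measured in
#'   the query; or a character vector of genes.
#' @param threshold,mode Expressed-gene threshold, as in
#'   [expressed_genes()].
#' @param n_lists Random lists per sample null model (default 1000).
#' @param seed Integer seed for the null draws (default 42).
#' @param lineages Optional subset of lineages to score.
#' @param normalize Add the per-lineage min-max normalized odds ratio
#'   (default TRUE).
#' @return A `ct_result` tibble with one row per (sample, lineage):
#'   `sample`, `lineage`, `n_hits`, `null_mean`, `null_int`, `p_value`,
#'   `odds_ratio` and (if `normalize`) `norm_odds_ratio`. Run settings are
#'   attached as the `settings` attribute (see [glance.ct_result()]).
#' @export
score_cohort <- function(query, signatures, universe = NULL,
                         threshold = 1, mode = c("absolute", "quantile"),
                         n_lists = 1000, seed = 42, lineages = NULL,
                         normalize = TRUE) {
  mode <- match.arg(mode)
  if (!inherits(signatures, "ct_signatures")) {
    abort("`signatures` must come from build_signatures().")
  }
  qm <- expr_matrix(query, "query")
  m_sig <- attr(signatures, "signature_size")
  n_lists <- check_count(n_lists, "n_lists", min = 1L)
  seed <- check_count(seed, "seed")

  sig_sets <- signature_gene_sets(signatures)
  if (!is.null(lineages)) {
    missing <- setdiff(lineages, names(sig_sets))
    if (length(missing)) {
      abort(sprintf("Lineage(s) not in the signature map: %s", paste(missing, collapse = ", ")))
    }
    sig_sets <- sig_sets[lineages]
  }

  if (is.null(universe)) {
    universe <- attr(signatures, "universe")
    universe_mode <- "atlas"
  } else if (identical(universe, "query")) {
    universe <- rownames(qm)
    universe_mode <- "query"
  } else {
    universe <- unique(as.character(universe))
    universe_mode <- "custom"
  }
  if (length(universe) < m_sig) abort("Universe smaller than the signature size.")
  absent <- lengths(lapply(sig_sets, setdiff, y = universe))
  if (any(absent > 0)) {
    warn(sprintf("%d signature gene(s) absent from the scoring universe (e.g. lineage '%s').",
                 sum(absent), names(sig_sets)[which(absent > 0)[1L]]))
  }

  per_sample <- lapply(colnames(qm), function(s) {
    expressed <- expressed_genes(qm[, s], threshold = threshold, mode = mode)
    e <- universe %in% expressed
    # Per-sample null, seeded from the base seed plus a content hash of the
    # expressed set: identical samples get identical draws, and a sample's
    # scores do not depend on cohort composition or order.
    set.seed((seed + sum(which(e))) %% 2147483647L)
    hits <- null_hit_counts(e, n_lists, m_sig)
    k_null_mean <- mean(hits)
    k_null <- as.integer(round_half_up(k_null_mean))
    rows <- lapply(names(sig_sets), function(l) {
      k_obs <- count_signature_hits(sig_sets[[l]], expressed)
      ft <- fisher_enrichment(k_obs, k_null, m_sig)
      tibble(sample = s, lineage = l, n_hits = k_obs,
             null_mean = k_null_mean, null_int = k_null,
             p_value = ft$p_value, odds_ratio = ft$odds_ratio)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(per_sample)
  attr(out, "settings") <- list(
    signature_size = m_sig, n_lists = n_lists, threshold = threshold,
    threshold_mode = mode, seed = seed, universe_mode = universe_mode,
    universe_size = length(universe), odds_ratio = "cross-product (Haldane-Anscombe)",
    normalized = normalize
  )
  class(out) <- c("ct_result", class(out))
  if (normalize) out <- normalize_odds_ratios(out) else out
}

#' Min-max normalize odds ratios across a cohort
#'
#' For each lineage, rescales the odds ratios of all samples scored
#' together to `[0, 1]` by `(OR - min) / (max - min)`; when a lineage's
#' odds ratios are constant across the cohort the normalized value is 0.
#' The normalized odds ratio is the intersample comparison score shown in
#' enrichment heatmaps.
#'
#' @param results A `ct_result` tibble from [score_cohort()].
#' @return The same tibble with a `norm_odds_ratio` column (re)computed.
#' @export
normalize_odds_ratios <- function(results) {
  if (!inherits(results, "ct_result")) abort("`results` must come from score_cohort().")
  at <- attributes(results)
  out <- dplyr::mutate(
    as_tibble(results),
    norm_odds_ratio = {
      rng <- max(.data$odds_ratio) - min(.data$odds_ratio)
      if (rng == 0) rep(0, length(.data$odds_ratio))
      else (.data$odds_ratio - min(.data$odds_ratio)) / rng
    },
    .by = "lineage")
  attr(out, "settings") <- at$settings
  attr(out, "settings")$normalized <- TRUE
  class(out) <- c("ct_result", class(out))
  out
}

#' Compare enrichment between two groups of samples
#'
#' Per lineage, a two-tailed Student's t-test on the odds ratios of the two
#' groups (pooled variance when unpaired; the one-sample test on paired
#' differences when `paired = TRUE`), followed by Benjamini-Hochberg
#' adjustment across lineages.
#'
#' @param results A `ct_result` tibble from [score_cohort()].
#' @param groups Data frame with columns `sample` and `group` (exactly two
#'   distinct groups); for paired mode, also `pair` identifying the
#'   matched pairs.
#' @param paired Logical; paired test (requires the `pair` column and equal
#'   group sizes).
#' @param value Which score to compare: `"odds_ratio"` (default) or
#'   `"norm_odds_ratio"`.
#' @param welch Use the Welch statistic instead of pooled variance
#'   (unpaired only).
#' @return A tibble with one row per lineage: `lineage`, `group1`,
#'   `group2`, `estimate`, `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(results, groups, paired = FALSE,
                           value = c("odds_ratio", "norm_odds_ratio"),
                           welch = FALSE) {
  value <- match.arg(value)
  if (!inherits(results, "ct_result")) abort("`results` must come from score_cohort().")
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    abort("`groups` must have columns `sample` and `group`.")
  }
  if (!value %in% names(results)) {
    abort(sprintf("Column `%s` not present; run normalize_odds_ratios() first.", value))
  }
  gl <- unique(as.character(groups$group))
  if (length(gl) != 2L) abort("Exactly two groups are required.")
  df <- dplyr::inner_join(as_tibble(results), as_tibble(groups), by = "sample")
  missing <- setdiff(unique(results$sample), groups$sample)
  if (length(missing)) {
    abort(sprintf("Sample(s) without a group label: %s", paste(missing, collapse = ", ")))
  }
  sizes <- dplyr::count(dplyr::distinct(df, .data$sample, .data$group), .data$group)
  if (any(sizes$n < 2L)) abort("Each group needs at least 2 samples.")
  if (paired) {
    if (!"pair" %in% names(groups)) abort("Paired mode requires a `pair` column in `groups`.")
    if (sizes$n[1L] != sizes$n[2L]) abort("Paired mode requires equal group sizes.")
  }
  per_lineage <- lapply(split(df, df$lineage), function(d) {
    x <- d[[value]][d$group == gl[1L]]
    y <- d[[value]][d$group == gl[2L]]
    if (paired) {
      px <- d$pair[d$group == gl[1L]]
      py <- d$pair[d$group == gl[2L]]
      if (!setequal(px, py) || anyDuplicated(px) || anyDuplicated(py)) {
        abort("Paired mode requires matching, unique pair keys in both groups.")
      }
      y <- y[match(px, py)]
      tt <- students_t_test(x, y, paired = TRUE)
    } else {
      tt <- students_t_test(x, y, paired = FALSE, welch = welch)
    }
    tibble(lineage = d$lineage[1L], group1 = gl[1L], group2 = gl[2L],
           estimate = tt$estimate, statistic = tt$statistic, df = tt$df,
           p_value = tt$p_value)
  })
  out <- dplyr::bind_rows(per_lineage)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' @export
print.ct_result <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<ct_result> %d samples x %d lineages (m = %d, B = %d, seed = %d)\n",
              length(unique(x$sample)), length(unique(x$lineage)),
              s$signature_size, s$n_lists, s$seed))
  NextMethod()
}
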