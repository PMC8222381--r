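#' Tidy an enrichment result
#'
#' @param x A `ct_result` from [score_cohort()].
#' @param ... Unused.
#' @return A plain tibble of the per-(sample, lineage) rows.
#' @method tidy ct_result
#' @export
tidy.ct_result <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "settings") <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of a scoring run's settings
#'
#' @param x A `ct_result` from [score_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: sample/lineage counts and the run settings
#'   (signature size m, null lists B, threshold and mode, seed, universe).
#' @method glance ct_result
#' @export
glance.ct_result <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_samples = length(unique(x$sample)),
         n_lineages = length(unique(x$lineage)),
         signature_size = s$signature_size, n_lists = s$n_lists,
         threshold = s$threshold, threshold_mode = s$threshold_mode,
         seed = s$seed, universe_mode = s$universe_mode,
         universe_size = s$universe_size)
}

#' @rdname tidy.ct_result
#' @method tidy ct_signatures
#' @export
tidy.ct_signatures <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "signature_size") <- NULL
  attr(out, "rank_by") <- NULL
  attr(out, "universe") <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname glance.ct_result
#' @method glance ct_signatures
#' @export
glance.ct_signatures <- function(x, ...) {
  tibble(n_lineages = length(unique(x$lineage)),
         signature_size = attr(x, "signature_size"),
         rank_by = attr(x, "rank_by"),
         universe_size = length(attr(x, "universe")))
}

#' @rdname tidy.ct_result
#' @method tidy ct_detection
#' @export
tidy.ct_detection <- function(x, ...) {
  out <- as_tibble(x)
  for (a in c("alpha", "lod", "n_samples")) attr(out, a) <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname glance.ct_result
#' @method glance ct_detection
#' @export
glance.ct_detection <- function(x, ...) {
  tibble(cell_type = x$cell_type[1L], n_samples = attr(x, "n_samples"),
         alpha = attr(x, "alpha"), limit_of_detection = attr(x, "lod"))
}
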