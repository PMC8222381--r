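# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code; expensive defaults are memoized per run.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic atlas (the study conditions) and its signatures,
# built once and shared across test files.
default_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_atlas()
  .fixtures$sim
}

default_signatures <- function() {
  if (is.null(.fixtures$sig)) {
    sim <- default_sim()
    atlas <- average_replicates(sim$expression, sim$replicate_map)
    .fixtures$atlas <- atlas
    .fixtures$sig <- build_signatures(atlas)
  }
  .fixtures$sig
}

default_atlas <- function() {
  default_signatures()
  .fixtures$atlas
}

# A tiny deterministic reference: 3 lineages, hand-checkable values.
tiny_expr <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    a1 = c(10, 0, 1, 2, 0), a2 = c(12, 0, 1, 4, 0),
    b1 = c(0, 8, 1, 1, 0),
    c1 = c(0, 0, 1, 1, 0), c2 = c(0, 2, 1, 1, 0), c3 = c(0, 1, 1, 1, 0)
  )
}

tiny_map <- function() {
  tibble::tibble(sample = c("a1", "a2", "b1", "c1", "c2", "c3"),
                 lineage = c("A", "A", "B", "C", "C", "C"))
}

# --- independent oracles -------------------------------------------------

# Two-sided Fisher p by exhaustive hypergeometric enumeration with
# binomial-coefficient arithmetic (independent of dhyper).
fisher_oracle_p <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; K <- a + c_; N <- m1 + m2
  lo <- max(0, K - m2); hi <- min(K, m1)
  support <- lo:hi
  probs <- vapply(support,
                  function(k) choose(m1, k) * choose(m2, K - k) / choose(N, K),
                  numeric(1L))
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# BH step-up straight from the definition: the adjusted value of p_i is
# the minimum over all j with rank >= rank(i) of n * p_(j) / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(n * sorted[i:n] / (i:n)))
  }, numeric(1L))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Two-tailed Student-t p-value by numerical integration of the t density.
t_p_oracle <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, lower = abs(tstat), upper = Inf,
                       rel.tol = 1e-12)$value
}

# Pearson r straight from the covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

expr_as_matrix <- function(df) {
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  m
}
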