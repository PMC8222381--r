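test_that("expressed-gene thresholding follows the absolute and quantile rules", {
  v <- c(g1 = 0, g2 = 0, g3 = 0)
  expect_length(expressed_genes(v, threshold = 0), 0)

  v <- c(g1 = 0.5, g2 = 2, g3 = 3)
  expect_equal(expressed_genes(v, threshold = 1), c("g2", "g3"))
  expect_equal(expressed_genes(c(g1 = 1, g2 = 2), threshold = 1), "g2")  # strict >

  set.seed(41)
  v <- setNames(runif(1000), sprintf("g%04d", 1:1000))
  got <- expressed_genes(v, threshold = 0.5, mode = "quantile")
  cut <- sort(v)[500]  # type-7 median of an even-length sample lies between
  oracle <- names(v)[v > unname(quantile(v, 0.5))]
  expect_setequal(got, oracle)
  expect_equal(length(got), 500)

  df <- tibble::tibble(gene = c("a", "b"), value = c(0.2, 5))
  expect_equal(expressed_genes(df, threshold = 1), "b")

  expect_error(expressed_genes(v, threshold = -1), ">= 0")
  expect_error(expressed_genes(v, threshold = 1.5, mode = "quantile"), "\\(0, 1\\)")
  expect_error(expressed_genes(unname(v)), "named")
})

test_that("signature hit counting is plain set intersection", {
  expect_equal(count_signature_hits(c("a", "b"), character(0)), 0)
  expect_equal(count_signature_hits(c("a", "b"), c("a", "b", "c")), 2)
  expect_equal(count_signature_hits(paste0("g", 1:5), c("g2", "g4", "g9")), 2)
})

test_that("null model hits the analytic hypergeometric mean", {
  u <- paste0("g", 1:200)
  all_in <- build_null_model(u, u, n_lists = 50, size = 30, seed = 1)
  expect_equal(all_in$hits, rep(30L, 50))
  expect_equal(all_in$mean, 30)

  none <- build_null_model(u, c("x1", "x2"), n_lists = 50, size = 30, seed = 1)
  expect_equal(none$mean, 0)

  # |U| = 1000, |E∩U| = 100, m = 80: hypergeometric mean 8,
  # SE = sqrt(m * 0.1 * 0.9 * (920/999) / B) ~ 0.081.
  u <- sprintf("u%04d", 1:1000)
  nm <- build_null_model(u, u[1:100], n_lists = 1000, size = 80, seed = 2)
  se <- sqrt(80 * 0.1 * 0.9 * (920 / 999) / 1000)
  expect_equal(nm$analytic_mean, 8)
  expect_lt(abs(nm$mean - 8), 3 * se)
  expect_equal(nm$mean_int, as.integer(floor(nm$mean + 0.5)))

  rerun <- build_null_model(u, u[1:100], n_lists = 1000, size = 80, seed = 2)
  expect_identical(nm$hits, rerun$hits)
  expect_error(build_null_model(u[1:10], u, size = 80), "at least 80")
})

test_that("null-model mean converges to m|E∩U|/|U| across seeded configurations", {
  set.seed(77)
  for (i in 1:20) {
    n_u <- sample(200:2000, 1)
    u <- sprintf("u%04d", seq_len(n_u))
    frac <- runif(1, 0.05, 0.9)
    e <- sample(u, round(frac * n_u))
    m <- sample(20:80, 1)
    nm <- build_null_model(u, e, n_lists = 1000, size = m, seed = i)
    pe <- length(e) / n_u
    se <- sqrt(m * pe * (1 - pe) * ((n_u - m) / (n_u - 1)) / 1000)
    expect_lt(abs(nm$mean - nm$analytic_mean), 4 * se)
  }
})

test_that("Fisher enrichment builds the observed-vs-null table correctly", {
  null0 <- fisher_enrichment(0, 0, 40)
  expect_equal(null0$p_value, 1)
  expect_equal(null0$odds_ratio, 1)

  ex <- fisher_enrichment(12, 8, 80)   # table [[12, 68], [8, 72]]
  expect_equal(ex$odds_ratio, (12 * 72) / (68 * 8), tolerance = 1e-12)
  expect_equal(ex$odds_ratio, 1.588235, tolerance = 1e-6)
  expect_equal(ex$p_value, 0.474101049069247, tolerance = 1e-12)  # enumeration oracle

  expect_error(fisher_enrichment(41, 5, 40), "exceed")
  expect_error(fisher_enrichment(-1, 5, 40), ">= 0")
})

test_that("enrichment is monotone in the observed hits past the null", {
  k_null <- 10; m <- 40
  res <- lapply(k_null:m, function(k) fisher_enrichment(k, k_null, m))
  or <- vapply(res, function(r) r$odds_ratio, numeric(1))
  p <- vapply(res, function(r) r$p_value, numeric(1))
  expect_true(all(diff(or) > 0))
  expect_true(all(diff(p) < 1e-15))   # strictly decreasing past the null
})

test_that("scoring recovers a planted lineage and is deterministic", {
  sim <- default_sim()
  sig <- default_signatures()

  # Planted lineage: 5% of L3 over marker-free background tissue.
  mix <- simulate_mixture(sim, c(background = 0.95, L3 = 0.05),
                          n_samples = 2, seed = 23)
  res <- score_cohort(mix, sig, threshold = 0.5, mode = "quantile",
                      n_lists = 1000, seed = 23)
  for (s in unique(res$sample)) {
    d <- res[res$sample == s, ]
    expect_equal(d$lineage[which.max(d$odds_ratio)], "L3")
    expect_lt(d$p_value[d$lineage == "L3"], 0.01)
  }

  # A sample that expresses the whole signature: maximal OR, p < 0.001.
  pure <- simulate_mixture(sim, c(L3 = 1), n_samples = 1, seed = 24)
  pres <- score_cohort(pure, sig, threshold = 0.5, mode = "quantile",
                       n_lists = 1000, seed = 24, normalize = FALSE)
  expect_equal(pres$lineage[which.max(pres$odds_ratio)], "L3")
  expect_lt(pres$p_value[pres$lineage == "L3"], 0.001)

  # Identical samples give identical rows; a rerun is identical throughout.
  dup <- mix
  dup[[3]] <- dup[[2]]
  res2 <- score_cohort(dup, sig, threshold = 0.5, mode = "quantile",
                       n_lists = 500, seed = 5)
  a <- res2[res2$sample == names(dup)[2], -1]
  b <- res2[res2$sample == names(dup)[3], -1]
  expect_equal(as.data.frame(a), as.data.frame(b))
  res3 <- score_cohort(dup, sig, threshold = 0.5, mode = "quantile",
                       n_lists = 500, seed = 5)
  expect_identical(tidy(res2), tidy(res3))
})

test_that("a sample with an empty expressed set is flat: p = 1, OR = 1", {
  sig <- default_signatures()
  qm <- matrix(0, nrow = 50, ncol = 1,
               dimnames = list(attr(sig, "universe")[1:50], "empty"))
  res <- score_cohort(qm, sig, threshold = 0, mode = "absolute",
                      n_lists = 100, seed = 1, normalize = FALSE)
  expect_equal(res$p_value, rep(1, 6))
  expect_equal(res$odds_ratio, rep(1, 6))
  expect_equal(res$n_hits, rep(0L, 6))
})

test_that("odds-ratio normalization is per-lineage min-max across the cohort", {
  res <- tibble::tibble(sample = paste0("s", 1:3),
                        lineage = "X",
                        n_hits = 1L, null_mean = 1, null_int = 1L,
                        p_value = 1, odds_ratio = c(2, 4, 6))
  attr(res, "settings") <- list(normalized = FALSE)
  class(res) <- c("ct_result", class(res))
  got <- normalize_odds_ratios(res)
  expect_equal(got$norm_odds_ratio, c(0, 0.5, 1))

  res$odds_ratio <- rep(3, 3)                     # degenerate: constant
  expect_equal(normalize_odds_ratios(res)$norm_odds_ratio, rep(0, 3))

  # Random OR matrix vs an independent two-pass min/max oracle.
  set.seed(55)
  long <- expand.grid(sample = paste0("s", 1:8), lineage = paste0("L", 1:5),
                      stringsAsFactors = FALSE)
  long$odds_ratio <- rlnorm(nrow(long))
  long <- tibble::as_tibble(cbind(long, n_hits = 1L, null_mean = 1,
                                  null_int = 1L, p_value = 1))
  attr(long, "settings") <- list(normalized = FALSE)
  class(long) <- c("ct_result", class(long))
  got <- normalize_odds_ratios(long)
  for (l in unique(long$lineage)) {
    v <- long$odds_ratio[long$lineage == l]
    lo <- Inf; hi <- -Inf
    for (x in v) { if (x < lo) lo <- x; if (x > hi) hi <- x }
    expect_equal(got$norm_odds_ratio[got$lineage == l], (v - lo) / (hi - lo),
                 tolerance = 1e-12)
  }
})

test_that("group comparison runs Student's t per lineage with BH adjustment", {
  mk_result <- function(or_matrix) {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(cbind(sample = rownames(or_matrix),
                              as.data.frame(or_matrix))),
      -sample, names_to = "lineage", values_to = "odds_ratio")
    long$odds_ratio <- as.numeric(long$odds_ratio)
    long <- tibble::as_tibble(long)
    attr(long, "settings") <- list(normalized = FALSE)
    class(long) <- c("ct_result", class(long))
    long
  }
  or <- rbind(s1 = c(A = 1, B = 5), s2 = c(2, 5), s3 = c(3, 5),
              s4 = c(4, 5), s5 = c(5, 5), s6 = c(6, 5))
  groups <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("g1", "g2"), each = 3))
  cmp <- compare_groups(mk_result(or), groups)
  a <- cmp[cmp$lineage == "A", ]
  expect_equal(round(a$statistic, 3), -3.674)
  expect_equal(a$df, 4)
  expect_equal(round(a$p_value, 4), 0.0213)
  b <- cmp[cmp$lineage == "B", ]                 # identical groups
  expect_equal(b$statistic, 0)
  expect_equal(b$p_value, 1)
  expect_equal(b$p_adjusted, 1)
  expect_equal(cmp$p_adjusted, bh_adjust(cmp$p_value))

  # BH across 20 lineages against the step-up oracle.
  set.seed(66)
  or20 <- matrix(rlnorm(8 * 20), 8, dimnames = list(paste0("s", 1:8), paste0("L", 1:20)))
  g20 <- tibble::tibble(sample = paste0("s", 1:8), group = rep(c("a", "b"), each = 4))
  cmp20 <- compare_groups(mk_result(or20), g20)
  expect_equal(cmp20$p_adjusted, bh_oracle(cmp20$p_value), tolerance = 1e-12)

  # Paired mode needs matching keys; tiny groups are rejected.
  gp <- tibble::tibble(sample = paste0("s", 1:6),
                       group = rep(c("g1", "g2"), each = 3),
                       pair = c("p1", "p2", "p3", "p1", "p2", "p9"))
  expect_error(compare_groups(mk_result(or), gp, paired = TRUE), "pair keys")
  expect_error(compare_groups(mk_result(or), groups[-1, ]), "without a group")
  g_small <- tibble::tibble(sample = paste0("s", 1:6),
                            group = c("g1", rep("g2", 5)))
  expect_error(compare_groups(mk_result(or), g_small), "at least 2")
})

test_that("the planted lineage tops the normalized odds ratios in positive-control cohorts", {
  sim <- default_sim()
  sig <- default_signatures()
  lineages <- paste0("L", 1:6)
  hits <- 0L
  n_runs <- 10L
  for (r in seq_len(n_runs)) {
    W <- cbind(diag(6) * 0.05, background = 0.95)
    colnames(W)[1:6] <- lineages
    mix <- simulate_mixture(sim, W, seed = 1000 + r, sample_prefix = "s")
    res <- score_cohort(mix, sig, threshold = 0.5, mode = "quantile",
                        n_lists = 500, seed = 1000 + r)
    strict <- vapply(seq_along(lineages), function(i) {
      d <- res[res$sample == sprintf("s%02d", i), ]
      v <- d$norm_odds_ratio
      v[d$lineage == lineages[i]] > max(v[d$lineage != lineages[i]])
    }, logical(1))
    hits <- hits + all(strict)
  }
  expect_gte(hits, n_runs - 1L)
})
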