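test_that("Yates chi-square reproduces printed and degenerate cases", {
  pf <- yates_chi2(c(33, 44, 8, 32))
  expect_equal(pf$value, 5.080, tolerance = 1e-3)
  expect_equal(pf$p_value, 0.024, tolerance = 0.02)
  fpf <- yates_chi2(c(171, 96, 15, 61))
  expect_equal(fpf$value, 45.024, tolerance = 1e-3)
  expect_lt(fpf$p_value, 0.001)

  flat <- yates_chi2(c(10, 10, 10, 10))
  expect_equal(flat$value, 0)
  expect_equal(flat$p_value, 1)

  expect_true(is.na(yates_chi2(c(0, 0, 5, 5))$value))  # zero marginal
})

test_that("Yates chi-square is invariant under transposition and row/col swaps", {
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(rpois(4, 15) + 1, 2)
    base <- yates_chi2(m)$value
    expect_equal(yates_chi2(t(m))$value, base)
    expect_equal(yates_chi2(m[2:1, 2:1])$value, base)
    # and matches the standard continuity-corrected test
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(base, unname(ref$statistic))
    expect_equal(yates_chi2(m)$p_value, ref$p.value)
  }
})

test_that("exact signed-rank test matches full enumeration", {
  # eight same-signed differences: smallest possible two-sided exact p
  res <- wilcoxon_exact(2:9, rep(1, 8))
  expect_equal(res$value, 0)
  expect_equal(res$ties, 0L)
  expect_equal(res$p_value, 2 / 256)

  # identical samples are all ties
  res <- wilcoxon_exact(1:5, 1:5)
  expect_true(is.na(res$value))
  expect_equal(res$ties, 5L)

  # brute-force oracle over all sign vectors, tied ranks included
  brute_p <- function(d) {
    d <- d[d != 0]; m <- length(d); r <- rank(abs(d))
    wobs <- min(sum(r[d > 0]), sum(r[d < 0])); tot <- sum(r)
    hits <- 0
    for (mask in 0:(2^m - 1)) {
      sgn <- as.integer(intToBits(mask))[1:m]
      w <- sum(r[sgn == 1])
      if (w <= wobs + 1e-9 || w >= tot - wobs - 1e-9) hits <- hits + 1
    }
    min(1, hits / 2^m)
  }
  set.seed(7)
  for (i in 1:25) {
    m <- sample(3:8, 1)
    x <- stats::rnorm(m)
    y <- x - sample(c(-2:-1, 1:2), m, replace = TRUE) * stats::runif(m, 0.2, 1)
    expect_equal(wilcoxon_exact(x, y)$p_value, brute_p(x - y))
  }
  # and agrees with the standard exact implementation when untied
  for (i in 1:10) {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    expect_equal(wilcoxon_exact(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("zero differences are dropped and counted as ties", {
  res <- wilcoxon_exact(c(1, 2, 3, 4, 7), c(1, 2, 1, 1, 9))
  expect_equal(res$ties, 2L)
  expect_equal(res$n, 3L)
})

test_that("large-sample signed-rank path tracks the normal approximation", {
  set.seed(3)
  x <- stats::rnorm(40); y <- stats::rnorm(40, 0.3)
  mine <- wilcoxon_exact(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$note, "normal approximation")
})

test_that("Monte-Carlo Kruskal-Wallis matches statistic and exact-permutation p", {
  ident <- kruskal_wallis_mc(list(c(1, 2, 3), c(1, 2, 3)), n_perm = 200, seed = 1)
  expect_equal(ident$value, 0)
  expect_equal(ident$p_value, 1, tolerance = 0.05)

  const <- kruskal_wallis_mc(list(rep(2, 4), rep(2, 3)), n_perm = 100, seed = 1)
  expect_equal(const$value, 0)
  expect_equal(const$p_value, 1)

  # exact permutation oracle by full enumeration of group assignments
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  vals <- unlist(g)
  h_of <- function(assign) {
    unname(stats::kruskal.test(vals, factor(assign))$statistic)
  }
  h_obs <- h_of(rep(1:3, each = 3))
  combs1 <- utils::combn(9, 3)
  hits <- 0; total <- 0
  for (i in seq_len(ncol(combs1))) {
    rest <- setdiff(1:9, combs1[, i])
    combs2 <- utils::combn(rest, 3)
    for (j in seq_len(ncol(combs2))) {
      assign <- integer(9)
      assign[combs1[, i]] <- 1
      assign[combs2[, j]] <- 2
      assign[assign == 0] <- 3
      total <- total + 1
      if (h_of(assign) >= h_obs - 1e-9) hits <- hits + 1
    }
  }
  p_exact <- hits / total
  mc <- kruskal_wallis_mc(vals, rep(1:3, each = 3), n_perm = 10000, seed = 11)
  expect_equal(unname(mc$value), h_obs)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$p_value - p_exact), 3 * mc_se + 2e-4)

  # fixed seed means bit-identical p
  again <- kruskal_wallis_mc(vals, rep(1:3, each = 3), n_perm = 10000, seed = 11)
  expect_identical(mc$p_value, again$p_value)
})

test_that("the randomization p-value holds its size on exchangeable data", {
  set.seed(17)
  n_rep <- 500
  rej <- 0
  for (i in seq_len(n_rep)) {
    v <- stats::rexp(15, rate = 1 / 40)   # session-duration-like scale
    res <- kruskal_wallis_mc(v, rep(1:3, each = 5), n_perm = 199)
    if (res$p_value <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("Dunn post hocs report rank differences with a Bonferroni cap", {
  ident <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_true(all(ident$p_value == 1))

  g <- list(lo = c(1, 2, 3), mid = c(8, 9, 10), hi = c(40, 50, 60))
  out <- dunn_bonferroni(g)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_value <= 1))
  expect_true(all(out$p_value >= out$p_unadjusted))
  # the extreme pair is the strongest separation
  lo_hi <- out[out$group1 == "hi" & out$group2 == "lo" |
                 out$group1 == "lo" & out$group2 == "hi", ]
  expect_equal(min(out$p_unadjusted), lo_hi$p_unadjusted)
  # mean-rank difference oracle: lo ranks 1-3, hi ranks 7-9
  expect_equal(abs(lo_hi$rank_diff), 6)
})

test_that("paired t-test reproduces the per-individual rate comparison", {
  rates <- rates_per_session(group_composition())
  res <- paired_t(rates$pf_rate, rates$fpf_rate)
  expect_equal(res$value, -2.608, tolerance = 2e-3)
  expect_equal(res$df, 20)
  expect_equal(res$p_value, 0.017, tolerance = 0.02)

  expect_true(is.na(paired_t(1:5, 1:5 + 2)$value))  # constant differences

  set.seed(2)
  for (i in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    ref <- stats::t.test(x, y, paired = TRUE)
    mine <- paired_t(x, y)
    expect_equal(mine$value, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
})

test_that("exact binomial test enumerates two-sided probabilities", {
  expect_equal(binomial_exact(5, 5)$p_value, 2 / 32)
  expect_equal(binomial_exact(5, 10)$p_value, 1)
  expect_equal(binomial_exact(0, 10)$p_value, 2 * 0.5^10)
  set.seed(5)
  for (i in 1:15) {
    n <- sample(4:30, 1); k <- sample(0:n, 1)
    expect_equal(binomial_exact(k, n)$p_value,
                 stats::binom.test(k, n)$p.value)
  }
})

test_that("Cohen's kappa follows the chance-corrected agreement formula", {
  expect_equal(cohens_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c"))$value, 1)

  # hand-computed 2x2 confusion matrix (20, 5; 10, 15)
  c1 <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  c2 <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  po <- 35 / 50
  pe <- (25 * 30 + 25 * 20) / 2500
  expect_equal(cohens_kappa(c1, c2)$value, (po - pe) / (1 - pe))

  set.seed(9)
  r1 <- sample(letters[1:3], 4000, replace = TRUE)
  r2 <- sample(letters[1:3], 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$value), 0.05)

  expect_true(is.na(cohens_kappa(rep("a", 5), rep("a", 5))$value))
})

test_that("duration agreement averages smaller/larger ratios", {
  one <- duration_ioa(15, 20)
  expect_equal(one$mean_ratio, 0.75)
  expect_equal(one$ioa_pct, 75)
  expect_equal(duration_ioa(c(3, 7), c(3, 7))$ioa_pct, 100)
  expect_equal(duration_ioa(c(15, 10), c(20, 10))$ioa_pct, 87.5)
  expect_error(duration_ioa(0, 5), "positive")
})

test_that("test rows expose broom-style tidiers", {
  res <- yates_chi2(c(33, 44, 8, 32))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "ethotest"))
  gl <- glance(res)
  expect_named(gl, c("method", "value", "p_value"))
})

test_that("restricted permutations respect strata", {
  v <- c(10, 12, 30, 31, 50, 52)
  g <- rep(1:3, each = 2)
  # singleton strata leave nothing to shuffle: every permuted H equals H
  res <- kruskal_wallis_mc(v, g, n_perm = 50, seed = 1, strata = seq_along(v))
  expect_equal(res$p_value, 1)
  # one global stratum is the unrestricted test
  free <- kruskal_wallis_mc(v, g, n_perm = 2000, seed = 2)
  one <- kruskal_wallis_mc(v, g, n_perm = 2000, seed = 2, strata = rep(1, 6))
  expect_equal(one$value, free$value)
  expect_lt(abs(one$p_value - free$p_value), 0.05)
})
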