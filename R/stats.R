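# The nonparametric/exact test toolbox used by the pipeline. These carry the
# field's reporting conventions (T = smaller signed-rank sum, zero-difference
# "ties" counts, Monte-Carlo permutation p with recorded seed), which base R's
# htest interfaces do not expose; base equivalents serve as oracles in tests.

#' Yates-corrected 2x2 chi-square test
#'
#' Continuity-corrected chi-square of association for a 2x2 contingency
#' table, `X^2 = N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)`, df = 1.
#' The correction is clamped at zero so that near-independent tables cannot
#' inflate the statistic. A zero marginal makes the test unavailable.
#'
#' @param table A 2x2 matrix (e.g. from [build_contingency()]) or a numeric
#'   vector `c(a, b, c, d)` read row-wise.
#' @return A one-row `ethotest` tibble (`value` = X^2, `df` = 1, `p_value`).
#' @export
#' @examples
#' yates_chi2(c(33, 44, 8, 32))
yates_chi2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, nrow = 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) abort("table must be 2x2")
  if (any(m < 0)) abort("counts must be non-negative")
  n <- sum(m)
  if (n == 0) abort("empty table")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) {
    return(new_ethotest("yates_chi2", "X-squared", NA_real_, df = 1, n = n,
                        correction = "Yates", note = "zero marginal"))
  }
  num <- max(abs(a * d - b * c_) - n / 2, 0)
  chi2 <- n * num^2 / prod(marg)
  new_ethotest("yates_chi2", "X-squared", chi2, df = 1, n = n,
               p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
               correction = "Yates")
}

# exact null distribution of the positive signed-rank sum for (possibly
# midrank-tied) ranks r: counts over doubled sums via subset convolution
signed_rank_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (w in r2) {
    if (w > 0) {
      shifted <- c(numeric(w), f[seq_len(total + 1 - w)])
      f <- f + shifted
    } else {
      f <- 2 * f
    }
  }
  f
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped and reported as the `ties` count; the
#' remaining absolute differences are mid-ranked and `T` is the smaller of
#' the positive and negative rank sums. For up to `exact_max` nonzero
#' differences the p-value is exact, from the full enumeration of the
#' `2^m` sign assignments (computed by convolution, so midrank ties are
#' handled exactly); beyond that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (directions refer to `x - y`).
#' @param exact_max Largest `m` for which the exact distribution is
#'   enumerated (default 25).
#' @return A one-row `ethotest` tibble (`value` = T, `n` = nonzero pairs,
#'   `ties` = zero differences, `p_value`).
#' @export
wilcoxon_exact <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact_max = 25) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 1) abort("need at least one pair")
  d <- x - y
  ties_n <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(new_ethotest("wilcoxon_exact", "T", NA_real_, n = 0L, ties = ties_n,
                        note = "all differences zero"))
  }
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  tstat <- min(wpos, wneg)
  if (m <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_counts(r2)
    total <- sum(r2)
    w2 <- as.integer(round(2 * wpos))
    cdf_le <- sum(f[seq_len(w2 + 1)]) / 2^m
    cdf_ge <- sum(f[(w2 + 1):(total + 1)]) / 2^m
    p <- switch(alternative,
      less = cdf_le,
      greater = cdf_ge,
      two.sided = {
        t2 <- as.integer(round(2 * tstat))
        lo <- sum(f[seq_len(t2 + 1)]) / 2^m
        hi <- sum(f[(total - t2 + 1):(total + 1)]) / 2^m
        min(1, lo + hi)
      }
    )
    note <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_le <- (wpos - mu + cc) / sqrt(sigma2)
    z_ge <- (wpos - mu - cc) / sqrt(sigma2)
    p <- switch(alternative,
      less = pnorm(z_le),
      greater = pnorm(z_ge, lower.tail = FALSE),
      two.sided = min(1, 2 * min(pnorm(z_le), pnorm(z_ge, lower.tail = FALSE)))
    )
    note <- "normal approximation"
  }
  new_ethotest("wilcoxon_exact", "T", tstat, n = m, ties = ties_n,
               p_value = p, note = note)
}

kw_statistic <- function(r, grp_idx, n_by_group, tie_factor, n) {
  sums <- rowsum(r, grp_idx, reorder = TRUE)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / n_by_group) - 3 * (n + 1)
  h / tie_factor
}

#' Kruskal-Wallis test with Monte-Carlo randomization
#'
#' Tie-corrected Kruskal-Wallis `H` on pooled mid-ranks, with the p-value
#' estimated by Monte-Carlo randomization: group labels are shuffled
#' `n_perm` times preserving group sizes and the add-one estimator
#' `p = (1 + #(H* >= H)) / (1 + n_perm)` is reported, so the p-value can
#' never be exactly zero. The seed used is recorded in the result.
#'
#' @param values Numeric observations (or a list of per-group numeric
#'   vectors, in which case `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @param strata Optional stratum labels (e.g. dyad ids): when given,
#'   permutations shuffle observations only within strata, a restricted
#'   randomization for data whose observations repeat individuals across
#'   groups.
#' @return A one-row `ethotest` tibble (`value` = H, `df` = groups - 1).
#' @export
kruskal_wallis_mc <- function(values, groups = NULL, n_perm = 10000, seed = NULL,
                              strata = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- !is.na(values)
  values <- values[keep]
  groups <- groups[keep]
  if (!is.null(strata)) strata <- strata[keep]
  grp <- factor(groups)
  if (nlevels(grp) < 2) abort("need at least two groups")
  n <- length(values)
  n_by_group <- as.vector(table(grp))
  if (any(n_by_group < 1)) abort("every group needs at least one observation")
  r <- rank(values)
  tie_tab <- table(r)
  tie_factor <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (tie_factor <= 0) {
    return(new_ethotest("kruskal_wallis_mc", "H", 0, df = nlevels(grp) - 1,
                        n = n, p_value = 1, n_perm = n_perm,
                        seed = seed %||% NA_integer_,
                        note = "all observations identical"))
  }
  grp_idx <- as.integer(grp)
  h_obs <- kw_statistic(r, grp_idx, n_by_group, tie_factor, n)
  if (!is.null(seed)) set.seed(seed)
  strat_idx <- if (!is.null(strata)) split(seq_len(n), strata)
  perm_ranks <- if (is.null(strata)) {
    function() r[sample.int(n)]
  } else {
    function() {
      rp <- r
      for (ix in strat_idx) if (length(ix) > 1) rp[ix] <- r[ix[sample.int(length(ix))]]
      rp
    }
  }
  exceed <- 0L
  eps <- 1e-12
  for (b in seq_len(n_perm)) {
    h_b <- kw_statistic(perm_ranks(), grp_idx, n_by_group, tie_factor, n)
    if (h_b >= h_obs - eps) exceed <- exceed + 1L
  }
  new_ethotest("kruskal_wallis_mc", "H", h_obs, df = nlevels(grp) - 1, n = n,
               p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
               seed = seed %||% NA_integer_)
}

#' Dunn post hoc comparisons with Bonferroni correction
#'
#' Pairwise mean-rank comparisons on the pooled ranking underlying a
#' Kruskal-Wallis test. For each pair the raw mean-rank difference, the
#' tie-corrected Dunn z and the Bonferroni-corrected p (multiplied by the
#' number of pairwise comparisons, capped at 1) are reported.
#'
#' @inheritParams kruskal_wallis_mc
#' @return A tibble with one row per group pair: `group1`, `group2`, `n1`,
#'   `n2`, `rank_diff` (mean rank of group1 minus group2), `z`,
#'   `p_unadjusted`, `p_value`.
#' @export
dunn_bonferroni <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    nm <- names(values) %||% as.character(seq_along(values))
    groups <- rep(nm, lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- !is.na(values)
  values <- values[keep]
  grp <- factor(groups[keep])
  if (nlevels(grp) < 2) abort("need at least two groups")
  n <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  mean_ranks <- tapply(r, grp, mean)
  sizes <- as.vector(table(grp))
  sigma2 <- n * (n + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  pairs <- utils::combn(nlevels(grp), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- mean_ranks[[i]] - mean_ranks[[j]]
    se <- sqrt(sigma2 * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se > 0) diff / se else 0
    p_raw <- 2 * pnorm(-abs(z))
    tibble::tibble(
      group1 = levels(grp)[i], group2 = levels(grp)[j],
      n1 = sizes[i], n2 = sizes[j],
      rank_diff = diff, z = z,
      p_unadjusted = p_raw, p_value = min(1, p_raw * m)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_comparisons") <- m
  out
}

#' Paired t-test
#'
#' Two-sided paired t-test, `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1`. Unavailable when the differences have zero variance.
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @return A one-row `ethotest` tibble.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 2) abort("need at least two pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    return(new_ethotest("paired_t", "t", NA_real_, df = n - 1, n = n,
                        note = "zero variance of differences"))
  }
  t <- mean(d) / (s / sqrt(n))
  new_ethotest("paired_t", "t", t, df = n - 1, n = n,
               p_value = 2 * pt(-abs(t), df = n - 1))
}

#' Exact two-sided binomial test
#'
#' Exact binomial test of `k` successes out of `n` against success
#' probability `p0`; the two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null success probability (default 0.5).
#' @return A one-row `ethotest` tibble (`value` = k).
#' @export
binomial_exact <- function(k, n, p0 = 0.5) {
  if (n < 1) abort("n must be positive")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  d <- stats::dbinom(0:n, n, p0)
  p <- sum(d[d <= d[k + 1] * (1 + 1e-07)])
  new_ethotest("binomial_exact", "k", k, n = n, p_value = min(1, p))
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` from the
#' confusion matrix of two equal-length categorical codings. Unavailable
#' when expected agreement is 1 (a single shared category).
#'
#' @param codes1,codes2 Equal-length vectors of category labels.
#' @return A one-row `ethotest` tibble (`value` = kappa).
#' @export
cohens_kappa <- function(codes1, codes2) {
  if (length(codes1) != length(codes2)) abort("codings must have equal length")
  if (length(codes1) == 0) abort("empty codings")
  lev <- sort(unique(c(as.character(codes1), as.character(codes2))))
  f1 <- factor(codes1, levels = lev)
  f2 <- factor(codes2, levels = lev)
  cm <- table(f1, f2)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    return(new_ethotest("cohens_kappa", "kappa", NA_real_, n = n,
                        note = "expected agreement is 1"))
  }
  new_ethotest("cohens_kappa", "kappa", (po - pe) / (1 - pe), n = n)
}

#' Duration-per-occurrence inter-observer agreement
#'
#' For each duration measurement trial the smaller of the two observers'
#' durations is divided by the larger; the IOA is the mean of these ratios
#' expressed as a percentage.
#'
#' @param d1,d2 Paired positive durations (seconds), one pair per trial.
#' @return A one-row tibble: `n_trials`, `mean_ratio`, `ioa_pct`.
#' @export
#' @examples
#' duration_ioa(15, 20)  # single trial: ratio 0.75, IOA 75%
duration_ioa <- function(d1, d2) {
  if (length(d1) != length(d2)) abort("d1 and d2 must have equal length")
  if (length(d1) == 0) abort("need at least one trial")
  if (any(d1 <= 0) || any(d2 <= 0)) abort("durations must be positive")
  ratio <- pmin(d1, d2) / pmax(d1, d2)
  tibble::tibble(n_trials = length(ratio), mean_ratio = mean(ratio),
                 ioa_pct = 100 * mean(ratio))
}
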