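#' Pearson brain-behavior correlation
#'
#' Pearson correlation with the parametric two-tailed p-value from the t
#' distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, equal length >= 3, both nonconstant.
#' @return List with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  x <- check_numeric_vector(x, "x", min_len = 3L)
  y <- check_numeric_vector(y, "y", min_len = 3L)
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("degenerate input: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's (1980) z test for the difference between two correlations that
#' share a variable (the Lee & Preacher web-utility variant): with behavior
#' `j` and the two conditions' similarities `k` and `h`, tests
#' `H0: rho_jk = rho_jh` using Fisher-transformed correlations and the pooled
#' covariance correction that accounts for `r_kh`.
#'
#' @param r_jk,r_jh The two correlations being compared (each with the common
#'   variable `j`); `|r| < 1`.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @param tails 1 or 2.
#' @return List (class `dependent_corr`) with `z_stat`, `p`, `r_jk`, `r_jh`,
#'   `r_kh`, `n`, `tails`.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n, tails = 2L) {
  for (r in c(r_jk, r_jh, r_kh)) {
    if (!is.finite(r) || abs(r) >= 1) stopf("correlations must satisfy |r| < 1")
  }
  n <- check_count(n, "n", min = 4L)
  if (!tails %in% c(1L, 2L)) stopf("'tails' must be 1 or 2")
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3L, 3L)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stopf("inconsistent correlation triple (r_jk=%.3f, r_jh=%.3f, r_kh=%.3f): not positive semidefinite",
          r_jk, r_jh, r_kh)
  }
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  sbar <- psi / (1 - rbar^2)^2
  z_stat <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * sbar))
  p <- if (tails == 2L) 2 * stats::pnorm(-abs(z_stat)) else stats::pnorm(-abs(z_stat))
  structure(list(z_stat = z_stat, p = p, r_jk = r_jk, r_jh = r_jh, r_kh = r_kh,
                 n = n, tails = as.integer(tails)),
            class = "dependent_corr")
}

## Shared tail bookkeeping for the permutation tests. Monte-Carlo p-values use
## the add-one rule (never exactly zero); exhaustive p-values are plain
## proportions over the full enumeration, which includes the identity
## assignment and is therefore also never zero.
perm_pvalues <- function(r_obs, r_null, exhaustive) {
  one_side <- if (r_obs >= 0) r_null >= r_obs - 1e-12 else r_null <= r_obs + 1e-12
  two_side <- abs(r_null) >= abs(r_obs) - 1e-12
  if (exhaustive) {
    list(p_one = mean(one_side), p_two = mean(two_side))
  } else {
    m <- length(r_null)
    list(p_one = (1 + sum(one_side)) / (m + 1), p_two = (1 + sum(two_side)) / (m + 1))
  }
}

perm_result <- function(r_obs, r_null, scheme, seed, n_possible, exhaustive) {
  p <- perm_pvalues(r_obs, r_null, exhaustive)
  structure(list(r_obs = r_obs, null_dist = r_null, p_one = p$p_one, p_two = p$p_two,
                 n_perm = length(r_null), scheme = scheme, seed = seed,
                 n_possible = n_possible, exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s-subject permutation test (%s, %d draws of %s possible)\n",
              x$scheme, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_perm, format(x$n_possible, big.mark = ",")))
  cat(sprintf("  r_obs = %.4f; p (one-tailed, observed direction) = %.4g; p (two-tailed) = %.4g\n",
              x$r_obs, x$p_one, x$p_two))
  invisible(x)
}

#' Between-subject permutation test of a brain-behavior correlation
#'
#' Builds the null distribution by shuffling the similarity values across
#' subjects and recomputing the Pearson correlation with the behavioral
#' outcome. The one-tailed p is directed by the sign of the observed
#' correlation; the two-tailed p compares absolute values. With `exhaustive =
#' TRUE` (n <= 9) all `n!` permutations are enumerated; otherwise `n_perm`
#' Monte-Carlo draws are taken and p-values use the add-one rule.
#'
#' @param similarity Per-subject Fisher-z similarity values.
#' @param outcome Per-subject behavioral outcomes (aligned by subject).
#' @param n_perm Monte-Carlo iterations.
#' @param seed RNG seed for the draws.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return A `permutation_result`: observed r, null distribution, one- and
#'   two-tailed p, scheme, seed, and the size `n!` of the permutation space.
#' @export
permutation_test_between <- function(similarity, outcome, n_perm = 5000L,
                                     seed = 1L, exhaustive = FALSE) {
  x <- check_numeric_vector(similarity, "similarity", min_len = 5L)
  y <- check_numeric_vector(outcome, "outcome", min_len = 5L)
  if (length(x) != length(y)) stopf("'similarity' and 'outcome' must be aligned by subject")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("degenerate input: constant vector")
  n <- length(x)
  r_obs <- stats::cor(x, y)
  if (exhaustive) {
    if (n > 9L) stopf("exhaustive between-subject mode supports n <= 9 (n! explodes)")
    idx <- all_permutations(n)
    X <- matrix(x[t(idx)], nrow = n)          # one permuted vector per column
    r_null <- as.numeric(stats::cor(X, y))
    return(perm_result(r_obs, r_null, "between", NA_integer_, factorial(n), TRUE))
  }
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
    X <- matrix(x[idx], nrow = n)
    r_null <- as.numeric(stats::cor(X, y))
    perm_result(r_obs, r_null, "between", seed, factorial(n), FALSE)
  })
}

#' Within-subject condition-swap permutation test
#'
#' Builds the null distribution by swapping, independently for each subject
#' with probability 1/2, the trained- and control-condition similarity values,
#' then recomputing the trained-condition correlation with the outcome. The
#' assignment space has `2^n` elements; `exhaustive = TRUE` (n <= 20)
#' enumerates all of them.
#'
#' @param sim_trained,sim_control Per-subject Fisher-z similarities for the
#'   two conditions, aligned by subject.
#' @param outcome Per-subject behavioral outcomes.
#' @inheritParams permutation_test_between
#' @return A `permutation_result` with `n_possible = 2^n`.
#' @export
permutation_test_within <- function(sim_trained, sim_control, outcome,
                                    n_perm = 5000L, seed = 1L, exhaustive = FALSE) {
  a <- check_numeric_vector(sim_trained, "sim_trained", min_len = 5L)
  b <- check_numeric_vector(sim_control, "sim_control", min_len = 5L)
  y <- check_numeric_vector(outcome, "outcome", min_len = 5L)
  n <- length(a)
  if (length(b) != n || length(y) != n) stopf("condition and outcome vectors must be aligned by subject")
  if (stats::sd(a) == 0 || stats::sd(y) == 0) stopf("degenerate input: constant vector")
  r_obs <- stats::cor(a, y)
  delta <- b - a
  if (exhaustive) {
    if (n > 20L) stopf("exhaustive within-subject mode supports n <= 20")
    masks <- seq_len(2^n) - 1L
    coin <- vapply(seq_len(n), function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L,
                   logical(length(masks)))
    X <- a + t(coin) * delta                  # n x 2^n swapped vectors
    r_null <- as.numeric(stats::cor(X, y))
    return(perm_result(r_obs, r_null, "within", NA_integer_, 2^n, TRUE))
  }
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  with_seed(seed, {
    coin <- matrix(stats::runif(n * n_perm) < 0.5, nrow = n)
    X <- a + coin * delta
    r_null <- as.numeric(stats::cor(X, y))
    perm_result(r_obs, r_null, "within", seed, 2^n, FALSE)
  })
}

#' Leave-one-out cross-validated prediction
#'
#' For each subject, fits the simple linear regression `outcome ~ similarity`
#' on the remaining `n - 1` subjects, predicts the held-out subject's outcome,
#' and records the relative prediction error
#' `(predicted - observed) / observed`.
#'
#' @param similarity Per-subject Fisher-z similarity values (n >= 4).
#' @param outcome Per-subject observed outcomes; must be nonzero.
#' @return List (class `loocv_result`) with `predicted`, `rel_error`,
#'   `max_abs_error`, `min_abs_error`.
#' @export
loocv_predict <- function(similarity, outcome) {
  x <- check_numeric_vector(similarity, "similarity", min_len = 4L)
  y <- check_numeric_vector(outcome, "outcome", min_len = 4L)
  if (length(x) != length(y)) stopf("'similarity' and 'outcome' must be aligned by subject")
  if (any(y == 0)) stopf("relative error undefined: observed outcome is zero")
  n <- length(x)
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i]; yt <- y[-i]
    if (stats::sd(xt) == 0) stopf("degenerate training fold %d: constant similarity", i)
    fit <- stats::lm(yt ~ xt)
    predicted[i] <- sum(stats::coef(fit) * c(1, x[i]))
  }
  rel_error <- (predicted - y) / y
  structure(list(predicted = predicted, rel_error = rel_error,
                 max_abs_error = max(abs(rel_error)),
                 min_abs_error = min(abs(rel_error))),
            class = "loocv_result")
}

#' Paired t test on matched similarity values
#'
#' Classical paired t test, used for the fast- vs slow-item median-split
#' contrast on per-subject Fisher-z similarities.
#'
#' @param fast_z,slow_z Per-subject values, equal length >= 3.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(fast_z, slow_z) {
  a <- check_numeric_vector(fast_z, "fast_z", min_len = 3L)
  b <- check_numeric_vector(slow_z, "slow_z", min_len = 3L)
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0))
    }
    stopf("degenerate paired differences: zero variance with nonzero mean")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate))
}
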