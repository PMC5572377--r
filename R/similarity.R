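#' Construct a pattern set
#'
#' A pattern set holds condition-mean voxel activation patterns (for example
#' GLM contrast estimates) as a 5-d array indexed subject x ROI x condition x
#' repetition x voxel, with exactly two repetitions.
#'
#' @param activations 5-d numeric array with dimnames on the first four axes.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(activations) {
  d <- dim(activations)
  if (length(d) != 5L) stopf("'activations' must be a 5-d array (subject, roi, condition, repetition, voxel)")
  if (d[4] != 2L) stopf("pattern sets require exactly 2 repetitions (got %d)", d[4])
  if (d[5] < 3L) stopf("pattern sets require >= 3 voxels per ROI (got %d)", d[5])
  if (any(!is.finite(activations))) stopf("'activations' contains non-finite values")
  dn <- dimnames(activations)
  if (is.null(dn) || any(vapply(dn[1:4], is.null, logical(1)))) {
    dn <- list(
      if (!is.null(dn[[1]])) dn[[1]] else sprintf("sub%02d", seq_len(d[1])),
      if (!is.null(dn[[2]])) dn[[2]] else paste0("roi", seq_len(d[2])),
      if (!is.null(dn[[3]])) dn[[3]] else paste0("cond", seq_len(d[3])),
      c("rep1", "rep2"),
      NULL
    )
    dimnames(activations) <- dn
  }
  structure(list(activations = activations), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$activations)
  cat(sprintf("Pattern set: %d subjects x %d ROIs x %d conditions x 2 reps x %d voxels\n",
              d[1], d[2], d[3], d[5]))
  invisible(x)
}

#' Cross-repetition pattern similarity
#'
#' Pearson product-moment correlation between the voxel activation patterns of
#' two repetitions of the same stimuli. Higher values indicate more
#' reproducible neural representations.
#'
#' @param rep1,rep2 Numeric voxel vectors of equal length (>= 3 voxels) with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pattern_similarity(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))  # 0.8
#' @export
pattern_similarity <- function(rep1, rep2) {
  rep1 <- check_numeric_vector(rep1, "rep1", min_len = 3L)
  rep2 <- check_numeric_vector(rep2, "rep2", min_len = 3L)
  if (length(rep1) != length(rep2)) {
    stopf("pattern length mismatch: %d vs %d voxels", length(rep1), length(rep2))
  }
  if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0) {
    stopf("degenerate pattern: zero variance across voxels")
  }
  stats::cor(rep1, rep2)
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` is `atanh(r)`, the variance-stabilizing transform of a
#' correlation; `inverse_fisher()` is `tanh(z)`. Correlations at exactly
#' `|r| = 1` are clamped to `1 - 1e-7` (with a warning) so downstream
#' statistics stay finite.
#'
#' @param r Correlation value(s) with `|r| <= 1`.
#' @param z Fisher-z value(s).
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stopf("fisher_z() requires |r| <= 1")
  }
  clamp <- 1 - 1e-7
  if (any(abs(r) >= clamp)) {
    warnf("correlation at |r| = 1 clamped to %g before Fisher transform", clamp)
    r <- pmin(pmax(r, -clamp), clamp)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

#' Cross-repetition similarity table
#'
#' Computes the Pearson pattern similarity between the two repetitions of each
#' (subject, ROI, condition) cell of a pattern set and Fisher-transforms it.
#'
#' @param patterns A [pattern_set()].
#' @return A data.frame (class `similarity_table`) with columns `subject`,
#'   `roi`, `condition`, `r`, `z`.
#' @export
similarity_table <- function(patterns) {
  if (!inherits(patterns, "pattern_set")) stopf("'patterns' must be a pattern_set")
  a <- patterns$activations
  dn <- dimnames(a)
  grid <- expand.grid(subject = dn[[1]], roi = dn[[2]], condition = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v1 <- a[grid$subject[i], grid$roi[i], grid$condition[i], 1L, ]
    v2 <- a[grid$subject[i], grid$roi[i], grid$condition[i], 2L, ]
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
      stopf("degenerate pattern in cell (%s, %s, %s): zero voxel variance",
            grid$subject[i], grid$roi[i], grid$condition[i])
    }
    r[i] <- stats::cor(v1, v2)
  }
  out <- data.frame(grid, r = r, z = fisher_z(r), stringsAsFactors = FALSE)
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Group-mean pattern similarity for an item subset
#'
#' Averages item-level voxel patterns over a set of items (separately per
#' repetition) and computes the cross-repetition similarity of the averaged
#' pattern for every subject x ROI cell. This is the item-level path used by
#' the median-split analysis, where the trained items are re-modeled in fast
#' and slow naming groups.
#'
#' @param item_patterns An `item_pattern_set` array
#'   (subject x roi x item x repetition x voxel), e.g. from
#'   [simulate_patterns()].
#' @param items Integer indices (or item dimnames) of the items to average.
#' @return Data.frame with columns `subject`, `roi`, `r`, `z`.
#' @export
item_group_similarity <- function(item_patterns, items) {
  d <- dim(item_patterns)
  if (length(d) != 5L) stopf("'item_patterns' must be a 5-d item pattern array")
  dn <- dimnames(item_patterns)
  if (is.character(items)) items <- match(items, dn[[3]])
  if (anyNA(items) || length(items) < 1L) stopf("'items' selects no valid items")
  grid <- expand.grid(subject = dn[[1]], roi = dn[[2]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    block <- item_patterns[grid$subject[i], grid$roi[i], items, , , drop = FALSE]
    m1 <- apply(block[1, 1, , 1, , drop = FALSE], 5L, mean)
    m2 <- apply(block[1, 1, , 2, , drop = FALSE], 5L, mean)
    r[i] <- pattern_similarity(m1, m2)
  }
  data.frame(grid, r = r, z = fisher_z(r), stringsAsFactors = FALSE)
}

#' Percent signal change
#'
#' ROI activation level expressed as percent signal change:
#' `contrast / run_mean * ppheight * 100`, where `ppheight` is the peak height
#' of the hemodynamic response relative to baseline.
#'
#' @param contrast Contrast (parameter-estimate) value.
#' @param run_mean Mean signal of the run; must be nonzero.
#' @param ppheight Design peak height (unitless).
#' @return Percent signal change.
#' @examples
#' percent_signal_change(5, 200, 1.5)  # 3.75
#' @export
percent_signal_change <- function(contrast, run_mean, ppheight = 1) {
  if (any(run_mean == 0)) stopf("percent signal change undefined: run mean is zero")
  contrast / run_mean * ppheight * 100
}
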