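#' Construct a behavior table
#'
#' Holds naming performance over the training period: mean RT (ms) and
#' accuracy per subject x day x task, plus optional per-item RTs for the
#' median-split analysis.
#'
#' @param rt Data.frame with columns `subject`, `day`, `task`, `rt` and
#'   optionally `accuracy`.
#' @param item_rt Optional data.frame with columns `item`, `day`, `task`, `rt`.
#' @return An object of class `behavior_table`.
#' @export
behavior_table <- function(rt, item_rt = NULL) {
  need <- c("subject", "day", "task", "rt")
  if (!all(need %in% names(rt))) {
    stopf("behavior 'rt' table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(rt$rt <= 0)) stopf("RTs must be positive")
  if ("accuracy" %in% names(rt) && any(rt$accuracy < 0 | rt$accuracy > 1, na.rm = TRUE)) {
    stopf("accuracy must lie in [0, 1]")
  }
  days <- sort(unique(rt$day))
  if (!identical(as.integer(days), seq_len(length(days)))) {
    stopf("days must be consecutive integers starting at 1")
  }
  if (!is.null(item_rt)) {
    ineed <- c("item", "day", "task", "rt")
    if (!all(ineed %in% names(item_rt))) {
      stopf("behavior 'item_rt' table must have columns %s", paste(ineed, collapse = ", "))
    }
  }
  structure(list(rt = rt, item_rt = item_rt), class = "behavior_table")
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("Behavior table: %d subjects x %d days x %d tasks%s\n",
              length(unique(x$rt$subject)), max(x$rt$day),
              length(unique(x$rt$task)),
              if (is.null(x$item_rt)) "" else
                sprintf("; item RTs for %d items", length(unique(x$item_rt$item)))))
  invisible(x)
}

#' Daily naming speed averaged over tasks
#'
#' Naming speed for each day is the unweighted mean of the RTs of the naming
#' tasks (word and picture naming), computed per subject. Every task must be
#' present for every subject x day cell.
#'
#' @param behavior A [behavior_table()].
#' @return Data.frame with columns `subject`, `day`, `rt`.
#' @export
daily_mean_rt <- function(behavior) {
  rt <- behavior$rt
  tasks <- unique(rt$task)
  counts <- stats::aggregate(task ~ subject + day, data = rt, FUN = length)
  bad <- counts[counts$task != length(tasks), , drop = FALSE]
  if (nrow(bad) > 0L) {
    stopf("missing task-day cell: subject %s, day %d has %d of %d tasks",
          bad$subject[1], bad$day[1], bad$task[1], length(tasks))
  }
  out <- stats::aggregate(rt ~ subject + day, data = rt, FUN = mean)
  out[order(out$subject, out$day), , drop = FALSE]
}

#' Post-training behavioral outcome
#'
#' Per-subject mean RT over the post-learning plateau (default Days 5-12) for
#' one naming task; the learning curves are flat over this range, so the mean
#' summarizes attained naming speed.
#'
#' @param behavior A [behavior_table()].
#' @param task Task label to summarize.
#' @param days Days entering the outcome mean.
#' @return Named numeric vector of outcome RTs (ms), one per subject.
#' @export
post_training_outcome <- function(behavior, task, days = 5:12) {
  rt <- behavior$rt[behavior$rt$task == task, , drop = FALSE]
  if (nrow(rt) == 0L) stopf("task '%s' not present in behavior table", task)
  missing_days <- setdiff(days, unique(rt$day))
  if (length(missing_days) > 0L) {
    stopf("behavior table lacks day(s) %s required for the outcome",
          paste(missing_days, collapse = ", "))
  }
  rt <- rt[rt$day %in% days, , drop = FALSE]
  agg <- stats::aggregate(rt ~ subject, data = rt, FUN = mean)
  stats::setNames(agg$rt, agg$subject)
}

#' Per-item post-training outcome
#'
#' Mean per-item RT over the plateau days for one task; used to form the
#' fast/slow median-split groups.
#'
#' @param behavior A [behavior_table()] carrying `item_rt`.
#' @param task Task label.
#' @param days Days entering the mean.
#' @return Named numeric vector of item outcome RTs.
#' @export
item_outcomes <- function(behavior, task, days = 5:12) {
  if (is.null(behavior$item_rt)) stopf("behavior table has no item-level RTs")
  it <- behavior$item_rt[behavior$item_rt$task == task & behavior$item_rt$day %in% days, ,
                         drop = FALSE]
  if (nrow(it) == 0L) stopf("no item RTs for task '%s' in days %s", task,
                            paste(range(days), collapse = "-"))
  agg <- stats::aggregate(rt ~ item, data = it, FUN = mean)
  stats::setNames(agg$rt, agg$item)
}

#' Fit a power-law learning curve
#'
#' Fits `RT = a * day^(-b)` by nonlinear least squares, where `a` is initial
#' performance (ms) and `b` the learning rate (larger `b` = faster learning).
#' Starting values come from ordinary least squares on `log(RT) ~ log(day)`;
#' the fit is then refined on the original scale with Levenberg-Marquardt
#' (minpack.lm). Goodness of fit is `R^2 = 1 - SS_res / SS_tot` on the
#' original (not log) scale; for constant RTs `SS_tot = 0` and `r2` is
#' reported as `NaN`.
#'
#' @param days Vector of day indices (>= 3 values).
#' @param rts Positive RTs, same length.
#' @return An object of class `learning_fit`: list with `a`, `b`, `r2`,
#'   `converged`, `n_days`, `message`.
#' @examples
#' fit_power_curve(1:12, 2000 * (1:12)^-0.3)
#' @export
fit_power_curve <- function(days, rts) {
  days <- check_numeric_vector(days, "days", min_len = 3L)
  rts <- check_numeric_vector(rts, "rts", min_len = 3L)
  if (length(days) != length(rts)) stopf("'days' and 'rts' must have equal length")
  if (any(rts <= 0)) stopf("RTs must be positive for the power-law fit")
  if (any(days <= 0)) stopf("days must be positive")

  fit_obj <- function(a, b, converged, msg = "") {
    pred <- a * days ^ (-b)
    ss_res <- sum((rts - pred)^2)
    ss_tot <- sum((rts - mean(rts))^2)
    r2 <- if (ss_tot == 0) NaN else 1 - ss_res / ss_tot
    structure(list(a = a, b = b, r2 = r2, converged = converged,
                   n_days = length(days), message = msg),
              class = "learning_fit")
  }

  if (stats::sd(rts) == 0) {
    # Flat trajectory: a = constant RT, b = 0 fits exactly; R^2 undefined.
    return(fit_obj(rts[1], 0, converged = TRUE,
                   msg = "constant RTs: R^2 undefined (SS_tot = 0)"))
  }

  ols <- stats::lm(log(rts) ~ log(days))
  a0 <- exp(stats::coef(ols)[[1]])
  b0 <- -stats::coef(ols)[[2]]
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(rts ~ a * days ^ (-b),
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(nls_fit, "error")) {
    return(fit_obj(a0, b0, converged = FALSE,
                   msg = sprintf("refinement failed (%s); log-log OLS start reported",
                                 conditionMessage(nls_fit))))
  }
  cf <- stats::coef(nls_fit)
  fit_obj(cf[["a"]], cf[["b"]], converged = nls_fit$convInfo$isConv)
}

#' @export
print.learning_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: a = %.2f ms, b = %.4f, R^2 = %.4f (%s)\n",
              x$a, x$b, x$r2,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  invisible(x)
}

#' Filter learning-curve fits by goodness of fit
#'
#' Excludes fits whose `R^2` falls below a threshold (or is undefined), the
#' standard guard before correlating learning rates with other measures.
#'
#' @param fits Named list of [fit_power_curve()] results (names = subject ids).
#' @param r2_min Minimum `R^2` to keep, in `[0, 1]`.
#' @return List with `kept` and `excluded` (both named lists of fits).
#' @export
filter_fits <- function(fits, r2_min = 0.7) {
  r2_min <- check_number(r2_min, "r2_min", min = 0, max = 1)
  r2 <- vapply(fits, function(f) as.numeric(f$r2), numeric(1))
  keep <- !is.na(r2) & r2 >= r2_min
  list(kept = fits[keep], excluded = fits[!keep])
}

#' Median split of items by outcome RT
#'
#' Divides items into fast and slow naming groups at the median of their
#' post-training RTs. Items are stably ordered by (RT, original position); the
#' lower half (first `ceiling(n/2)` items) forms the fast group, so for even
#' counts the groups are equal and for odd counts they differ by one. Ties
#' spanning the boundary are broken by original item order with a warning.
#'
#' @param item_outcomes Named numeric vector of per-item outcome RTs.
#' @return List with `fast` and `slow` character vectors of item ids.
#' @examples
#' median_split_items(c(i1 = 2, i2 = 4, i3 = 6, i4 = 8))
#' @export
median_split_items <- function(item_outcomes) {
  n <- length(item_outcomes)
  if (n < 2L) stopf("median split requires at least 2 items")
  ids <- names(item_outcomes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(item_outcomes, seq_len(n))  # stable: RT then original position
  k <- ceiling(n / 2)
  boundary_tie <- item_outcomes[ord[k]] == item_outcomes[ord[min(k + 1L, n)]] && k < n
  if (boundary_tie) {
    warnf("tied RTs at the median split boundary; resolved by item order")
  }
  list(fast = ids[ord[seq_len(k)]], slow = ids[ord[seq.int(k + 1L, n)]])
}
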