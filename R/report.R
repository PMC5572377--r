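#' Analysis run configuration
#'
#' Bundles the constants of the ROI brain-behavior analysis: permutation
#' count, significance level, ROI and task labels, goodness-of-fit threshold
#' for the learning-rate analysis, and the plateau day range defining the
#' behavioral outcome.
#'
#' @param n_perm Permutation iterations per test (default 5000).
#' @param alpha Significance level.
#' @param rois ROI labels (default: left pars opercularis, left pars
#'   triangularis, left fusiform, right fusiform).
#' @param tasks Naming task labels.
#' @param r2_min Minimum learning-curve `R^2` for the learning-rate analysis.
#' @param outcome_days Days averaged into the post-training outcome.
#' @param seed Root seed for the permutation streams.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_perm = 5000L,
                       alpha = 0.05,
                       rois = c("left_pars_opercularis", "left_pars_triangularis",
                                "left_fusiform", "right_fusiform"),
                       tasks = c("word_naming", "picture_naming"),
                       r2_min = 0.7,
                       outcome_days = 5:12,
                       seed = 1L) {
  structure(list(
    n_perm = check_count(n_perm, "n_perm", min = 1L),
    alpha = check_number(alpha, "alpha", min = 1e-12, max = 1),
    rois = as.character(rois),
    tasks = as.character(tasks),
    r2_min = check_number(r2_min, "r2_min", min = 0, max = 1),
    outcome_days = as.integer(outcome_days),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "run_config")
}

#' Run the full ROI brain-behavior analysis
#'
#' End-to-end orchestration of the pattern-similarity pipeline. For every ROI
#' and naming task it computes: the trained- and control-condition Pearson
#' correlations between cross-repetition similarity (Fisher z) and the
#' post-training outcome RT; the dependent-correlation comparison of the two
#' conditions (sharing the behavioral variable, with the cross-correlation
#' between the two similarity vectors estimated from the data); between- and
#' within-subject permutation tests for the trained condition; and
#' leave-one-out cross-validated prediction with relative errors. It also fits
#' per-subject power-law learning curves on the task-averaged daily RTs,
#' excludes poor fits (`R^2 <` threshold), and correlates the learning rate
#' `b` with trained-condition similarity per ROI; when item-level data are
#' supplied it runs the fast/slow median-split paired t tests.
#'
#' No multiple-comparison adjustment is applied across ROI x task cells; the
#' report states the number of tests and includes an optional Bonferroni
#' column.
#'
#' @param patterns A [pattern_set()] whose condition axis contains `"trained"`
#'   and `"control"`.
#' @param behavior A [behavior_table()] aligned to the same subjects.
#' @param config A [run_config()]; ROI/task labels must match the data.
#' @param item_patterns Optional `item_pattern_set` for the median-split
#'   analysis (requires `behavior$item_rt`).
#' @return An object of class `rsa_report`: list with elements
#'   `brain_behavior` (data.frame per ROI x task x condition), `dependent`
#'   (condition comparison per ROI x task), `permutation` (nested results),
#'   `loocv`, `learning_rate`, `median_split`, `n_tests`, `config`.
#' @export
run_full_analysis <- function(patterns, behavior, config = run_config(),
                              item_patterns = NULL) {
  if (!inherits(patterns, "pattern_set")) stopf("'patterns' must be a pattern_set")
  if (!inherits(behavior, "behavior_table")) stopf("'behavior' must be a behavior_table")
  dn <- dimnames(patterns$activations)
  if (!all(c("trained", "control") %in% dn[[3]])) {
    stopf("pattern set must contain 'trained' and 'control' conditions")
  }
  rois <- dn[[2]]
  subjects <- dn[[1]]
  bsubj <- sort(unique(behavior$rt$subject))
  if (!setequal(subjects, bsubj)) {
    stopf("subject ids differ between patterns (%d) and behavior (%d)",
          length(subjects), length(bsubj))
  }

  sim <- similarity_table(patterns)
  z_of <- function(roi, condition) {
    rows <- sim[sim$roi == roi & sim$condition == condition, , drop = FALSE]
    stats::setNames(rows$z, rows$subject)[subjects]
  }

  bb_rows <- list(); dep_rows <- list()
  perms <- list(); loocvs <- list()
  test_id <- 0L
  for (task in config$tasks) {
    outcome <- tryCatch(
      post_training_outcome(behavior, task, config$outcome_days),
      error = function(e) stopf("outcome stage failed for task '%s': %s",
                                task, conditionMessage(e))
    )[subjects]
    for (roi in rois) {
      test_id <- test_id + 1L
      z_tr <- z_of(roi, "trained")
      z_ct <- z_of(roi, "control")
      ct_tr <- correlate(z_tr, outcome)
      ct_ct <- correlate(z_ct, outcome)
      bb_rows[[length(bb_rows) + 1L]] <- data.frame(
        roi = roi, task = task,
        condition = c("trained", "control"),
        r = c(ct_tr$r, ct_ct$r), p = c(ct_tr$p, ct_ct$p),
        n = ct_tr$n, stringsAsFactors = FALSE
      )
      r_kh <- stats::cor(z_tr, z_ct)
      dep <- compare_dependent_correlations(ct_tr$r, ct_ct$r, r_kh,
                                            n = length(subjects), tails = 1L)
      dep_rows[[length(dep_rows) + 1L]] <- data.frame(
        roi = roi, task = task, z_stat = dep$z_stat, p_one = dep$p,
        r_trained = ct_tr$r, r_control = ct_ct$r, r_kh = r_kh,
        stringsAsFactors = FALSE
      )
      key <- paste(roi, task, sep = ".")
      perms[[key]] <- list(
        between = permutation_test_between(z_tr, outcome, n_perm = config$n_perm,
                                           seed = child_seed(config$seed, 100L + test_id)),
        within = permutation_test_within(z_tr, z_ct, outcome, n_perm = config$n_perm,
                                         seed = child_seed(config$seed, 200L + test_id))
      )
      loocvs[[key]] <- loocv_predict(z_tr, outcome)
    }
  }
  brain_behavior <- do.call(rbind, bb_rows)
  n_tests <- sum(brain_behavior$condition == "trained")
  brain_behavior$p_bonferroni <- pmin(1, brain_behavior$p * n_tests)
  brain_behavior$significant <- brain_behavior$p < config$alpha

  # Learning-rate analysis on task-averaged daily RTs.
  daily <- daily_mean_rt(behavior)
  fits <- lapply(stats::setNames(subjects, subjects), function(s) {
    d <- daily[daily$subject == s, , drop = FALSE]
    fit_power_curve(d$day, d$rt)
  })
  flt <- filter_fits(fits, config$r2_min)
  kept_ids <- names(flt$kept)
  learning_rate <- NULL
  if (length(kept_ids) >= 3L) {
    b_hat <- vapply(flt$kept, function(f) f$b, numeric(1))
    lr_rows <- lapply(rois, function(roi) {
      ct <- correlate(z_of(roi, "trained")[kept_ids], b_hat)
      data.frame(roi = roi, r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
    })
    learning_rate <- list(table = do.call(rbind, lr_rows),
                          n_kept = length(kept_ids),
                          n_excluded = length(flt$excluded),
                          excluded = names(flt$excluded))
  }

  # Median-split contrast, when item-level patterns and RTs are available.
  median_split <- NULL
  if (!is.null(item_patterns) && !is.null(behavior$item_rt)) {
    ms_rows <- list()
    for (task in config$tasks) {
      io <- item_outcomes(behavior, task, config$outcome_days)
      grp <- median_split_items(io)
      fast_idx <- as.integer(sub("^item", "", grp$fast))
      slow_idx <- as.integer(sub("^item", "", grp$slow))
      if (anyNA(fast_idx)) { fast_idx <- match(grp$fast, dimnames(item_patterns)[[3]]) }
      if (anyNA(slow_idx)) { slow_idx <- match(grp$slow, dimnames(item_patterns)[[3]]) }
      fast_sim <- item_group_similarity(item_patterns, fast_idx)
      slow_sim <- item_group_similarity(item_patterns, slow_idx)
      for (roi in rois) {
        fz <- fast_sim$z[fast_sim$roi == roi][match(subjects, fast_sim$subject[fast_sim$roi == roi])]
        sz <- slow_sim$z[slow_sim$roi == roi][match(subjects, slow_sim$subject[slow_sim$roi == roi])]
        tt <- paired_t_test(fz, sz)
        ms_rows[[length(ms_rows) + 1L]] <- data.frame(
          roi = roi, task = task, t = tt$t, df = tt$df, p = tt$p,
          mean_diff = tt$mean_diff, stringsAsFactors = FALSE
        )
      }
    }
    median_split <- do.call(rbind, ms_rows)
  }

  structure(list(
    brain_behavior = brain_behavior,
    dependent = do.call(rbind, dep_rows),
    permutation = perms,
    loocv = loocvs,
    learning_rate = learning_rate,
    median_split = median_split,
    n_tests = n_tests,
    config = config
  ), class = "rsa_report")
}

#' Significant trained-condition cells of a report
#'
#' @param report An `rsa_report`.
#' @param alpha Significance level (defaults to the report's).
#' @return Data.frame of ROI x task cells whose trained-condition correlation
#'   p-value falls below `alpha`.
#' @export
report_flags <- function(report, alpha = report$config$alpha) {
  bb <- report$brain_behavior
  bb[bb$condition == "trained" & bb$p < alpha, c("roi", "task", "r", "p"), drop = FALSE]
}

#' @export
print.rsa_report <- function(x, ...) {
  cat("ROI brain-behavior analysis report\n")
  cat(sprintf("  %d trained-condition tests (no multiplicity adjustment; Bonferroni column provided)\n",
              x$n_tests))
  bb <- x$brain_behavior[x$brain_behavior$condition == "trained", , drop = FALSE]
  for (i in seq_len(nrow(bb))) {
    key <- paste(bb$roi[i], bb$task[i], sep = ".")
    pm <- x$permutation[[key]]
    cat(sprintf("  %-24s %-15s r = %+.3f  p = %.4f  perm p(btw/wth) = %.4f/%.4f  max|rel err| = %.3f\n",
                bb$roi[i], bb$task[i], bb$r[i], bb$p[i],
                pm$between$p_two, pm$within$p_two,
                x$loocv[[key]]$max_abs_error))
  }
  if (!is.null(x$learning_rate)) {
    cat(sprintf("  learning-rate analysis: %d kept, %d excluded (R^2 < %.2f)\n",
                x$learning_rate$n_kept, x$learning_rate$n_excluded, x$config$r2_min))
  }
  if (!is.null(x$median_split)) {
    cat(sprintf("  median-split paired tests: %d ROI x task cells\n", nrow(x$median_split)))
  }
  invisible(x)
}
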