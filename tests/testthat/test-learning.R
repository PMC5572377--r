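test_that("daily_mean_rt averages the two naming tasks and flags missing cells", {
  beh <- toy_behavior("s1", 3, function(s, d, task) {
    if (task == "word_naming") 800 + 10 * d else 1000 + 10 * d
  })
  daily <- daily_mean_rt(beh)
  expect_equal(daily$rt, 900 + 10 * (1:3))

  const <- toy_behavior(c("s1", "s2"), 4, function(s, d, task) 700)
  expect_true(all(daily_mean_rt(const)$rt == 700))

  broken <- beh
  broken$rt <- broken$rt[-1, ]
  expect_error(daily_mean_rt(broken), "missing task-day cell")
})

test_that("daily_mean_rt matches a spreadsheet-style oracle on a 12-day table", {
  set.seed(55)
  vals <- new.env()
  beh <- toy_behavior(c("a", "b"), 12, function(s, d, task) {
    v <- round(runif(1, 600, 1600), 1)
    assign(paste(s, d, task), v, envir = vals)
    v
  })
  daily <- daily_mean_rt(beh)
  for (i in seq_len(nrow(daily))) {
    expected <- mean(c(get(paste(daily$subject[i], daily$day[i], "word_naming"), envir = vals),
                       get(paste(daily$subject[i], daily$day[i], "picture_naming"), envir = vals)))
    expect_equal(daily$rt[i], expected, tolerance = 1e-12)
  }
})

test_that("post_training_outcome averages days 5-12 and ignores days 1-4", {
  beh <- toy_behavior("s1", 12, function(s, d, task) {
    if (task != "word_naming") return(999)
    if (d < 5) 5000 else 850 - 10 * (d - 5)
  })
  out <- post_training_outcome(beh, "word_naming")
  expect_equal(unname(out), 815)

  # perturbing days 1-4 leaves the outcome unchanged
  beh2 <- toy_behavior("s1", 12, function(s, d, task) {
    if (task != "word_naming") return(999)
    if (d < 5) 100 * d else 850 - 10 * (d - 5)
  })
  expect_equal(post_training_outcome(beh2, "word_naming"), out)

  short <- toy_behavior("s1", 8, function(s, d, task) 900)
  expect_error(post_training_outcome(short, "word_naming"), "day")
})

test_that("fit_power_curve recovers noiseless parameters exactly", {
  fit <- fit_power_curve(1:12, 2000 * (1:12)^(-0.3))
  expect_true(fit$converged)
  expect_equal(fit$a, 2000, tolerance = 1e-6)
  expect_equal(fit$b, 0.3, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-6)
})

test_that("fit_power_curve handles constant RTs as the degenerate flat curve", {
  fit <- fit_power_curve(1:10, rep(700, 10))
  expect_true(fit$converged)
  expect_equal(fit$b, 0)
  expect_true(is.nan(fit$r2))
})

test_that("fit_power_curve validates inputs", {
  expect_error(fit_power_curve(1:5, c(900, 800, -1, 700, 650)), "positive")
  expect_error(fit_power_curve(1:2, c(900, 800)), "length")
})

test_that("R^2 never exceeds 1 and hits 1 only with zero residuals", {
  set.seed(77)
  for (i in 1:20) {
    y <- 1800 * (1:12)^(-0.25) + rnorm(12, 0, 40)
    fit <- fit_power_curve(1:12, y)
    expect_lte(fit$r2, 1)
    expect_lt(fit$r2, 1)  # noise guarantees residuals
  }
})

test_that("fit inverts the zero-noise generator (parameter recovery)", {
  cfg <- simulation_config(n_subjects = 4, n_voxels = 12, n_rois = 1,
                           a_range = c(1700, 2300), b_range = c(0.15, 0.45),
                           coupling_slope = 0, rt_noise_sd = 0,
                           task_offsets = c(word_naming = 0, picture_naming = 0),
                           simulate_items = FALSE, seed = 12)
  ds <- simulate_dataset(cfg)
  daily <- daily_mean_rt(ds$behavior)
  for (s in names(ds$truth$a)) {
    d <- daily[daily$subject == s, ]
    fit <- fit_power_curve(d$day, d$rt)
    expect_equal(fit$a, unname(ds$truth$a[s]), tolerance = 1e-6 * ds$truth$a[s])
    expect_equal(fit$b, unname(ds$truth$b[s]), tolerance = 1e-6)
  }
})

test_that("filter_fits applies the R^2 threshold and drops undefined fits", {
  mk <- function(r2) structure(list(a = 1000, b = 0.3, r2 = r2, converged = TRUE),
                               class = "learning_fit")
  fits <- list(s1 = mk(0.9), s2 = mk(0.65), s3 = mk(0.71), s4 = mk(NaN))
  flt <- filter_fits(fits, 0.7)
  expect_identical(names(flt$kept), c("s1", "s3"))
  expect_identical(names(flt$excluded), c("s2", "s4"))
  all_defined <- filter_fits(fits, 0)
  expect_identical(names(all_defined$excluded), "s4")
})

test_that("median_split_items partitions items with near-equal group sizes", {
  grp <- median_split_items(c(i1 = 2, i2 = 4, i3 = 6, i4 = 8))
  expect_identical(grp$fast, c("i1", "i2"))
  expect_identical(grp$slow, c("i3", "i4"))

  set.seed(9)
  rts <- setNames(sample(30) * 10 + 600, paste0("it", 1:30))
  grp30 <- median_split_items(rts)
  expect_identical(length(grp30$fast), 15L)
  expect_identical(length(grp30$slow), 15L)
  expect_setequal(c(grp30$fast, grp30$slow), names(rts))
  expect_true(max(rts[grp30$fast]) <= min(rts[grp30$slow]))

  odd <- median_split_items(setNames(1:5, letters[1:5]))
  expect_identical(lengths(odd), c(fast = 3L, slow = 2L))

  expect_warning(tied <- median_split_items(setNames(rep(5, 6), letters[1:6])), "tie")
  expect_identical(tied$fast, letters[1:3])
})
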