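test_that("planted rho = 1 yields perfect cross-repetition correlation", {
  cfg <- simulation_config(n_subjects = 4, n_voxels = 12, n_rois = 1,
                           rho_trained = c(1, 1), rho_control = c(1, 1),
                           simulate_items = FALSE, seed = 3)
  sim <- simulate_patterns(cfg)
  a <- sim$patterns$activations
  for (s in 1:4) {
    r <- cor(a[s, 1, "trained", 1, ], a[s, 1, "trained", 2, ])
    expect_equal(r, 1, tolerance = 1e-10)
  }
})

test_that("planted correlations are recovered in the mean across many subjects", {
  for (rho in c(0, 0.5)) {
    cfg <- simulation_config(n_subjects = 500, n_voxels = 100, n_rois = 1,
                             rho_trained = c(rho, rho), simulate_items = FALSE,
                             seed = 17 + round(10 * rho))
    sim <- simulate_patterns(cfg)
    tab <- similarity_table(sim$patterns)
    obs <- tab$r[tab$condition == "trained"]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - rho), 3 * se)
  }
})

test_that("out-of-range planted correlations are rejected", {
  expect_error(simulation_config(rho_trained = c(-0.2, 1.3)), "rho_trained")
  expect_error(simulation_config(rho_trained = c(0.5, 0.1)), "rho_trained")
})

test_that("zero coupling and zero noise give identical trajectories for fixed (a, b)", {
  cfg <- simulation_config(n_subjects = 5, n_voxels = 12, n_rois = 1,
                           a_range = c(2000, 2000), b_range = c(0.3, 0.3),
                           coupling_slope = 0, rt_noise_sd = 0,
                           simulate_items = FALSE, seed = 8)
  ds <- simulate_dataset(cfg)
  wide <- reshape(ds$behavior$rt[ds$behavior$rt$task == "word_naming",
                                 c("subject", "day", "rt")],
                  idvar = "subject", timevar = "day", direction = "wide")
  traj <- as.matrix(wide[, -1])
  expect_true(all(abs(sweep(traj, 2, traj[1, ])) < 1e-9))
  expect_equal(unname(traj[1, ]), 2000 * (1:12)^(-0.3), tolerance = 1e-9)
})

test_that("negative coupling with zero noise gives perfect rank coupling on the plateau", {
  cfg <- simulation_config(n_subjects = 10, n_voxels = 12, n_rois = 1,
                           a_range = c(2000, 2000), b_range = c(0.3, 0.3),
                           coupling_slope = -150, rt_noise_sd = 0,
                           simulate_items = FALSE, seed = 21)
  sim <- simulate_patterns(cfg)
  beh <- simulate_behavior(cfg, sim$truth)
  out <- post_training_outcome(beh, "word_naming")
  z <- sim$truth$z_latent[match(names(out), names(sim$truth$a))]
  expect_equal(cor(z, out, method = "spearman"), -1)
})

test_that("identical seeds reproduce the dataset; different seeds differ", {
  a <- simulate_dataset(mini_config())
  b <- simulate_dataset(mini_config())
  c <- simulate_dataset(mini_config(seed = 43L))
  expect_identical(a$patterns$activations, b$patterns$activations)
  expect_identical(a$behavior$rt, b$behavior$rt)
  expect_false(identical(a$patterns$activations, c$patterns$activations))
})

test_that("component streams are independent: behavior can be regenerated alone", {
  cfg <- mini_config()
  sim <- simulate_patterns(cfg)
  b1 <- simulate_behavior(cfg, sim$truth)
  b2 <- simulate_behavior(cfg, sim$truth)
  expect_identical(b1$rt, b2$rt)
})

test_that("extreme parameters clip RT at the floor with a warning", {
  cfg <- simulation_config(n_subjects = 4, n_voxels = 12, n_rois = 1,
                           a_range = c(300, 300), b_range = c(1.5, 1.5),
                           rt_floor = 200, rt_noise_sd = 0, coupling_slope = 0,
                           simulate_items = FALSE, seed = 2)
  sim <- simulate_patterns(cfg)
  expect_warning(beh <- simulate_behavior(cfg, sim$truth), "floor")
  expect_true(all(beh$rt$rt >= 200))
})

test_that("item-level ground truth couples item similarity to item RT", {
  cfg <- simulation_config(n_subjects = 4, n_voxels = 20, n_rois = 1,
                           rt_noise_sd = 0, item_coupling_slope = -200, seed = 31)
  ds <- simulate_dataset(cfg)
  io <- item_outcomes(ds$behavior, "word_naming")
  z_item <- atanh(ds$truth$rho_item)[as.integer(names(io))]
  expect_equal(cor(z_item, io, method = "spearman"), -1)
  expect_identical(dim(ds$item_patterns), c(4L, 1L, 30L, 2L, 20L))
})
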