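#' Configure the synthetic-data generator
#'
#' The generator plants a known ground truth so every downstream stage of the
#' pattern-similarity pipeline can be validated: per-subject voxel patterns
#' whose two repetitions have a planted Pearson correlation, a power-law
#' reaction-time learning trajectory per subject over the training days, and a
#' negative coupling between the trained-condition pattern similarity (on the
#' Fisher-z scale) and the post-learning RT plateau.
#'
#' Two stimulus conditions are simulated: `"trained"` (the novel words whose
#' similarity is coupled to behavior) and `"control"` (a familiar language,
#' decoupled from behavior). Coupling acts only in the ROIs listed in
#' `coupled_rois`, where all coupled ROIs share the subject's latent
#' similarity; the remaining ROIs (and the control condition everywhere)
#' receive independent draws from the same correlation range.
#'
#' @param n_subjects Number of subjects.
#' @param n_voxels Voxels per ROI.
#' @param n_rois Number of ROIs.
#' @param roi_names Optional ROI labels (defaults to `roi1..roiK`).
#' @param rho_trained,rho_control Length-2 intervals; each subject's planted
#'   cross-repetition correlation is drawn uniformly from the interval.
#' @param coupled_rois Indices of ROIs whose trained-condition similarity
#'   drives behavior. Default: all ROIs.
#' @param coupling_slope RT shift per unit Fisher-z similarity, in ms; negative
#'   values mean more reproducible patterns predict faster naming.
#' @param a_range,b_range Intervals for the power-law parameters of
#'   `RT = a * day^(-b)` (a in ms; b dimensionless learning rate).
#' @param rt_noise_sd Day-level RT noise, ms.
#' @param task_offsets Named additive RT offsets per task, ms.
#' @param n_days Training days.
#' @param plateau_day First day of the post-learning plateau; the similarity
#'   coupling shifts RT only from this day on.
#' @param n_items Items in the trained condition (for the item-level path).
#' @param item_coupling_slope Item-level analogue of `coupling_slope`.
#' @param rt_floor Lower clip for simulated RTs, ms.
#' @param simulate_items Generate item-level patterns and RTs (needed by the
#'   median-split analysis)? Disable to save memory in large sweeps.
#' @param seed Root seed; schedule, pattern, behavior and item streams are
#'   derived from it so components can be regenerated independently.
#' @return An object of class `sim_config`.
#' @seealso [simulate_patterns()], [simulate_behavior()], [simulate_dataset()]
#' @export
simulation_config <- function(n_subjects = 24L,
                              n_voxels = 100L,
                              n_rois = 4L,
                              roi_names = NULL,
                              rho_trained = c(0.05, 0.7),
                              rho_control = c(0.05, 0.7),
                              coupled_rois = seq_len(n_rois),
                              coupling_slope = -150,
                              a_range = c(1900, 2100),
                              b_range = c(0.25, 0.35),
                              rt_noise_sd = 50,
                              task_offsets = c(word_naming = 0, picture_naming = 100),
                              n_days = 12L,
                              plateau_day = 5L,
                              n_items = 30L,
                              item_coupling_slope = coupling_slope,
                              rt_floor = 200,
                              simulate_items = TRUE,
                              seed = 1L) {
  check_interval <- function(x, name, lo, hi) {
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < lo || x[2] > hi) {
      stopf("'%s' must be an ordered interval within (%g, %g)", name, lo, hi)
    }
    as.numeric(x)
  }
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects", min = 2L),
    n_voxels = check_count(n_voxels, "n_voxels", min = 3L),
    n_rois = check_count(n_rois, "n_rois", min = 1L),
    rho_trained = check_interval(rho_trained, "rho_trained", -1, 1),
    rho_control = check_interval(rho_control, "rho_control", -1, 1),
    coupled_rois = as.integer(coupled_rois),
    coupling_slope = check_number(coupling_slope, "coupling_slope"),
    a_range = check_interval(a_range, "a_range", 1e-9, Inf),
    b_range = check_interval(b_range, "b_range", -Inf, Inf),
    rt_noise_sd = check_number(rt_noise_sd, "rt_noise_sd", min = 0),
    task_offsets = task_offsets,
    n_days = check_count(n_days, "n_days", min = 2L),
    plateau_day = check_count(plateau_day, "plateau_day", min = 1L),
    n_items = check_count(n_items, "n_items", min = 2L),
    item_coupling_slope = check_number(item_coupling_slope, "item_coupling_slope"),
    rt_floor = check_number(rt_floor, "rt_floor", min = 0),
    simulate_items = isTRUE(simulate_items),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(cfg$n_rois))
  if (length(roi_names) != cfg$n_rois) stopf("'roi_names' must have length n_rois")
  cfg$roi_names <- as.character(roi_names)
  if (length(cfg$coupled_rois) &&
      (min(cfg$coupled_rois) < 1L || max(cfg$coupled_rois) > cfg$n_rois)) {
    stopf("'coupled_rois' must index ROIs 1..%d", cfg$n_rois)
  }
  if (is.null(names(cfg$task_offsets)) || any(!nzchar(names(cfg$task_offsets)))) {
    stopf("'task_offsets' must be a named numeric vector (one entry per task)")
  }
  structure(cfg, class = "sim_config")
}

## One synthetic pattern pair: rep2 = rho * std(rep1) + sqrt(1-rho^2) * std(noise),
## so the population cross-repetition Pearson correlation equals rho.
plant_pair <- function(n_voxels, rho) {
  x <- stats::rnorm(n_voxels)
  e <- stats::rnorm(n_voxels)
  xs <- as.numeric(scale(x))
  es <- as.numeric(scale(e))
  cbind(rep1 = x, rep2 = rho * xs + sqrt(1 - rho^2) * es)
}

#' Simulate voxel pattern sets with planted similarity
#'
#' Draws per-subject, per-ROI, per-condition voxel patterns for two
#' repetitions such that the expected cross-repetition Pearson correlation
#' equals a planted value. In coupled ROIs the trained-condition correlation is
#' the subject's latent similarity (shared across those ROIs and later coupled
#' to behavior); everywhere else correlations are independent draws.
#'
#' @param config A [simulation_config()].
#' @return A list with `patterns` (a [pattern_set()]), `truth` (class
#'   `ground_truth`: planted correlations, latent Fisher-z values, power-law
#'   parameters drawn for behavior, item-level plants) and, when
#'   `config$simulate_items` is set, `item_patterns` (an `item_pattern_set`
#'   array subject x roi x item x repetition x voxel for the trained
#'   condition).
#' @export
simulate_patterns <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a simulation_config")
  ns <- config$n_subjects; nr <- config$n_rois; nv <- config$n_voxels
  conditions <- c("trained", "control")
  subjects <- sprintf("sub%02d", seq_len(ns))

  with_seed(child_seed(config$seed, 2L), {
    rho_latent <- stats::runif(ns, config$rho_trained[1], config$rho_trained[2])
    rho <- array(NA_real_, c(ns, nr, 2L),
                 dimnames = list(subjects, config$roi_names, conditions))
    for (r in seq_len(nr)) {
      rho[, r, "trained"] <- if (r %in% config$coupled_rois) {
        rho_latent
      } else {
        stats::runif(ns, config$rho_trained[1], config$rho_trained[2])
      }
      rho[, r, "control"] <- stats::runif(ns, config$rho_control[1], config$rho_control[2])
    }
    acts <- array(NA_real_, c(ns, nr, 2L, 2L, nv),
                  dimnames = list(subjects, config$roi_names, conditions,
                                  c("rep1", "rep2"), NULL))
    for (s in seq_len(ns)) for (r in seq_len(nr)) for (cc in 1:2) {
      pair <- plant_pair(nv, rho[s, r, cc])
      acts[s, r, cc, 1L, ] <- pair[, 1]
      acts[s, r, cc, 2L, ] <- pair[, 2]
    }

    # Per-subject behavioral parameters live in the ground truth so that
    # simulate_behavior() can be re-run without regenerating patterns.
    a_s <- stats::runif(ns, config$a_range[1], config$a_range[2])
    b_s <- stats::runif(ns, config$b_range[1], config$b_range[2])

    item_patterns <- NULL
    rho_item <- NULL
    if (config$simulate_items) {
      rho_item <- stats::runif(config$n_items, config$rho_trained[1], config$rho_trained[2])
      item_patterns <- array(
        NA_real_, c(ns, nr, config$n_items, 2L, nv),
        dimnames = list(subjects, config$roi_names,
                        paste0("item", seq_len(config$n_items)),
                        c("rep1", "rep2"), NULL)
      )
      for (s in seq_len(ns)) for (r in seq_len(nr)) for (i in seq_len(config$n_items)) {
        pair <- plant_pair(nv, rho_item[i])
        item_patterns[s, r, i, 1L, ] <- pair[, 1]
        item_patterns[s, r, i, 2L, ] <- pair[, 2]
      }
      class(item_patterns) <- "item_pattern_set"
    }

    truth <- structure(list(
      rho = rho,
      z_latent = atanh(rho_latent),
      a = stats::setNames(a_s, subjects),
      b = stats::setNames(b_s, subjects),
      rho_item = rho_item,
      coupling_slope = config$coupling_slope,
      item_coupling_slope = config$item_coupling_slope,
      coupled_rois = config$coupled_rois
    ), class = "ground_truth")

    list(patterns = pattern_set(acts), truth = truth, item_patterns = item_patterns)
  })
}

#' Simulate behavioral learning data coupled to planted similarity
#'
#' Generates per-subject, per-day, per-task naming RTs following a power-law
#' learning curve `RT = a * day^(-b)` plus, from the plateau day onward, an
#' additive shift `coupling_slope * z` where `z` is the subject's planted
#' trained-condition Fisher-z similarity. Accuracy follows a saturating curve
#' (generated for completeness; the analyses use RT only). When item-level
#' ground truth is present, per-item RTs with the analogous item-level
#' coupling are produced for the median-split analysis.
#'
#' @param config A [simulation_config()].
#' @param truth The `ground_truth` returned by [simulate_patterns()].
#' @return A [behavior_table()] with `rt`, `accuracy` and (optionally)
#'   `item_rt` components.
#' @export
simulate_behavior <- function(config, truth) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a simulation_config")
  if (!inherits(truth, "ground_truth")) stopf("'truth' must come from simulate_patterns()")
  ns <- config$n_subjects
  if (length(truth$a) != ns) stopf("ground truth does not match config dimensions")
  subjects <- names(truth$a)
  days <- seq_len(config$n_days)
  tasks <- names(config$task_offsets)

  with_seed(child_seed(config$seed, 3L), {
    grid <- expand.grid(subject = subjects, day = days, task = tasks,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    s_idx <- match(grid$subject, subjects)
    base <- truth$a[s_idx] * grid$day ^ (-truth$b[s_idx])
    plateau <- as.numeric(grid$day >= config$plateau_day)
    shift <- config$coupling_slope * truth$z_latent[s_idx] * plateau
    rt <- base + config$task_offsets[grid$task] + shift +
      stats::rnorm(nrow(grid), 0, config$rt_noise_sd)
    if (any(rt < config$rt_floor)) {
      warnf("%d simulated RTs fell below the %g ms floor and were clipped",
            sum(rt < config$rt_floor), config$rt_floor)
      rt <- pmax(rt, config$rt_floor)
    }
    acc <- 1 - 0.5 * grid$day ^ (-0.9) + stats::rnorm(nrow(grid), 0, 0.03)
    acc <- pmin(pmax(acc, 0), 1)
    rt_df <- data.frame(grid, rt = as.numeric(rt), accuracy = acc,
                        stringsAsFactors = FALSE)

    item_df <- NULL
    if (!is.null(truth$rho_item)) {
      a_bar <- mean(config$a_range); b_bar <- mean(config$b_range)
      z_item <- atanh(truth$rho_item)
      igrid <- expand.grid(item = seq_len(config$n_items), day = days, task = tasks,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      ibase <- a_bar * igrid$day ^ (-b_bar)
      ishift <- config$item_coupling_slope * z_item[igrid$item] *
        as.numeric(igrid$day >= config$plateau_day)
      irt <- ibase + config$task_offsets[igrid$task] + ishift +
        stats::rnorm(nrow(igrid), 0, config$rt_noise_sd)
      irt <- pmax(irt, config$rt_floor)
      item_df <- data.frame(igrid, rt = as.numeric(irt), stringsAsFactors = FALSE)
    }
    behavior_table(rt_df, item_rt = item_df)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_patterns()] and [simulate_behavior()]
#' under one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `patterns`, `truth`, `item_patterns`, `behavior`.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_subjects = 6, n_voxels = 20,
#'                                          n_rois = 2, simulate_items = FALSE,
#'                                          seed = 3))
#' similarity_table(ds$patterns)[1:4, ]
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_patterns(config)
  behavior <- simulate_behavior(config, sim$truth)
  c(sim, list(behavior = behavior))
}
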