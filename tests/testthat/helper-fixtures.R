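# Shared fixtures, built in code at test time.

# Small simulation configuration for fast end-to-end runs.
mini_config <- function(seed = 42L, ...) {
  simulation_config(n_subjects = 6L, n_voxels = 20L, n_rois = 2L,
                    simulate_items = FALSE, seed = seed, ...)
}

# Two-subject, one-ROI, one-condition pattern set with hand-entered 4-voxel
# patterns (used as a brute-force oracle for similarity_table).
tiny_patterns <- function() {
  a <- array(NA_real_, c(2, 1, 1, 2, 4),
             dimnames = list(c("s1", "s2"), "roiA", "trained",
                             c("rep1", "rep2"), NULL))
  a["s1", 1, 1, 1, ] <- c(1, 2, 3, 4)
  a["s1", 1, 1, 2, ] <- c(2, 1, 4, 3)
  a["s2", 1, 1, 1, ] <- c(10, 20, 15, 5)
  a["s2", 1, 1, 2, ] <- c(3, 8, 9, 1)
  pattern_set(a)
}

# Naive two-pass Pearson correlation, independent of stats::cor.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Behavior table with explicit values for a given RT function rt_fun(subject, day, task).
toy_behavior <- function(subjects, n_days, rt_fun,
                         tasks = c("word_naming", "picture_naming")) {
  grid <- expand.grid(subject = subjects, day = seq_len(n_days), task = tasks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rt <- mapply(rt_fun, grid$subject, grid$day, grid$task)
  behavior_table(grid)
}
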