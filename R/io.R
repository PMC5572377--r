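#' Read and write pattern tables
#'
#' Pattern sets are serialized in long format, one voxel per row, with columns
#' `subject`, `roi`, `condition`, `repetition` (1 or 2), `voxel_index`,
#' `value`. The long format keeps files diff-friendly and lets every row be
#' validated on read. Round trips are lossless.
#'
#' @param path CSV or TSV file path (delimiter detected by data.table).
#' @return `read_pattern_table()` returns a [pattern_set()];
#'   `write_pattern_table()` returns `path` invisibly.
#' @export
read_pattern_table <- function(path) {
  if (!file.exists(path)) stopf("pattern table not found: %s", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("subject", "roi", "condition", "repetition", "voxel_index", "value")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stopf("pattern table %s lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(dt$value)) stopf("pattern table %s: 'value' column is not numeric", path)
  if (!all(dt$repetition %in% 1:2)) {
    bad <- which(!dt$repetition %in% 1:2)[1]
    stopf("pattern table %s: repetition must be 1 or 2 (data row %d)", path, bad)
  }
  if (anyNA(dt$value) || any(!is.finite(dt$value))) {
    bad <- which(!is.finite(dt$value))[1]
    stopf("pattern table %s: non-finite value at data row %d", path, bad)
  }
  key <- paste(dt$subject, dt$roi, dt$condition, dt$repetition, dt$voxel_index)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stopf("pattern table %s: duplicate key at data row %d (%s, %s, %s, rep %s, voxel %s)",
          path, d, dt$subject[d], dt$roi[d], dt$condition[d], dt$repetition[d],
          dt$voxel_index[d])
  }
  # first-appearance order so a write -> read round trip preserves axis order
  subjects <- unique(dt$subject)
  rois <- unique(dt$roi)
  conditions <- unique(dt$condition)
  voxels <- sort(unique(dt$voxel_index))
  acts <- array(NA_real_,
                c(length(subjects), length(rois), length(conditions), 2L, length(voxels)),
                dimnames = list(subjects, rois, conditions, c("rep1", "rep2"), NULL))
  idx <- cbind(match(dt$subject, subjects), match(dt$roi, rois),
               match(dt$condition, conditions), dt$repetition,
               match(dt$voxel_index, voxels))
  acts[idx] <- dt$value
  if (anyNA(acts)) stopf("pattern table %s is not a complete subject x roi x condition x repetition x voxel grid", path)
  pattern_set(acts)
}

#' @param patterns A [pattern_set()].
#' @rdname read_pattern_table
#' @export
write_pattern_table <- function(patterns, path) {
  if (!inherits(patterns, "pattern_set")) stopf("'patterns' must be a pattern_set")
  a <- patterns$activations
  d <- dim(a); dn <- dimnames(a)
  long <- data.table::data.table(
    subject = rep(dn[[1]], times = prod(d[2:5])),
    roi = rep(rep(dn[[2]], each = d[1]), times = prod(d[3:5])),
    condition = rep(rep(dn[[3]], each = prod(d[1:2])), times = prod(d[4:5])),
    repetition = rep(rep(1:2, each = prod(d[1:3])), times = d[5]),
    voxel_index = rep(seq_len(d[5]), each = prod(d[1:4])),
    value = as.numeric(a)
  )
  # rows ordered by array axes (subject fastest) -- deterministic, so files diff cleanly
  data.table::fwrite(long, path)
  invisible(path)
}

#' Read and write behavior tables
#'
#' The subject-level table has columns `subject`, `day`, `task`, `rt` and
#' optionally `accuracy`; the optional item-level table has `item`, `day`,
#' `task`, `rt`.
#'
#' @param path CSV/TSV path for the subject-level table.
#' @param item_path Optional CSV/TSV path for the item-level table.
#' @return `read_behavior_table()` returns a [behavior_table()].
#' @export
read_behavior_table <- function(path, item_path = NULL) {
  if (!file.exists(path)) stopf("behavior table not found: %s", path)
  rt <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  item_rt <- NULL
  if (!is.null(item_path)) {
    if (!file.exists(item_path)) stopf("item RT table not found: %s", item_path)
    item_rt <- as.data.frame(data.table::fread(item_path, showProgress = FALSE))
  }
  behavior_table(rt, item_rt = item_rt)
}

#' @param behavior A [behavior_table()].
#' @rdname read_behavior_table
#' @export
write_behavior_table <- function(behavior, path, item_path = NULL) {
  if (!inherits(behavior, "behavior_table")) stopf("'behavior' must be a behavior_table")
  data.table::fwrite(behavior$rt, path)
  if (!is.null(item_path) && !is.null(behavior$item_rt)) {
    data.table::fwrite(behavior$item_rt, item_path)
  }
  invisible(path)
}

#' Extract ROI voxel patterns from NIfTI contrast maps
#'
#' Reads per-condition, per-repetition 3-D contrast maps and binary ROI masks
#' and assembles a [pattern_set()]. Voxels are ordered by ascending linear
#' index within each mask's native array order, identically across conditions
#' and repetitions. Requires the RNifti package.
#'
#' @param map_paths Nested named list: `map_paths[[subject]][[condition]]` is a
#'   character vector of two file paths (repetition 1 and 2).
#' @param mask_paths Named character vector or list of ROI mask paths.
#' @return A [pattern_set()].
#' @export
extract_patterns_from_nifti <- function(map_paths, mask_paths) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("NIfTI extraction requires the RNifti package")
  }
  subjects <- names(map_paths)
  rois <- names(mask_paths)
  if (is.null(subjects) || is.null(rois)) stopf("'map_paths' and 'mask_paths' must be named")
  masks <- lapply(mask_paths, function(p) {
    m <- as.array(RNifti::readNifti(p))
    vals <- unique(as.numeric(m))
    if (!all(vals %in% c(0, 1))) stopf("mask %s is not binary", p)
    idx <- which(m != 0)
    if (length(idx) == 0L) stopf("empty ROI: mask %s selects no voxels", p)
    list(dim = dim(m), idx = idx)
  })
  conditions <- names(map_paths[[1]])
  n_vox <- max(vapply(masks, function(m) length(m$idx), integer(1)))
  acts <- array(NA_real_, c(length(subjects), length(rois), length(conditions), 2L, n_vox),
                dimnames = list(subjects, rois, conditions, c("rep1", "rep2"), NULL))
  for (s in subjects) for (cc in conditions) {
    paths <- map_paths[[s]][[cc]]
    if (length(paths) != 2L) stopf("expected 2 repetition maps for %s/%s", s, cc)
    for (rep_i in 1:2) {
      vol <- as.array(RNifti::readNifti(paths[rep_i]))
      for (roi in rois) {
        m <- masks[[roi]]
        if (!identical(dim(vol), m$dim)) {
          stopf("grid mismatch: map %s is %s but mask '%s' is %s",
                paths[rep_i], paste(dim(vol), collapse = "x"), roi,
                paste(m$dim, collapse = "x"))
        }
        acts[s, roi, cc, rep_i, seq_along(m$idx)] <- vol[m$idx]
      }
    }
  }
  # Pad ragged ROIs (different mask sizes) is not supported: require equal sizes.
  sizes <- vapply(masks, function(m) length(m$idx), integer(1))
  if (length(unique(sizes)) > 1L) {
    stopf("ROI masks select different voxel counts (%s); extract per ROI instead",
          paste(sizes, collapse = ", "))
  }
  pattern_set(acts)
}

#' Serialize an analysis report to JSON
#'
#' Writes the machine-readable form of an `rsa_report`. Null distributions are
#' summarized by their quantiles to keep reports small; all p-values, effect
#' sizes and configuration constants are included.
#'
#' @param report An `rsa_report` from [run_full_analysis()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  perm_json <- lapply(report$permutation, function(pr) {
    lapply(pr, function(p) list(
      r_obs = p$r_obs, p_one = p$p_one, p_two = p$p_two,
      n_perm = p$n_perm, scheme = p$scheme, seed = p$seed,
      n_possible = p$n_possible,
      null_quantiles = as.list(stats::quantile(p$null_dist, c(0.025, 0.05, 0.5, 0.95, 0.975)))
    ))
  })
  loocv_json <- lapply(report$loocv, function(l) list(
    predicted = l$predicted, rel_error = l$rel_error,
    max_abs_error = l$max_abs_error, min_abs_error = l$min_abs_error
  ))
  out <- list(
    brain_behavior = report$brain_behavior,
    dependent = report$dependent,
    permutation = perm_json,
    loocv = loocv_json,
    learning_rate = report$learning_rate,
    median_split = report$median_split,
    n_tests = report$n_tests,
    config = unclass(report$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write run configurations
#'
#' Configurations are stored as YAML (or JSON via [jsonlite]); all thresholds
#' are explicit in the serialized file.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config()` returns a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst)
}

#' @param config A [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
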