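#' Specify a rapid event-related design
#'
#' Captures the structural parameters of a rapid event-related passive-viewing
#' run: several stimulus conditions (languages), a fixed number of items per
#' condition each shown exactly twice, a handful of filler (catch) trials, a
#' jittered inter-stimulus interval (ISI), and a constraint on how many trials
#' may intervene between the two presentations of the same item.
#'
#' Defaults reproduce the design used throughout this package's analyses:
#' 3 conditions x 30 items x 2 repetitions plus 9 fillers (189 trials),
#' 600 ms stimuli, ISI jittered on 1--5 s with mean 2 s, repetition spacing of
#' 4--8 intervening trials, and a 2 s repetition time (TR).
#'
#' @param n_conditions Number of stimulus conditions.
#' @param n_items_per_condition Items per condition; each is presented twice.
#' @param n_repetitions Presentations per item; the spacing constraint is
#'   defined for exactly 2 repetitions.
#' @param n_fillers Number of filler trials interleaved uniformly at random.
#' @param stim_duration Stimulus duration in seconds.
#' @param isi_min,isi_max,isi_mean ISI bounds and target mean, in seconds. The
#'   jitter distribution is a truncated-geometric profile on a 0.5 s grid
#'   calibrated so the expected ISI equals `isi_mean`.
#' @param spacing_min,spacing_max Allowed counts of intervening trials between
#'   the two presentations of an item (fillers count as intervening trials).
#' @param tr Repetition time in seconds (volume acquisition interval).
#' @param seed Integer seed controlling schedule randomization.
#' @return An object of class `design_spec`.
#' @seealso [generate_event_schedule()], [schedule_summary()]
#' @export
design_spec <- function(n_conditions = 3L,
                        n_items_per_condition = 30L,
                        n_repetitions = 2L,
                        n_fillers = 9L,
                        stim_duration = 0.6,
                        isi_min = 1, isi_max = 5, isi_mean = 2,
                        spacing_min = 4L, spacing_max = 8L,
                        tr = 2.0,
                        seed = 1L) {
  spec <- list(
    n_conditions = check_count(n_conditions, "n_conditions", min = 1L),
    n_items_per_condition = check_count(n_items_per_condition, "n_items_per_condition", min = 1L),
    n_repetitions = check_count(n_repetitions, "n_repetitions", min = 1L),
    n_fillers = check_count(n_fillers, "n_fillers", min = 0L),
    stim_duration = check_number(stim_duration, "stim_duration", min = 0),
    isi_min = check_number(isi_min, "isi_min", min = 0),
    isi_max = check_number(isi_max, "isi_max", min = 0),
    isi_mean = check_number(isi_mean, "isi_mean", min = 0),
    spacing_min = check_count(spacing_min, "spacing_min", min = 0L),
    spacing_max = check_count(spacing_max, "spacing_max", min = 0L),
    tr = check_number(tr, "tr", min = 1e-9),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$isi_min > spec$isi_mean || spec$isi_mean > spec$isi_max) {
    stopf("ISI parameters must satisfy isi_min <= isi_mean <= isi_max")
  }
  if (spec$spacing_min > spec$spacing_max) {
    stopf("spacing_min must not exceed spacing_max")
  }
  if (spec$n_repetitions != 2L) {
    stopf("the repetition-spacing constraint is defined for n_repetitions = 2")
  }
  structure(spec, class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Event-related design: %d conditions x %d items x %d reps + %d fillers (%d trials)\n",
    x$n_conditions, x$n_items_per_condition, x$n_repetitions, x$n_fillers,
    x$n_conditions * x$n_items_per_condition * x$n_repetitions + x$n_fillers
  ))
  cat(sprintf("  stimulus %.3g s; ISI %.3g-%.3g s (mean %.3g); spacing %d-%d; TR %.3g s\n",
              x$stim_duration, x$isi_min, x$isi_max, x$isi_mean,
              x$spacing_min, x$spacing_max, x$tr))
  invisible(x)
}

## Truncated-geometric ISI profile on a 0.5 s grid: p_k proportional to q^k over
## the grid, with q solved so the mean hits the target. Many short and few long
## ISIs for targets below the grid midpoint, mirroring rapid-design practice.
isi_distribution <- function(isi_min, isi_max, isi_mean, step = 0.5) {
  grid <- seq(isi_min, isi_max, by = step)
  if (abs(grid[length(grid)] - isi_max) > 1e-9) grid <- c(grid, isi_max)
  k <- length(grid)
  if (k == 1L) {
    return(list(grid = grid, prob = 1))
  }
  mean_for <- function(q) {
    w <- q ^ (seq_len(k) - 1L)
    sum(grid * w) / sum(w)
  }
  lo <- 1e-8; hi <- 1e8
  if (isi_mean <= mean_for(lo)) {
    prob <- c(1, rep(0, k - 1L))
  } else if (isi_mean >= mean_for(hi)) {
    prob <- c(rep(0, k - 1L), 1)
  } else {
    q <- stats::uniroot(function(q) mean_for(q) - isi_mean,
                        lower = lo, upper = hi, tol = 1e-12)$root
    w <- q ^ (seq_len(k) - 1L)
    prob <- w / sum(w)
  }
  list(grid = grid, prob = prob)
}

#' Generate a constraint-satisfying event schedule
#'
#' Builds an ordered trial sequence in which every item appears exactly twice
#' with 4--8 (configurable) intervening trials between its two presentations,
#' fillers are interleaved uniformly at random, and ISIs are drawn from a
#' jitter distribution calibrated so the expected ISI equals the design's
#' target mean. Placement is randomized-greedy with rejection: trials are laid
#' down slot by slot, a second presentation is forced when its spacing window
#' is about to close, and the whole sequence is restarted (up to
#' `max_restarts` times) if the constraints wedge.
#'
#' @param spec A [design_spec()].
#' @param max_restarts Restart budget for the rejection sampler.
#' @return An object of class `event_schedule`: a list with `trials` (a
#'   data.frame with columns `onset`, `condition`, `item`, `repetition`,
#'   `is_filler`) and `total_duration` (seconds, last onset + stimulus
#'   duration).
#' @examples
#' sched <- generate_event_schedule(design_spec(seed = 7))
#' nrow(sched$trials)   # 189
#' @export
generate_event_schedule <- function(spec, max_restarts = 1000L) {
  if (!inherits(spec, "design_spec")) stopf("'spec' must be a design_spec")
  with_seed(child_seed(spec$seed, 1L), {
    order <- place_trials(spec, max_restarts)
    n <- nrow(order)
    isi <- isi_distribution(spec$isi_min, spec$isi_max, spec$isi_mean)
    gaps <- if (n > 1L) sample(isi$grid, n - 1L, replace = TRUE, prob = isi$prob) else numeric(0)
    onsets <- cumsum(c(0, gaps + spec$stim_duration))
    trials <- data.frame(
      onset = onsets,
      condition = order$condition,
      item = order$item,
      repetition = order$repetition,
      is_filler = order$is_filler,
      stringsAsFactors = FALSE
    )
    structure(
      list(trials = trials,
           total_duration = if (n > 0L) onsets[n] + spec$stim_duration else 0),
      class = "event_schedule"
    )
  })
}

## Randomized-greedy slot filling. Words are (condition, item) pairs needing
## two placements; fillers are single placements. At each slot the candidate
## set is: any eligible second presentation (spacing window open), any unused
## first presentation whose second can still fit, or a filler. A pending second
## whose window closes this slot is placed immediately; two simultaneously
## forced seconds, or an empty candidate set, abort the attempt.
place_trials <- function(spec, max_restarts) {
  n_words <- spec$n_conditions * spec$n_items_per_condition
  n_slots <- n_words * 2L + spec$n_fillers
  word_cond <- rep(seq_len(spec$n_conditions), each = spec$n_items_per_condition)
  word_item <- rep(seq_len(spec$n_items_per_condition), times = spec$n_conditions)
  smin <- spec$spacing_min; smax <- spec$spacing_max

  for (attempt in seq_len(max_restarts)) {
    slot_word <- integer(n_slots)      # 0 = filler
    slot_rep <- integer(n_slots)
    firsts <- sample.int(n_words)      # unused first presentations, random order
    n_first <- n_words
    pend_word <- integer(0)            # placed once, awaiting second
    pend_pos <- integer(0)
    fillers_left <- spec$n_fillers
    failed <- FALSE

    for (t in seq_len(n_slots)) {
      gap <- t - pend_pos - 1L         # intervening trials if second placed now
      forced <- which(gap >= smax)
      if (length(forced) > 1L) { failed <- TRUE; break }
      if (length(forced) == 1L) {
        pick <- forced
        slot_word[t] <- pend_word[pick]; slot_rep[t] <- 2L
        pend_word <- pend_word[-pick]; pend_pos <- pend_pos[-pick]
        next
      }
      eligible <- which(gap >= smin)
      first_ok <- n_first > 0L && (t + smin + 1L) <= n_slots
      n_cand <- length(eligible) + (if (first_ok) n_first else 0L) + fillers_left
      if (n_cand == 0L) { failed <- TRUE; break }
      u <- sample.int(n_cand, 1L)
      if (u <= length(eligible)) {
        pick <- eligible[u]
        slot_word[t] <- pend_word[pick]; slot_rep[t] <- 2L
        pend_word <- pend_word[-pick]; pend_pos <- pend_pos[-pick]
      } else if (first_ok && u <= length(eligible) + n_first) {
        w <- firsts[n_first]; n_first <- n_first - 1L
        slot_word[t] <- w; slot_rep[t] <- 1L
        pend_word <- c(pend_word, w); pend_pos <- c(pend_pos, t)
      } else {
        fillers_left <- fillers_left - 1L   # slot_word stays 0
      }
    }
    if (!failed && n_first == 0L && length(pend_word) == 0L && fillers_left == 0L) {
      is_filler <- slot_word == 0L
      return(data.frame(
        condition = ifelse(is_filler, "filler", paste0("cond", word_cond[pmax(slot_word, 1L)])),
        item = ifelse(is_filler, NA_integer_, word_item[pmax(slot_word, 1L)]),
        repetition = ifelse(is_filler, NA_integer_, slot_rep),
        is_filler = is_filler,
        stringsAsFactors = FALSE
      ))
    }
  }
  stopf("infeasible design: no constraint-satisfying schedule found in %d restarts",
        max_restarts)
}

#' Validate an event schedule against its design
#'
#' Independent checker for the schedule invariants: strictly increasing onsets,
#' every non-filler item presented exactly twice, repetition spacing within
#' bounds (counting fillers as intervening trials), every ISI within the
#' design's jitter range, and the stated filler count.
#'
#' @param schedule An `event_schedule`.
#' @param spec The [design_spec()] it should satisfy.
#' @return Invisibly `TRUE`; otherwise an error describing the first violation.
#' @export
validate_schedule <- function(schedule, spec) {
  tr <- schedule$trials
  if (any(diff(tr$onset) <= 0)) stopf("onsets are not strictly increasing")
  if (sum(tr$is_filler) != spec$n_fillers) {
    stopf("expected %d fillers, found %d", spec$n_fillers, sum(tr$is_filler))
  }
  words <- tr[!tr$is_filler, , drop = FALSE]
  words$pos <- which(!tr$is_filler)
  key <- paste(words$condition, words$item)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) != spec$n_repetitions) {
      stopf("item %s presented %d times, expected %d", k, length(idx), spec$n_repetitions)
    }
    rows <- match(k, key)  # first occurrence
    pos <- sort(words$pos[idx])
    intervening <- pos[2] - pos[1] - 1L
    if (intervening < spec$spacing_min || intervening > spec$spacing_max) {
      stopf("item %s has %d intervening trials (allowed %d-%d)",
            k, intervening, spec$spacing_min, spec$spacing_max)
    }
    if (!identical(sort(tr$repetition[words$pos[idx]]), seq_len(spec$n_repetitions))) {
      stopf("item %s has malformed repetition labels", k)
    }
  }
  isi <- diff(tr$onset) - spec$stim_duration
  if (length(isi) && (min(isi) < spec$isi_min - 1e-9 || max(isi) > spec$isi_max + 1e-9)) {
    stopf("ISI outside [%g, %g]", spec$isi_min, spec$isi_max)
  }
  invisible(TRUE)
}

#' Summarize an event schedule
#'
#' @param schedule An `event_schedule` (an empty trial list gives zero counts).
#' @param tr Repetition time in seconds.
#' @return A list with `n_trials`, `n_nonfiller`, `total_duration` and
#'   `n_volumes = ceiling(total_duration / tr)`.
#' @examples
#' # A 566 s run at TR = 2 s spans 283 volumes.
#' @export
schedule_summary <- function(schedule, tr) {
  tr <- check_number(tr, "tr", min = 1e-9)
  n <- nrow(schedule$trials)
  list(
    n_trials = n,
    n_nonfiller = if (n > 0L) sum(!schedule$trials$is_filler) else 0L,
    total_duration = schedule$total_duration,
    n_volumes = as.integer(ceiling(schedule$total_duration / tr))
  )
}

#' Inter-stimulus intervals of a schedule
#'
#' @param schedule An `event_schedule`.
#' @param stim_duration Stimulus duration used when the schedule was built.
#' @return Numeric vector of ISIs (seconds), length `n_trials - 1`.
#' @export
schedule_isis <- function(schedule, stim_duration = 0.6) {
  diff(schedule$trials$onset) - stim_duration
}

#' @export
print.event_schedule <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("Event schedule: %d trials (%d fillers), %.1f s\n",
              n, sum(x$trials$is_filler), x$total_duration))
  invisible(x)
}
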