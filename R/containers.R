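#' Continuous pupillometry recording
#'
#' Bundles a uniformly sampled pupil-diameter trace with the simultaneous
#' gaze position (in degrees visual angle from fixation) and a per-sample
#' validity mask. All downstream pupil analyses (fixation filtering, event
#' detection, rate estimation) operate on this container.
#'
#' @param diameter Numeric vector, pupil diameter in arbitrary units.
#' @param gaze_x,gaze_y Numeric vectors, gaze position in degrees visual
#'   angle relative to fixation. Same length as `diameter`.
#' @param fs Sampling rate in Hz (> 0).
#' @param t Optional time stamps in ms. Defaults to a uniform grid starting
#'   at 0 with step `1000/fs`; if supplied it must be strictly increasing
#'   with that constant step.
#' @param valid Logical vector marking usable samples; recycled if length 1.
#'
#' @return An object of class `pupil_recording`: a list with elements
#'   `t`, `diameter`, `gaze_x`, `gaze_y`, `valid` and `fs`.
#' @export
pupil_recording <- function(diameter, gaze_x, gaze_y, fs, t = NULL,
                            valid = TRUE) {
  n <- length(diameter)
  stopifnot(is.numeric(diameter), is.numeric(gaze_x), is.numeric(gaze_y),
            length(gaze_x) == n, length(gaze_y) == n,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  step <- 1000 / fs
  if (is.null(t)) {
    t <- (seq_len(n) - 1L) * step
  } else {
    if (length(t) != n) {
      stop("`t` must have the same length as `diameter`", call. = FALSE)
    }
    check_uniform_grid(t, step)
  }
  if (length(valid) == 1L) valid <- rep(as.logical(valid), n)
  stopifnot(is.logical(valid), length(valid) == n)
  structure(
    list(t = as.numeric(t), diameter = as.numeric(diameter),
         gaze_x = as.numeric(gaze_x), gaze_y = as.numeric(gaze_y),
         valid = valid, fs = fs),
    class = "pupil_recording"
  )
}

# Relative (ppm-level) uniformity check on a time grid.
check_uniform_grid <- function(t, step, tol_ppm = 1) {
  if (length(t) > 1L) {
    d <- diff(t)
    if (any(d <= 0)) {
      stop("time stamps must be strictly increasing", call. = FALSE)
    }
    if (any(abs(d - step) > tol_ppm * 1e-6 * step)) {
      stop("non-uniform time grid (tolerance 1 ppm of the sample step)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              length(x$diameter), x$fs, length(x$diameter) / x$fs,
              100 * mean(x$valid)))
  invisible(x)
}

#' Trial schedule
#'
#' Onset times and condition labels of a block of stimulus snippets.
#' Conditions are two-level: `"A"` (the familiar class in the study design)
#' and `"B"` (unfamiliar).
#'
#' @param onsets_ms Strictly increasing numeric vector of snippet onsets, ms.
#' @param conditions Character vector in `{"A","B"}`, one label per trial.
#' @param snippet_ms Snippet duration in ms.
#' @param min_isi_ms Minimum inter-stimulus interval used to validate onset
#'   gaps; `NULL` skips the gap check.
#' @param balanced If `TRUE`, require exactly half the trials per condition.
#'
#' @return An object of class `trial_schedule`: a data.frame with columns
#'   `onset_ms` and `condition`, and attributes `snippet_ms`, `n_trials`.
#' @export
trial_schedule <- function(onsets_ms, conditions, snippet_ms,
                           min_isi_ms = NULL, balanced = TRUE) {
  n <- length(onsets_ms)
  stopifnot(length(conditions) == n, n >= 1L, snippet_ms > 0)
  conditions <- as.character(conditions)
  if (!all(conditions %in% c("A", "B"))) {
    stop("conditions must be \"A\" or \"B\"", call. = FALSE)
  }
  if (n > 1L && any(diff(onsets_ms) <= 0)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  if (!is.null(min_isi_ms) && n > 1L &&
      any(diff(onsets_ms) < snippet_ms + min_isi_ms - 1e-9)) {
    stop("onset gaps smaller than snippet duration + minimum ISI",
         call. = FALSE)
  }
  if (balanced && sum(conditions == "A") * 2L != n) {
    stop("balanced schedule requires exactly n_trials/2 trials per condition",
         call. = FALSE)
  }
  structure(
    data.frame(onset_ms = as.numeric(onsets_ms), condition = conditions,
               stringsAsFactors = FALSE),
    snippet_ms = snippet_ms, n_trials = n,
    class = c("trial_schedule", "data.frame")
  )
}

#' One subject's EEG epochs
#'
#' Stimulus-locked EEG segments with their channel layout and condition
#' labels, the unit every group-level EEG analysis consumes.
#'
#' @param data Numeric array `[epoch x channel x time]`, microvolts.
#' @param times Numeric vector of sample times in ms relative to stimulus
#'   onset; length must equal `dim(data)[3]`.
#' @param fs Sampling rate in Hz.
#' @param conditions Condition label (`"A"`/`"B"`) per epoch.
#' @param layout Data frame with columns `channel`, `x`, `y`: planar channel
#'   positions in arbitrary units, one row per channel.
#' @param subject_id,group,dyad_id Identification metadata; `group` is
#'   `"main"` or `"control"`.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, conditions, layout,
                      subject_id = NA_character_, group = "main",
                      dyad_id = NA_integer_) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (length(times) != d[3]) {
    stop("`times` length must match the time dimension of `data`",
         call. = FALSE)
  }
  if (length(conditions) != d[1]) {
    stop("one condition label is required per epoch", call. = FALSE)
  }
  stopifnot(is.data.frame(layout),
            all(c("channel", "x", "y") %in% names(layout)))
  if (nrow(layout) != d[2]) {
    stop("layout must have one position per channel", call. = FALSE)
  }
  if (!group %in% c("main", "control")) {
    stop("group must be \"main\" or \"control\"", call. = FALSE)
  }
  structure(
    list(data = data, times = as.numeric(times), fs = fs,
         conditions = as.character(conditions), layout = layout,
         subject_id = subject_id, group = group, dyad_id = dyad_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s (%s): %d epochs x %d channels x %d samples, [%g, %g) ms @ %g Hz\n",
    x$subject_id, x$group, d[1], d[2], d[3],
    min(x$times), max(x$times) + 1000 / x$fs, x$fs))
  invisible(x)
}

#' Per-trial pupil dilation-event train
#'
#' Event times of one trial, re-expressed relative to snippet onset and
#' confined to the half-open peristimulus window.
#'
#' @param trial_index Integer trial number within the schedule.
#' @param event_times_ms Sorted numeric vector of event times, ms relative
#'   to onset, all inside `window`.
#' @param window Numeric length-2, the half-open window `[start, end)` ms.
#' @param condition Condition label of the trial.
#'
#' @return An object of class `pupil_event_train`.
#' @export
pupil_event_train <- function(trial_index, event_times_ms, window,
                              condition) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  event_times_ms <- as.numeric(event_times_ms)
  if (is.unsorted(event_times_ms)) {
    stop("event times must be sorted ascending", call. = FALSE)
  }
  if (length(event_times_ms) &&
      (any(event_times_ms < window[1]) || any(event_times_ms >= window[2]))) {
    stop("event times must lie inside the half-open window", call. = FALSE)
  }
  structure(
    list(trial_index = as.integer(trial_index),
         event_times_ms = event_times_ms,
         window = as.numeric(window), condition = condition),
    class = "pupil_event_train"
  )
}

#' Kernel-smoothed dilation-event rate series
#'
#' @param times_ms Peristimulus time grid, ms.
#' @param rate Event rate in events/s at each time point.
#' @param n_trials Number of trials averaged.
#' @param condition Condition label, or `"diff"` for a difference series.
#' @param baseline_corrected Whether a pre-onset mean has been subtracted.
#' @param baseline_interval Half-open `[start, end)` interval used, ms.
#'
#' @return An object of class `event_rate_series`.
#' @export
event_rate_series <- function(times_ms, rate, n_trials, condition,
                              baseline_corrected = FALSE,
                              baseline_interval = NULL) {
  stopifnot(length(times_ms) == length(rate), all(is.finite(rate)))
  structure(
    list(times_ms = as.numeric(times_ms), rate = as.numeric(rate),
         n_trials = as.integer(n_trials), condition = condition,
         baseline_corrected = baseline_corrected,
         baseline_interval = baseline_interval),
    class = "event_rate_series"
  )
}

#' @export
print.event_rate_series <- function(x, ...) {
  cat(sprintf(
    "<event_rate_series> condition %s: %d points in [%g, %g] ms, %d trials%s\n",
    x$condition, length(x$rate), min(x$times_ms), max(x$times_ms),
    x$n_trials,
    if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}
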