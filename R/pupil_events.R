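#' Invalidate samples with gaze away from fixation
#'
#' Marks every sample whose radial gaze deviation exceeds `max_dev_deg`
#' (default 1 degree) as invalid. The diameter trace is untouched; the
#' validity mask is the single channel through which exclusion propagates
#' to event detection.
#'
#' @param recording A [pupil_recording()].
#' @param max_dev_deg Maximum tolerated deviation from fixation, degrees.
#' @return The recording with an updated `valid` mask; the fraction of
#'   newly invalidated samples is attached as attribute
#'   `fraction_removed`.
#' @export
filter_fixation <- function(recording, max_dev_deg = 1.0) {
  stopifnot(inherits(recording, "pupil_recording"), max_dev_deg >= 0)
  dev <- sqrt(recording$gaze_x^2 + recording$gaze_y^2)
  bad <- dev > max_dev_deg
  removed <- mean(bad & recording$valid)
  recording$valid <- recording$valid & !bad
  attr(recording, "fraction_removed") <- removed
  recording
}

#' Detect pupil dilation events
#'
#' A dilation event is an instantaneous positive sign-change of the
#' diameter derivative: with the first difference `d[i] = x[i+1] - x[i]`,
#' sample `i` is an event iff `d[i] > 0` and `d[i-1] <= 0` — the first
#' sample at which the diameter begins to increase, so a flat trough
#' yields exactly one event at its first rising sample. Both differences
#' must be defined on valid samples: no event is emitted at the first or
#' last sample or across invalid-sample gaps, and events falling on
#' invalid samples are discarded.
#'
#' @param recording A [pupil_recording()].
#' @param presmooth_ms Optional centred moving-average window applied to
#'   the diameter before differencing, ms; `0` (default) keeps the
#'   derivative instantaneous.
#' @return Integer vector of event sample indices (1-based).
#' @export
detect_dilation_events <- function(recording, presmooth_ms = 0) {
  stopifnot(inherits(recording, "pupil_recording"))
  x <- recording$diameter
  n <- length(x)
  if (n < 3L) stop("recording must contain at least 3 samples",
                   call. = FALSE)
  if (presmooth_ms > 0) {
    w <- max(1L, round(presmooth_ms * recording$fs / 1000))
    if (w > 1L) {
      k <- rep(1 / w, w)
      x <- stats::filter(x, k, sides = 2)
      x[is.na(x)] <- recording$diameter[is.na(x)]
      x <- as.numeric(x)
    }
  }
  d <- diff(x)                       # d[i] = x[i+1] - x[i]
  dvalid <- recording$valid[-n] & recording$valid[-1L]
  i <- 2:(n - 1L)
  ev <- i[d[i] > 0 & d[i - 1L] <= 0 &
            dvalid[i] & dvalid[i - 1L] &
            recording$valid[i]]
  as.integer(ev)
}

#' Assign detected events to peristimulus trial windows
#'
#' Each event is assigned to every trial whose window contains it, with its
#' time re-expressed relative to that trial's onset. Windows are half-open
#' `[start, end)`. A warning is issued when consecutive windows overlap
#' (events then legitimately appear in more than one train).
#'
#' @param event_times_ms Event times in ms on the recording clock.
#' @param schedule A [trial_schedule()].
#' @param window Peristimulus window `[start, end)` in ms relative to
#'   onset; the default mirrors the EEG epoching.
#' @return A list of [pupil_event_train()], one per trial.
#' @export
epoch_events <- function(event_times_ms, schedule,
                         window = c(-500, 1500)) {
  stopifnot(inherits(schedule, "trial_schedule"), length(window) == 2L,
            window[1] < window[2])
  if (nrow(schedule) == 0L) stop("empty trial schedule", call. = FALSE)
  gaps <- diff(schedule$onset_ms)
  if (length(gaps) && any(gaps < diff(window))) {
    warning("peristimulus windows overlap between consecutive trials",
            call. = FALSE)
  }
  event_times_ms <- sort(as.numeric(event_times_ms))
  lapply(seq_len(nrow(schedule)), function(i) {
    on <- schedule$onset_ms[i]
    rel <- event_times_ms - on
    pupil_event_train(i, rel[rel >= window[1] & rel < window[2]],
                      window = window, condition = schedule$condition[i])
  })
}

#' Causal gamma-shaped smoothing kernel
#'
#' The rate-estimation kernel `w(tau) = alpha^2 * tau * exp(-alpha * tau)`
#' (a Gamma(2) density in tau >= 0), sampled on the analysis grid and
#' truncated at `duration_ms` without renormalisation; the truncation
#' deficit is reported instead so the unit integral stays interpretable.
#' The kernel integrates to 1 and peaks at `tau = 1/alpha` (50 ms at the
#' default decay parameter of 1/50 per ms).
#'
#' @param alpha_per_ms Decay parameter in 1/ms.
#' @param fs Sampling rate of the rate series, Hz.
#' @param duration_ms Truncation length, ms. Values below `5/alpha` leave
#'   more than ~4% of the kernel mass outside the support and trigger a
#'   warning.
#' @return An object of class `smoothing_kernel` with fields `alpha`,
#'   `duration_ms`, `fs`, `weights` (units 1/ms) and `truncation_error`.
#' @export
make_kernel <- function(alpha_per_ms = 1 / 50, fs = 1000,
                        duration_ms = 500) {
  stopifnot(alpha_per_ms > 0, fs > 0, duration_ms > 0)
  if (duration_ms < 5 / alpha_per_ms) {
    warning(sprintf(
      "kernel truncated at %g ms < 5/alpha = %g ms: integral deficit > 4%%",
      duration_ms, 5 / alpha_per_ms), call. = FALSE)
  }
  tau <- seq(0, duration_ms, by = 1000 / fs)
  weights <- alpha_per_ms^2 * tau * exp(-alpha_per_ms * tau)
  trunc_err <- (1 + alpha_per_ms * duration_ms) *
    exp(-alpha_per_ms * duration_ms)
  structure(
    list(alpha = alpha_per_ms, duration_ms = duration_ms, fs = fs,
         weights = weights, truncation_error = trunc_err),
    class = "smoothing_kernel")
}

#' Trial-normalized, kernel-smoothed dilation-event rate
#'
#' Bins each trial's events into binary impulse trains on the peristimulus
#' grid, sums over trials, scales by `fs / n_trials` (events per second
#' before smoothing), convolves causally with the kernel, and finally
#' subtracts the mean over the pre-onset baseline interval. Because the
#' kernel has unit integral, a stationary input rate is preserved by the
#' smoothing.
#'
#' @param trains List of [pupil_event_train()] sharing one window.
#' @param kernel A [make_kernel()] whose `fs` matches the analysis grid.
#' @param baseline_interval Half-open `[start, end)` baseline in ms, or
#'   `NULL` to skip baseline correction.
#' @param condition Optional label stored on the result; defaults to the
#'   common condition of the trains (or `"mixed"`).
#' @return An [event_rate_series()].
#' @export
event_rate <- function(trains, kernel, baseline_interval = c(-200, 0),
                       condition = NULL) {
  if (!length(trains)) stop("at least one trial is required", call. = FALSE)
  stopifnot(inherits(kernel, "smoothing_kernel"))
  window <- trains[[1L]]$window
  fs <- kernel$fs
  step <- 1000 / fs
  times <- seq(window[1], window[2] - step / 2, by = step)
  nt <- length(times)
  counts <- numeric(nt)
  for (tr in trains) {
    stopifnot(all(tr$window == window))
    if (length(tr$event_times_ms)) {
      bins <- floor((tr$event_times_ms - window[1]) / step) + 1L
      bins <- bins[bins >= 1L & bins <= nt]
      for (b in bins) counts[b] <- counts[b] + 1
    }
  }
  raw <- counts * fs / length(trains)
  smoothed <- causal_convolve(raw, kernel$weights * step)
  if (!is.null(baseline_interval)) {
    sel <- times >= baseline_interval[1] & times < baseline_interval[2]
    if (!any(sel)) stop("baseline interval contains no samples",
                        call. = FALSE)
    smoothed <- smoothed - mean(smoothed[sel])
  }
  if (is.null(condition)) {
    conds <- unique(vapply(trains, `[[`, "", "condition"))
    condition <- if (length(conds) == 1L) conds else "mixed"
  }
  event_rate_series(times, smoothed, n_trials = length(trains),
                    condition = condition,
                    baseline_corrected = !is.null(baseline_interval),
                    baseline_interval = baseline_interval)
}

# Causal FIR convolution: y[i] = sum_k w[k+1] x[i-k], output clipped to
# the input length so y[i] depends only on x at indices <= i. FFT-based,
# zero-padded to a highly composite length (R's mixed-radix FFT degrades
# badly on near-prime lengths).
causal_convolve <- function(x, w) {
  n <- length(x)
  m <- length(w)
  nfft <- stats::nextn(n + m - 1L, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(w, numeric(nfft - m))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Per-condition rates and their difference for one subject
#'
#' Convenience wrapper running [event_rate()] separately on the `"A"` and
#' `"B"` trains of one subject and forming the A - B difference series
#' (the quantity entering the group-level bootstrap test).
#'
#' @param trains List of [pupil_event_train()] for one subject.
#' @param kernel A [make_kernel()].
#' @param baseline_interval Passed to [event_rate()].
#' @return List with elements `A`, `B` and `diff`
#'   ([event_rate_series()] objects).
#' @export
condition_rates <- function(trains, kernel,
                            baseline_interval = c(-200, 0)) {
  conds <- vapply(trains, `[[`, "", "condition")
  ra <- event_rate(trains[conds == "A"], kernel, baseline_interval, "A")
  rb <- event_rate(trains[conds == "B"], kernel, baseline_interval, "B")
  d <- event_rate_series(ra$times_ms, ra$rate - rb$rate,
                         n_trials = ra$n_trials + rb$n_trials,
                         condition = "diff",
                         baseline_corrected = ra$baseline_corrected,
                         baseline_interval = baseline_interval)
  list(A = ra, B = rb, diff = d)
}
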