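#' Simulation settings for one pupil condition
#'
#' Describes the inhomogeneous point process generating dilation events and
#' the forward model turning events into a diameter trace. Dilation events
#' occur at a baseline rate throughout the recording; each snippet onset of
#' the matching condition adds a transient rate increase ("bump") so that
#' the smoothed event rate rises shortly after stimulus onset, as observed
#' for brief auditory stimuli. Each event adds a smooth positive diameter
#' transient (gamma-shaped rise with its own amplitude and time constant,
#' deliberately parameterised independently of the analysis kernel) on top
#' of slow baseline wander.
#'
#' @param baseline_rate Stationary event rate, events/s.
#' @param bump_amplitude Peak rate added after matching onsets, events/s.
#' @param bump_onset_ms,bump_width_ms Post-onset timing of the rate bump:
#'   a raised-cosine window on `[bump_onset, bump_onset + bump_width)` ms.
#' @param response_amp Diameter increase per event, arbitrary units.
#' @param response_tau_ms Time-to-peak of the per-event diameter transient.
#' @param drift_sd Standard deviation of the slow baseline wander
#'   (smooth noise with ~1 s knots), arbitrary units.
#' @param gaze_jitter_deg SD of fixational gaze jitter, degrees.
#' @param gaze_excursion_prob Per-sample probability that a contiguous
#'   excursion run (> 1 degree from fixation) starts.
#' @param gaze_excursion_mean_ms Mean duration of an excursion run, ms.
#'
#' @return An object of class `pupil_sim_spec`.
#' @export
pupil_sim_spec <- function(baseline_rate = 2, bump_amplitude = 1,
                           bump_onset_ms = 100, bump_width_ms = 200,
                           response_amp = 0.05, response_tau_ms = 80,
                           drift_sd = 0.01, gaze_jitter_deg = 0.1,
                           gaze_excursion_prob = 2e-4,
                           gaze_excursion_mean_ms = 100) {
  stopifnot(baseline_rate >= 0, bump_amplitude >= 0, bump_width_ms > 0,
            response_tau_ms > 0, drift_sd >= 0,
            gaze_excursion_prob >= 0, gaze_excursion_prob <= 1)
  structure(as.list(environment()), class = "pupil_sim_spec")
}

#' Simulation settings for a multi-subject ERP study
#'
#' Every epoch is a shared onset-response template plus a subject-constant
#' offset and i.i.d. Gaussian sensor noise; epochs of condition `"B"`
#' additionally receive a constant amplitude shift confined to a
#' spatio-temporal block (`effect_channels` x `effect_window_ms`), the
#' ground-truth cluster the permutation test should recover.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Number of channels, laid out on a near-square planar
#'   grid with unit spacing.
#' @param n_epochs_per_condition Epochs per condition per subject.
#' @param fs Sampling rate, Hz.
#' @param window_ms Half-open epoch window `[start, end)` in ms.
#' @param noise_sd Sensor noise SD, microvolts.
#' @param erp_template Either a numeric vector on the epoch time grid or
#'   `NULL` for the built-in biphasic onset response (early positive peaks
#'   followed by a sustained deflection).
#' @param effect_channels Integer channel indices carrying the effect.
#' @param effect_window_ms Half-open `[start, end)` window of the effect.
#' @param effect_size Amplitude difference B - A inside the block,
#'   microvolts.
#' @param between_subject_sd SD of the subject-constant offset, microvolts.
#'
#' @return An object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(n_subjects = 8, n_channels = 16,
                         n_epochs_per_condition = 100, fs = 128,
                         window_ms = c(-500, 1500), noise_sd = 10,
                         erp_template = NULL,
                         effect_channels = 1:4,
                         effect_window_ms = c(350, 750),
                         effect_size = 2, between_subject_sd = 2) {
  stopifnot(n_subjects >= 1, n_channels >= 1, n_epochs_per_condition >= 1,
            fs > 0, length(window_ms) == 2L, window_ms[1] < window_ms[2],
            noise_sd >= 0, between_subject_sd >= 0,
            all(effect_channels %in% seq_len(n_channels)),
            effect_window_ms[1] >= window_ms[1],
            effect_window_ms[2] <= window_ms[2])
  structure(as.list(environment()), class = "eeg_sim_spec")
}

#' Generate a randomized trial schedule
#'
#' Snippet onsets follow the paradigm's block structure: consecutive onsets
#' are separated by the snippet duration plus an inter-stimulus interval
#' drawn uniformly from `[isi_min_ms, isi_max_ms]`; condition labels are a
#' random permutation of an equal split.
#'
#' @param n_trials Number of trials (must be even when `balanced`).
#' @param snippet_ms Snippet duration, ms.
#' @param isi_min_ms,isi_max_ms ISI range, ms.
#' @param seed Integer RNG seed.
#' @param start_ms Onset of the first trial, ms.
#' @param balanced Require an exact 50/50 condition split.
#'
#' @return A [trial_schedule()].
#' @export
generate_trial_schedule <- function(n_trials = 200, snippet_ms = 750,
                                    isi_min_ms = 1000, isi_max_ms = 1500,
                                    seed = NULL, start_ms = 2000,
                                    balanced = TRUE) {
  stopifnot(isi_min_ms <= isi_max_ms)
  if (balanced && n_trials %% 2L != 0L) {
    stop("balanced schedule requires an even number of trials",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  gaps <- snippet_ms + stats::runif(n_trials - 1L, isi_min_ms, isi_max_ms)
  onsets <- start_ms + c(0, cumsum(gaps))
  half <- n_trials %/% 2L
  conditions <- sample(c(rep("A", n_trials - half), rep("B", half)))
  trial_schedule(onsets, conditions, snippet_ms = snippet_ms,
                 min_isi_ms = isi_min_ms, balanced = balanced)
}

# Raised-cosine rate bump on [onset, onset + width) ms; peak = amplitude.
bump_profile <- function(tau_ms, onset_ms, width_ms, amplitude) {
  out <- numeric(length(tau_ms))
  inside <- tau_ms >= onset_ms & tau_ms < onset_ms + width_ms
  u <- (tau_ms[inside] - onset_ms) / width_ms
  out[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u))
  out
}

# Smooth slow wander: Gaussian knots every `knot_ms`, spline-interpolated,
# rescaled to the requested SD.
slow_drift <- function(n, fs, sd, knot_ms = 1000) {
  if (sd <= 0) return(numeric(n))
  knot_step <- max(2L, round(knot_ms * fs / 1000))
  knots_at <- seq(1L, n + knot_step, by = knot_step)
  z <- stats::rnorm(length(knots_at))
  d <- stats::spline(knots_at, z, xout = seq_len(n))$y
  s <- stats::sd(d)
  if (s > 0) d <- d / s * sd
  d - d[1]
}

#' Simulate a continuous pupil recording for one block
#'
#' Dilation events are drawn from an inhomogeneous Poisson process whose
#' intensity is the baseline rate plus a condition-specific post-onset
#' bump; each event adds a gamma-shaped diameter transient onto slow
#' baseline drift. The true event times are returned for oracle testing.
#' The gaze trace fixates near (0,0) with occasional contiguous excursion
#' runs beyond 1 degree.
#'
#' @param schedule A [trial_schedule()].
#' @param spec_a,spec_b [pupil_sim_spec()] for conditions A and B
#'   (`spec_b` defaults to `spec_a`).
#' @param seed Integer RNG seed.
#' @param fs Sampling rate, Hz.
#' @param tail_ms Recording time kept after the last snippet ends, ms.
#' @param baseline_diameter Diameter offset, arbitrary units.
#'
#' @return A list with elements `recording` ([pupil_recording()]) and
#'   `event_times_ms` (true event times, ms from recording start).
#' @export
generate_pupil_recording <- function(schedule, spec_a = pupil_sim_spec(),
                                     spec_b = spec_a, seed = NULL,
                                     fs = 1000, tail_ms = 2000,
                                     baseline_diameter = 5) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(spec_a, "pupil_sim_spec"),
            inherits(spec_b, "pupil_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  snippet_ms <- attr(schedule, "snippet_ms")
  dur_ms <- max(schedule$onset_ms) + snippet_ms + tail_ms
  n <- floor(dur_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs

  # intensity: shared baseline + per-trial condition bump
  rate <- rep((spec_a$baseline_rate + spec_b$baseline_rate) / 2, n)
  for (i in seq_len(nrow(schedule))) {
    sp <- if (schedule$condition[i] == "A") spec_a else spec_b
    if (sp$bump_amplitude > 0) {
      i0 <- findInterval(schedule$onset_ms[i] + sp$bump_onset_ms, t_ms)
      i1 <- min(n, findInterval(
        schedule$onset_ms[i] + sp$bump_onset_ms + sp$bump_width_ms, t_ms))
      if (i1 >= i0 && i0 >= 1L) {
        idx <- i0:i1
        rate[idx] <- rate[idx] + bump_profile(
          t_ms[idx] - schedule$onset_ms[i],
          sp$bump_onset_ms, sp$bump_width_ms, sp$bump_amplitude)
      }
    }
  }

  # Bernoulli thinning of the intensity on the sample grid
  event_idx <- which(stats::runif(n) < rate / fs)
  event_times_ms <- t_ms[event_idx]

  # diameter = baseline + drift + superposed event transients
  diameter <- rep(baseline_diameter, n) +
    slow_drift(n, fs, (spec_a$drift_sd + spec_b$drift_sd) / 2)
  if (length(event_idx)) {
    impulses <- numeric(n)
    tab <- table(event_idx)
    impulses[as.integer(names(tab))] <- as.numeric(tab)
    tau <- spec_a$response_tau_ms
    ku <- seq(0, 6 * tau, by = 1000 / fs)
    h <- spec_a$response_amp * (ku / tau) * exp(1 - ku / tau)
    diameter <- diameter + causal_convolve(impulses, h)
  }

  gaze_x <- stats::rnorm(n, 0, spec_a$gaze_jitter_deg)
  gaze_y <- stats::rnorm(n, 0, spec_a$gaze_jitter_deg)
  starts <- which(stats::runif(n) < spec_a$gaze_excursion_prob)
  run_len <- pmax(1L, stats::rgeom(length(starts),
                                   1000 / fs / spec_a$gaze_excursion_mean_ms) + 1L)
  for (j in seq_along(starts)) {
    idx <- starts[j]:min(n, starts[j] + run_len[j] - 1L)
    ang <- stats::runif(1, 0, 2 * pi)
    mag <- stats::runif(1, 1.5, 3)
    gaze_x[idx] <- mag * cos(ang)
    gaze_y[idx] <- mag * sin(ang)
  }

  list(recording = pupil_recording(diameter, gaze_x, gaze_y, fs = fs,
                                   t = t_ms),
       event_times_ms = event_times_ms)
}

# Near-square planar grid layout with unit spacing.
grid_layout <- function(n_channels) {
  ncol_grid <- ceiling(sqrt(n_channels))
  idx <- seq_len(n_channels) - 1L
  data.frame(channel = paste0("ch", seq_len(n_channels)),
             x = as.numeric(idx %% ncol_grid),
             y = as.numeric(idx %/% ncol_grid))
}

# Built-in onset-response template: two early positive peaks and a
# sustained deflection, vaguely P1/P2-like.
default_erp_template <- function(times_ms) {
  g <- function(mu, sdv) exp(-0.5 * ((times_ms - mu) / sdv)^2)
  amp <- 3 * g(70, 20) + 4 * g(190, 40) +
    1.5 * stats::plogis((times_ms - 300) / 40) *
    stats::plogis((750 - times_ms) / 80)
  amp * (times_ms >= 0)
}

#' Simulate a multi-subject ERP study
#'
#' @param spec An [eeg_sim_spec()].
#' @param seed Integer RNG seed.
#' @param group Group label stored in each subject's [epoch_set()].
#' @return A list of [epoch_set()] objects, one per subject.
#' @export
generate_eeg_study <- function(spec, seed = NULL, group = "main") {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  step <- 1000 / spec$fs
  times <- seq(spec$window_ms[1], spec$window_ms[2] - step / 2, by = step)
  nt <- length(times)
  template <- if (is.null(spec$erp_template)) {
    default_erp_template(times)
  } else {
    stopifnot(length(spec$erp_template) == nt)
    spec$erp_template
  }
  eff_t <- times >= spec$effect_window_ms[1] & times < spec$effect_window_ms[2]
  layout <- grid_layout(spec$n_channels)
  n_ep <- 2L * spec$n_epochs_per_condition
  conditions <- rep(c("A", "B"), each = spec$n_epochs_per_condition)
  lapply(seq_len(spec$n_subjects), function(s) {
    offset <- stats::rnorm(1, 0, spec$between_subject_sd)
    base <- outer(rep(1, spec$n_channels), template) + offset
    data <- array(stats::rnorm(n_ep * spec$n_channels * nt, 0,
                               spec$noise_sd),
                  dim = c(n_ep, spec$n_channels, nt))
    for (e in seq_len(n_ep)) {
      data[e, , ] <- data[e, , ] + base
      if (conditions[e] == "B" && spec$effect_size != 0) {
        data[e, spec$effect_channels, eff_t] <-
          data[e, spec$effect_channels, eff_t] + spec$effect_size
      }
    }
    epoch_set(data, times = times, fs = spec$fs, conditions = conditions,
              layout = layout, subject_id = sprintf("sub%02d", s),
              group = group)
  })
}

#' Per-subject condition means of an epoch set
#'
#' Averages epochs within each condition, the subject-level summary the
#' group analyses (cluster permutation test, ANOVA) operate on.
#'
#' @param x An [epoch_set()].
#' @return A list with `A` and `B`: matrices `[channel x time]`.
#' @export
condition_means <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  avg <- function(cond) {
    sel <- which(x$conditions == cond)
    if (!length(sel)) stop("no epochs with condition ", cond, call. = FALSE)
    m <- apply(x$data[sel, , , drop = FALSE], c(2, 3), mean)
    m
  }
  list(A = avg("A"), B = avg("B"))
}
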