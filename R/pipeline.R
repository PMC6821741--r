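#' One-subject pupil analysis chain
#'
#' Fixation filtering, dilation-event detection, trial epoching and
#' kernel-smoothed rate estimation for a single recording, returning
#' everything downstream inference needs.
#'
#' @param recording A [pupil_recording()].
#' @param schedule The block's [trial_schedule()].
#' @param alpha_per_ms Kernel decay parameter, 1/ms.
#' @param kernel_duration_ms Kernel truncation, ms.
#' @param window Peristimulus window `[start, end)`, ms.
#' @param baseline_interval Baseline interval `[start, end)`, ms.
#' @param max_dev_deg Fixation tolerance, degrees.
#' @param presmooth_ms Optional derivative pre-smoothing, ms.
#' @return List with `recording` (filtered), `event_idx`,
#'   `event_times_ms`, `trains`, `rates` (list `A`, `B`, `diff`) and
#'   `fraction_removed`.
#' @export
pupil_rate_analysis <- function(recording, schedule, alpha_per_ms = 1 / 50,
                                kernel_duration_ms = 500,
                                window = c(-500, 1500),
                                baseline_interval = c(-200, 0),
                                max_dev_deg = 1.0, presmooth_ms = 0) {
  rec <- filter_fixation(recording, max_dev_deg)
  idx <- detect_dilation_events(rec, presmooth_ms)
  ev_ms <- rec$t[idx]
  trains <- epoch_events(ev_ms, schedule, window)
  kernel <- make_kernel(alpha_per_ms, fs = rec$fs,
                        duration_ms = kernel_duration_ms)
  rates <- condition_rates(trains, kernel, baseline_interval)
  list(recording = rec, event_idx = idx, event_times_ms = ev_ms,
       trains = trains, rates = rates,
       fraction_removed = attr(rec, "fraction_removed"))
}

#' Simulate a complete multi-subject pupil study
#'
#' Draws an independent schedule and recording per subject with a shared
#' pair of condition specs.
#'
#' @param n_subjects Number of subjects.
#' @param spec_a,spec_b Condition [pupil_sim_spec()]s.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param n_trials,snippet_ms,isi_min_ms,isi_max_ms Schedule parameters.
#' @return List of per-subject lists with `schedule`, `recording`,
#'   `event_times_ms` (ground truth).
#' @export
simulate_pupil_study <- function(n_subjects = 10,
                                 spec_a = pupil_sim_spec(),
                                 spec_b = pupil_sim_spec(bump_amplitude = 0),
                                 seed = NULL, n_trials = 200,
                                 snippet_ms = 750, isi_min_ms = 1000,
                                 isi_max_ms = 1500) {
  if (!is.null(seed)) set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    sched <- generate_trial_schedule(n_trials, snippet_ms, isi_min_ms,
                                     isi_max_ms,
                                     seed = subj_seeds[2L * s - 1L])
    sim <- generate_pupil_recording(sched, spec_a, spec_b,
                                    seed = subj_seeds[2L * s])
    list(schedule = sched, recording = sim$recording,
         event_times_ms = sim$event_times_ms)
  })
}
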