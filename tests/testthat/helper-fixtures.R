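# Shared fixture builders; everything is generated in code.

# Tiny uniform recording from a diameter trace, all gaze on fixation.
toy_recording <- function(diameter, fs = 1000, gaze_x = 0, gaze_y = 0,
                          valid = TRUE) {
  n <- length(diameter)
  pupil_recording(diameter,
                  gaze_x = rep(gaze_x, length.out = n),
                  gaze_y = rep(gaze_y, length.out = n),
                  fs = fs, valid = rep(valid, length.out = n))
}

# Independent brute-force dilation-event scan over all sample triples.
oracle_detect <- function(x, valid = rep(TRUE, length(x))) {
  idx <- integer(0)
  for (i in 2:(length(x) - 1L)) {
    d_prev <- x[i] - x[i - 1L]
    d_cur <- x[i + 1L] - x[i]
    ok <- valid[i - 1L] && valid[i] && valid[i + 1L]
    if (ok && d_cur > 0 && d_prev <= 0) idx <- c(idx, i)
  }
  idx
}

# Small deterministic epoch_set with a given data array.
toy_epochs <- function(data, fs = 100, conditions = NULL,
                       times = NULL) {
  d <- dim(data)
  if (is.null(conditions)) {
    conditions <- rep(c("A", "B"), length.out = d[1])
  }
  if (is.null(times)) times <- (seq_len(d[3]) - 1L) * 1000 / fs
  epoch_set(data, times = times, fs = fs, conditions = conditions,
            layout = data.frame(channel = paste0("ch", seq_len(d[2])),
                                x = seq_len(d[2]), y = rep(0, d[2])),
            subject_id = "toy")
}

# Subject-by-channel-by-time arrays for the paired cluster test, with an
# optional constant effect block added to `a`.
paired_arrays <- function(n_subj, n_chan, n_time, noise_sd = 1,
                          effect = 0, effect_channels = integer(0),
                          effect_times = integer(0), seed = 1) {
  set.seed(seed)
  a <- array(rnorm(n_subj * n_chan * n_time, 0, noise_sd),
             dim = c(n_subj, n_chan, n_time))
  b <- array(rnorm(n_subj * n_chan * n_time, 0, noise_sd),
             dim = c(n_subj, n_chan, n_time))
  if (effect != 0) {
    a[, effect_channels, effect_times] <-
      a[, effect_channels, effect_times] + effect
  }
  list(a = a, b = b)
}

# Planar grid layout (package-internal helper, re-exposed for tests).
grid_layout_df <- function(n_channels) phasic:::grid_layout(n_channels)
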