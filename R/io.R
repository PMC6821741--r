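#' Read a pupil recording from CSV
#'
#' The dialect is a header row `t_ms,diameter,gaze_x_deg,gaze_y_deg` with one
#' sample per row on a uniform time grid. The sampling rate is inferred from
#' the median time step and the grid is checked for uniformity to within
#' 1 ppm.
#'
#' @param path Path to the CSV file.
#' @return A [pupil_recording()] with `valid` all `TRUE`.
#' @export
read_pupil_csv <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("t_ms", "diameter", "gaze_x_deg", "gaze_y_deg")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("pupil CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(dt) < 2L) stop("pupil CSV must contain at least 2 samples",
                          call. = FALSE)
  step <- stats::median(diff(dt$t_ms))
  if (!is.finite(step) || step <= 0) {
    stop("cannot infer sampling rate: time stamps not increasing",
         call. = FALSE)
  }
  pupil_recording(diameter = dt$diameter, gaze_x = dt$gaze_x_deg,
                  gaze_y = dt$gaze_y_deg, fs = 1000 / step, t = dt$t_ms)
}

#' Write a pupil recording to CSV
#'
#' @param x A [pupil_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pupil_csv <- function(x, path) {
  stopifnot(inherits(x, "pupil_recording"))
  data.table::fwrite(
    data.frame(t_ms = x$t, diameter = x$diameter,
               gaze_x_deg = x$gaze_x, gaze_y_deg = x$gaze_y),
    path)
  invisible(path)
}

#' Read / write a trial schedule CSV (`onset_ms,condition`)
#'
#' @param path CSV path.
#' @param snippet_ms Snippet duration in ms (stored outside the CSV).
#' @param balanced Passed through to [trial_schedule()].
#' @return A [trial_schedule()].
#' @export
read_trial_schedule <- function(path, snippet_ms = 750, balanced = TRUE) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  if (!all(c("onset_ms", "condition") %in% names(dt))) {
    stop("schedule CSV needs columns onset_ms,condition", call. = FALSE)
  }
  trial_schedule(dt$onset_ms, dt$condition, snippet_ms = snippet_ms,
                 balanced = balanced)
}

#' @rdname read_trial_schedule
#' @param x A [trial_schedule()].
#' @export
write_trial_schedule <- function(x, path) {
  stopifnot(inherits(x, "trial_schedule"))
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

# Sidecar/matrix path pair for the epochs container.
epochs_paths <- function(path) {
  base <- sub("\\.json$", "", path)
  list(json = paste0(base, ".json"), mat = paste0(base, ".dat.csv"))
}

#' Write an EEG epoch set as JSON sidecar + flat matrix
#'
#' The container is plain text: a JSON sidecar holding sampling rate, time
#' axis, condition labels, layout and identifiers, next to a headerless CSV
#' matrix of `epoch * channel` rows by `time` columns (epoch-major order).
#'
#' @param x An [epoch_set()].
#' @param path Base path; `<path>.json` and `<path>.dat.csv` are written.
#' @return The sidecar path, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  p <- epochs_paths(path)
  d <- dim(x$data)
  sidecar <- list(
    fs = x$fs, times_ms = x$times, conditions = x$conditions,
    layout = x$layout, subject_id = x$subject_id, group = x$group,
    dyad_id = x$dyad_id,
    n_epochs = d[1], n_channels = d[2], n_times = d[3])
  jsonlite::write_json(sidecar, p$json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  # rows ordered epoch-major: (epoch 1, channel 1..C), (epoch 2, ...)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat), p$mat,
                     col.names = FALSE)
  invisible(p$json)
}

#' Read an EEG epoch set written by [write_epochs()]
#'
#' @param path Base path or sidecar path used at write time.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  p <- epochs_paths(path)
  if (!file.exists(p$json)) stop("sidecar not found: ", p$json, call. = FALSE)
  sc <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  mat <- as.matrix(data.table::fread(p$mat, header = FALSE))
  storage.mode(mat) <- "double"
  ne <- sc$n_epochs; nc <- sc$n_channels; nt <- sc$n_times
  if (nrow(mat) != ne * nc || ncol(mat) != nt) {
    stop(sprintf(
      "epochs matrix shape [%d x %d] does not match sidecar (%d epochs x %d channels x %d samples)",
      nrow(mat), ncol(mat), ne, nc, nt), call. = FALSE)
  }
  data <- aperm(array(t(mat), dim = c(nt, nc, ne)), c(3, 2, 1))
  layout <- as.data.frame(sc$layout)
  epoch_set(data, times = sc$times_ms, fs = sc$fs,
            conditions = sc$conditions, layout = layout,
            subject_id = sc$subject_id, group = sc$group,
            dyad_id = if (is.null(sc$dyad_id)) NA_integer_ else sc$dyad_id)
}

#' Write a rate series / significance-interval / cluster table CSV
#'
#' Small convenience writers for the standard pipeline outputs.
#'
#' @param x Object to write (see Details).
#' @param path Output path.
#' @return `path`, invisibly.
#' @details `write_rate_csv()` writes columns
#'   `t_ms,rate_eventspersec,condition,n_trials`;
#'   `write_intervals_csv()` writes `start_ms,end_ms`.
#' @export
write_rate_csv <- function(x, path) {
  stopifnot(inherits(x, "event_rate_series"))
  data.table::fwrite(
    data.frame(t_ms = x$times_ms, rate_eventspersec = x$rate,
               condition = x$condition, n_trials = x$n_trials),
    path)
  invisible(path)
}

#' @rdname write_rate_csv
#' @export
write_h0_csv <- function(x, path) {
  stopifnot(inherits(x, "h0_distribution"), is.numeric(x$samples),
            !is.matrix(x$samples))
  data.table::fwrite(data.frame(sample = x$samples), path)
  invisible(path)
}

#' @rdname write_rate_csv
#' @export
write_intervals_csv <- function(x, path) {
  iv <- if (is.data.frame(x)) x else x$intervals
  if (is.null(iv) || !nrow(iv)) {
    iv <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  }
  data.table::fwrite(iv, path)
  invisible(path)
}
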