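#' Bootstrap test configuration
#'
#' @param n_iter Number of bootstrap iterations (>= 100).
#' @param criterion Proportion criterion in (0.5, 1): a time point is
#'   significant when the proportion of bootstrap means above zero, or the
#'   proportion below zero, exceeds this value. The OR over the two tails
#'   makes the effective two-sided level about `2 * (1 - criterion)`
#'   (~0.02 at the default 0.99).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param side Only `"two_tailed_criterion"` (the OR rule) is implemented.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_iter = 1000, criterion = 0.99, seed = NULL,
                             side = "two_tailed_criterion") {
  stopifnot(n_iter >= 100, criterion > 0.5, criterion < 1)
  side <- match.arg(side, "two_tailed_criterion")
  structure(list(n_iter = as.integer(n_iter), criterion = criterion,
                 seed = seed, side = side),
            class = "bootstrap_config")
}

# Coerce subject difference input (matrix or list of event_rate_series)
# to a subjects x time matrix plus time axis.
as_diff_matrix <- function(subject_diffs, times_ms = NULL) {
  if (is.list(subject_diffs) && !is.data.frame(subject_diffs) &&
      !is.matrix(subject_diffs)) {
    times_ms <- subject_diffs[[1L]]$times_ms
    subject_diffs <- do.call(rbind,
                             lapply(subject_diffs, function(s) s$rate))
  }
  stopifnot(is.matrix(subject_diffs))
  if (is.null(times_ms)) times_ms <- seq_len(ncol(subject_diffs))
  list(d = subject_diffs, times_ms = as.numeric(times_ms))
}

# Maximal runs of a logical mask, reported as half-open ms intervals.
mask_intervals <- function(mask, times_ms) {
  if (!any(mask)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  }
  step <- if (length(times_ms) > 1L) times_ms[2] - times_ms[1] else 1
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_ms = times_ms[starts[keep]],
             end_ms = times_ms[ends[keep]] + step)
}

#' Subject-level bootstrap test of a condition difference time series
#'
#' Each iteration resamples subjects with replacement and stores the
#' across-subject mean difference series. At every time point the
#' difference is declared significant when the proportion of bootstrap
#' means above zero, or below zero, exceeds the criterion (default 0.99).
#' Maximal runs of significant samples are reported as intervals; a run of
#' a single sample counts.
#'
#' @param subject_diffs Subjects-by-time numeric matrix of per-subject
#'   condition difference series, or a list of difference
#'   [event_rate_series()].
#' @param cfg A [bootstrap_config()].
#' @param times_ms Time axis in ms (taken from the series when
#'   `subject_diffs` is a list).
#' @return An object of class `significance_mask`: list with `times_ms`,
#'   `significant`, `intervals` (data frame `start_ms`,`end_ms`),
#'   `prop_above`, `boot_mean`, `boot_sd`, and the configuration used.
#' @export
bootstrap_difference_test <- function(subject_diffs,
                                      cfg = bootstrap_config(),
                                      times_ms = NULL) {
  dm <- as_diff_matrix(subject_diffs, times_ms)
  d <- dm$d
  n <- nrow(d)
  if (n < 2L) stop("bootstrap over subjects needs at least 2 subjects",
                   call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  # multinomial resampling counts are equivalent to index resampling
  counts <- stats::rmultinom(cfg$n_iter, size = n, prob = rep(1 / n, n))
  bm <- crossprod(counts, d) / n          # n_iter x time
  prop_above <- colMeans(bm > 0)
  prop_below <- colMeans(bm < 0)
  sig <- prop_above > cfg$criterion | prop_below > cfg$criterion
  structure(
    list(times_ms = dm$times_ms, significant = sig,
         intervals = mask_intervals(sig, dm$times_ms),
         prop_above = prop_above,
         boot_mean = colMeans(bm), boot_sd = apply(bm, 2, stats::sd),
         cfg = cfg, n_subjects = n),
    class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> %d/%d significant samples, %d interval(s)\n",
    sum(x$significant), length(x$significant), nrow(x$intervals)))
  if (nrow(x$intervals)) {
    cat(paste(sprintf("  [%g, %g) ms", x$intervals$start_ms,
                      x$intervals$end_ms), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Trial-shuffle permutation control of the pupil bootstrap test
#'
#' For every iteration, each subject's trials are pooled across conditions
#' and randomly reassigned to the two labels (preserving the condition
#' counts); the per-subject difference series and the subject-level
#' bootstrap test are then recomputed. Because the relabelling destroys any
#' true condition effect, the frequency of iterations with at least one
#' significant time point estimates the procedure's false-positive rate.
#'
#' @param trains_by_subject List (one element per subject) of lists of
#'   [pupil_event_train()] covering both conditions.
#' @param kernel A [make_kernel()].
#' @param cfg A [bootstrap_config()] for the inner bootstrap test.
#' @param n_iter Number of shuffle iterations.
#' @param seed Master seed; inner bootstrap seeds are derived from it.
#' @param baseline_interval Passed to [event_rate()].
#' @return List with `freq_any_significant`, logical vector
#'   `any_significant` per iteration, `n_iter` and `seed`.
#' @export
trial_shuffle_control <- function(trains_by_subject, kernel,
                                  cfg = bootstrap_config(), n_iter = 100,
                                  seed = NULL,
                                  baseline_interval = c(-200, 0)) {
  stopifnot(n_iter >= 1)
  for (subj in trains_by_subject) {
    conds <- vapply(subj, `[[`, "", "condition")
    if (length(unique(conds)) < 2L) {
      stop("every subject needs trials from both conditions",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  iter_intervals <- vector("list", n_iter)
  any_sig <- logical(n_iter)
  for (it in seq_len(n_iter)) {
    diffs <- lapply(trains_by_subject, function(subj) {
      conds <- vapply(subj, `[[`, "", "condition")
      new_conds <- sample(conds)
      subj <- lapply(seq_along(subj), function(k) {
        tr <- subj[[k]]
        tr$condition <- new_conds[k]
        tr
      })
      condition_rates(subj, kernel, baseline_interval)$diff
    })
    icfg <- cfg
    icfg$seed <- iter_seeds[it]
    res <- bootstrap_difference_test(diffs, icfg)
    any_sig[it] <- any(res$significant)
    iter_intervals[[it]] <- res$intervals
  }
  list(freq_any_significant = mean(any_sig), any_significant = any_sig,
       intervals = iter_intervals, n_iter = n_iter, seed = seed)
}

#' Null distribution from an unfamiliar-listener control pool
#'
#' Each iteration draws `n_pick` control datasets with replacement from the
#' pool and averages their condition-difference series; the collection of
#' these averages (optionally reduced to the mean over a time interval)
#' forms the H0 distribution against which an observed effect is ranked.
#'
#' @param control_diffs Datasets-by-time matrix of condition difference
#'   series, or a list of difference [event_rate_series()].
#' @param n_pick Number of datasets drawn per iteration.
#' @param n_iter Number of iterations.
#' @param seed Integer RNG seed.
#' @param interval Optional `[start, end)` ms interval; when given, each
#'   iteration is reduced to its mean over the interval and `samples` is a
#'   numeric vector, otherwise a matrix of mean series is returned.
#' @param times_ms Time axis (taken from the series when available).
#' @return An object of class `h0_distribution` with fields `samples`,
#'   `observed` (NA until compared), `p_value` (NA), `n_iter`.
#' @export
control_pool_bootstrap <- function(control_diffs, n_pick = 10,
                                   n_iter = 1000, seed = NULL,
                                   interval = NULL, times_ms = NULL) {
  dm <- as_diff_matrix(control_diffs, times_ms)
  pool <- nrow(dm$d)
  if (pool < 1L) stop("empty control pool", call. = FALSE)
  if (pool < n_pick) stop("pool smaller than n_pick", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- matrix(sample.int(pool, n_pick * n_iter, replace = TRUE),
                 nrow = n_iter)
  means <- t(apply(draw, 1, function(idx) colMeans(dm$d[idx, , drop = FALSE])))
  if (ncol(dm$d) == 1L) means <- matrix(means, ncol = 1L)
  if (!is.null(interval)) {
    sel <- dm$times_ms >= interval[1] & dm$times_ms < interval[2]
    if (!any(sel)) stop("interval contains no samples", call. = FALSE)
    samples <- rowMeans(means[, sel, drop = FALSE])
  } else {
    samples <- means
  }
  h0_distribution(samples, n_iter = n_iter)
}

#' H0 distribution container
#'
#' @param samples Numeric vector (or iteration-by-time matrix) of
#'   resampled statistic values.
#' @param observed Observed statistic, if already compared.
#' @param p_value Resampling p-value, if already computed.
#' @param n_iter Number of resampling iterations.
#' @return An object of class `h0_distribution`.
#' @export
h0_distribution <- function(samples, observed = NA_real_,
                            p_value = NA_real_, n_iter = NULL) {
  if (is.null(n_iter)) {
    n_iter <- if (is.matrix(samples)) nrow(samples) else length(samples)
  }
  structure(list(samples = samples, observed = observed,
                 p_value = p_value, n_iter = n_iter),
            class = "h0_distribution")
}

#' Resampling p-value of an observed interval mean against H0
#'
#' Uses the add-one convention `p = (1 + #{samples at least as extreme}) /
#' (n_iter + 1)` so that p is never exactly zero; the two-sided value
#' doubles the smaller tail and is capped at 1.
#'
#' @param observed Observed scalar statistic.
#' @param h0 An [h0_distribution()] with a numeric vector of samples.
#' @param side `"two_sided"`, `"greater"` or `"less"`.
#' @return The [h0_distribution()] with `observed` and `p_value` filled in.
#' @export
interval_mean_pvalue <- function(observed, h0,
                                 side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(inherits(h0, "h0_distribution"), is.numeric(h0$samples),
            !is.matrix(h0$samples), length(h0$samples) >= 1L)
  s <- h0$samples
  n <- length(s)
  p_greater <- (1 + sum(s >= observed)) / (n + 1)
  p_less <- (1 + sum(s <= observed)) / (n + 1)
  p <- switch(side,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  h0$observed <- observed
  h0$p_value <- p
  h0
}

#' Behavioural proportion-correct t-tests
#'
#' Standard pooled-variance independent-samples t-test between the two
#' groups plus a one-sample t-test of each group against chance.
#'
#' @param scores_main,scores_control Per-subject proportion-correct scores.
#' @param chance Chance level (default 0.5).
#' @return List with elements `independent`, `one_sample_main`,
#'   `one_sample_control`, each a list `t`, `df`, `p`.
#' @export
proportion_correct_tests <- function(scores_main, scores_control,
                                     chance = 0.5) {
  stopifnot(length(scores_main) >= 2L, length(scores_control) >= 2L)
  tidy_t <- function(ht) list(t = unname(ht$statistic),
                              df = unname(ht$parameter),
                              p = ht$p.value)
  two_sample <- function(x, y) {
    sp2 <- ((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 == 0) {
      # degenerate: zero pooled variance; t.test refuses constant data
      df <- length(x) + length(y) - 2
      tt <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
      return(list(t = tt, df = df, p = if (tt == 0) 1 else 0))
    }
    tidy_t(stats::t.test(x, y, var.equal = TRUE))
  }
  one_sample <- function(x, mu) {
    if (stats::sd(x) == 0) {
      tt <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
      return(list(t = tt, df = length(x) - 1, p = if (tt == 0) 1 else 0))
    }
    tidy_t(stats::t.test(x, mu = mu))
  }
  list(independent = two_sample(scores_main, scores_control),
       one_sample_main = one_sample(scores_main, chance),
       one_sample_control = one_sample(scores_control, chance))
}
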