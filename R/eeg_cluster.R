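#' Preprocess continuous EEG into stimulus-locked epochs
#'
#' Runs the standard chain: anti-aliased decimation to the analysis rate,
#' zero-phase FIR low-pass, re-referencing to the across-channel average,
#' epoching on a half-open window, and baseline correction with the
#' pre-onset mean. Onsets are aligned to the nearest sample of the
#' analysis-rate grid.
#'
#' @param x Numeric matrix `[time x channel]` of continuous data, microvolts.
#' @param fs Input sampling rate, Hz (must be an integer multiple of
#'   `target_fs` and at least twice `lowpass_hz`).
#' @param onsets_ms Stimulus onsets, ms from recording start.
#' @param conditions Condition label per onset.
#' @param layout Channel layout data frame (`channel`, `x`, `y`).
#' @param target_fs Analysis sampling rate, Hz.
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param window_ms Half-open epoch window `[start, end)`, ms.
#' @param baseline_ms Half-open baseline interval, ms.
#' @param subject_id,group,dyad_id Metadata stored on the result.
#' @return An [epoch_set()].
#' @export
preprocess_eeg <- function(x, fs, onsets_ms, conditions, layout,
                           target_fs = 128, lowpass_hz = 40,
                           window_ms = c(-500, 1500),
                           baseline_ms = c(-200, 0),
                           subject_id = NA_character_, group = "main",
                           dyad_id = NA_integer_) {
  stopifnot(is.matrix(x), fs >= 2 * lowpass_hz,
            length(onsets_ms) == length(conditions))
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("input rate must be an integer multiple of the target rate",
         call. = FALSE)
  }
  q <- as.integer(round(q))
  if (q > 1L) {
    # anti-alias at 80% of the post-decimation Nyquist, zero phase
    b_aa <- signal::fir1(max(30L, 10L * q), 0.8 / q)
    x <- apply(x, 2, function(ch) signal::filtfilt(b_aa, ch))
    x <- x[seq(1L, nrow(x), by = q), , drop = FALSE]
  }
  b_lp <- signal::fir1(64, lowpass_hz / (target_fs / 2))
  x <- apply(x, 2, function(ch) signal::filtfilt(b_lp, ch))
  x <- x - rowMeans(x)                       # average reference
  step <- 1000 / target_fs
  n_samp <- round((window_ms[2] - window_ms[1]) / step)
  times <- window_ms[1] + (seq_len(n_samp) - 1L) * step
  n_ep <- length(onsets_ms)
  data <- array(NA_real_, dim = c(n_ep, ncol(x), n_samp))
  for (e in seq_len(n_ep)) {
    k0 <- round((onsets_ms[e] + window_ms[1]) / step) + 1L
    if (k0 < 1L || k0 + n_samp - 1L > nrow(x)) {
      stop("epoch window exceeds data bounds", call. = FALSE)
    }
    data[e, , ] <- t(x[k0:(k0 + n_samp - 1L), , drop = FALSE])
  }
  bsel <- times >= baseline_ms[1] & times < baseline_ms[2]
  if (!any(bsel)) stop("baseline interval contains no samples",
                       call. = FALSE)
  for (e in seq_len(n_ep)) {
    blm <- rowMeans(matrix(data[e, , bsel], nrow = ncol(x)))
    data[e, , ] <- data[e, , ] - blm
  }
  epoch_set(data, times = times, fs = target_fs, conditions = conditions,
            layout = layout, subject_id = subject_id, group = group,
            dyad_id = dyad_id)
}

#' Automatic epoch rejection from summary statistics
#'
#' Computes six per-epoch summary statistics — variance, range, maximum
#' absolute value, mean absolute z-score, maximum absolute z-score and
#' kurtosis (z-scores are taken per channel-time sample across epochs, the
#' remaining statistics over the flattened epoch) — and rejects every epoch
#' whose robust z-score (median/MAD) on any statistic exceeds the
#' threshold. This is an automatic thresholding rejector intended to stand
#' in for interactive visual screening.
#'
#' @param epochs An [epoch_set()] with at least 3 epochs.
#' @param z_threshold Robust z-score threshold (one-sided, high).
#' @return List with `epochs` (the retained subset) and `log`, a data
#'   frame of the per-epoch statistics, robust z-scores and the rejection
#'   flag.
#' @export
reject_epochs_by_stats <- function(epochs, z_threshold = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 3L) stop("need at least 3 epochs", call. = FALSE)
  mu <- apply(epochs$data, c(2, 3), mean)
  sdv <- apply(epochs$data, c(2, 3), stats::sd)
  sdv[sdv == 0] <- Inf                      # constant samples carry no z
  stats_df <- t(vapply(seq_len(d[1]), function(e) {
    v <- epochs$data[e, , ]
    z <- abs((v - mu) / sdv)
    c(variance = stats::var(as.vector(v)),
      range = diff(range(v)),
      max_abs = max(abs(v)),
      mean_z = mean(z),
      max_z = max(z),
      kurtosis = e1071::kurtosis(as.vector(v)))
  }, numeric(6)))
  rz <- apply(stats_df, 2, function(s) {
    md <- stats::median(s)
    sc <- stats::mad(s)
    if (sc == 0) ifelse(s == md, 0, Inf * sign(s - md)) else (s - md) / sc
  })
  rejected <- apply(rz, 1, function(r) any(r > z_threshold))
  if (all(rejected)) stop("all epochs rejected", call. = FALSE)
  keep <- which(!rejected)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$conditions <- epochs$conditions[keep]
  log_df <- data.frame(epoch = seq_len(d[1]), stats_df,
                       rejected = rejected)
  list(epochs = out, log = log_df)
}

#' Channel adjacency from planar layout
#'
#' Two channels are neighbours iff their Euclidean planar distance is at
#' most `max_dist`.
#'
#' @param layout Data frame with `channel`, `x`, `y`.
#' @param max_dist Distance threshold in layout units.
#' @return An object of class `adjacency_graph`: `n_channels`, `edges`
#'   (two-column matrix of channel index pairs, `i < j`), `max_dist` and
#'   `neighbors` (list of integer vectors).
#' @export
build_adjacency <- function(layout, max_dist) {
  stopifnot(is.data.frame(layout), nrow(layout) >= 1L, max_dist >= 0)
  nc <- nrow(layout)
  dmat <- as.matrix(stats::dist(layout[, c("x", "y")]))
  pairs <- which(upper.tri(dmat) & dmat <= max_dist, arr.ind = TRUE)
  edges <- unname(cbind(pairs[, 1], pairs[, 2]))
  nbrs <- lapply(seq_len(nc), function(i) {
    sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  })
  structure(list(n_channels = nc, edges = edges, max_dist = max_dist,
                 neighbors = nbrs),
            class = "adjacency_graph")
}

# Spatio-temporal neighbour lists on the channel x time lattice.
# Node index = channel + (time - 1) * n_channels.
lattice_neighbors <- function(adjacency, n_time) {
  nc <- adjacency$n_channels
  nbrs <- vector("list", nc * n_time)
  for (tt in seq_len(n_time)) {
    off <- (tt - 1L) * nc
    for (c in seq_len(nc)) {
      nb <- adjacency$neighbors[[c]] + off
      if (tt > 1L) nb <- c(nb, c + off - nc)
      if (tt < n_time) nb <- c(nb, c + off + nc)
      nbrs[[c + off]] <- nb
    }
  }
  nbrs
}

# Connected components of `mask` under the neighbour lists; returns an
# integer component label per node (0 = not in mask).
label_components <- function(mask, nbrs) {
  comp <- integer(length(mask))
  cur <- 0L
  for (v in which(mask)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    comp[v] <- cur
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in nbrs[[u]]) {
        if (mask[w] && comp[w] == 0L) {
          comp[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

# All suprathreshold clusters of a t map (per sign); list of
# (nodes, t_sum, sign).
find_clusters <- function(tvals, nbrs, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tvals > tcrit else tvals < -tcrit
    if (!any(mask)) next
    comp <- label_components(mask, nbrs)
    for (k in seq_len(max(comp))) {
      nodes <- which(comp == k)
      out[[length(out) + 1L]] <- list(
        nodes = nodes, t_sum = sum(tvals[nodes]),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out
}

max_cluster_stat <- function(tvals, nbrs, tcrit) {
  cl <- find_clusters(tvals, nbrs, tcrit)
  if (!length(cl)) return(0)
  max(abs(vapply(cl, `[[`, 0, "t_sum")))
}

#' Spatio-temporal cluster-based permutation test (paired design)
#'
#' Computes a paired t-statistic between the two conditions at every
#' (channel, time) sample, thresholds it two-sided at `cluster_alpha`,
#' groups suprathreshold samples of equal sign into connected components
#' under spatial channel adjacency plus temporal succession, and scores
#' each cluster by the sum of its t-values (`t_sum`). The null
#' distribution of the maximal `|t_sum|` is obtained by flipping each
#' subject's condition sign — exhaustively over all `2^n` assignments when
#' `2^n <= n_perm`, otherwise by seeded Monte-Carlo draws — which controls
#' the family-wise error rate across the whole channel-by-time search
#' space.
#'
#' @param a,b Arrays `[subject x channel x time]` of per-subject condition
#'   means (see [condition_means()]); the test statistic addresses A - B.
#' @param adjacency An [build_adjacency()] graph over the channels.
#' @param n_perm Number of permutations (upper bound when exhaustive
#'   enumeration is feasible).
#' @param cluster_alpha Two-sided cluster-forming threshold on the paired
#'   t-statistic.
#' @param fwer_alpha Family-wise significance level for clusters.
#' @param seed Integer RNG seed for the Monte-Carlo flips.
#' @return An object of class `cluster_test_result`: `clusters` (each with
#'   `members` data frame of channel/time indices, `t_sum`, `sign`,
#'   `p_value`, `significant`), the `tmap` `[channel x time]`,
#'   `null_max_stats`, `n_perm`, `mode` (`"exhaustive"` or
#'   `"montecarlo"`), thresholds and `tcrit`.
#' @export
cluster_permutation_test <- function(a, b, adjacency, n_perm = 1000,
                                     cluster_alpha = 0.05,
                                     fwer_alpha = 0.05, seed = NULL) {
  stopifnot(is.array(a), is.array(b), all(dim(a) == dim(b)),
            length(dim(a)) == 3L,
            inherits(adjacency, "adjacency_graph"),
            dim(a)[2] == adjacency$n_channels)
  n <- dim(a)[1]
  if (n < 2L) stop("paired design needs at least 2 subjects",
                   call. = FALSE)
  nc <- dim(a)[2]
  ntm <- dim(a)[3]
  np <- nc * ntm
  d <- matrix(a - b, nrow = n)             # n x (channel * time)
  nbrs <- lattice_neighbors(adjacency, ntm)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  ss <- colSums(d^2)                       # invariant under sign flips

  t_of_means <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    tt <- m / sqrt(v / n)
    bad <- !is.finite(tt)                  # zero variance: 0/0 or m/0
    tt[bad] <- sign(m[bad]) * Inf
    tt[bad & m == 0] <- 0
    tt
  }

  tmap <- t_of_means(colMeans(d))
  obs_clusters <- find_clusters(tmap, nbrs, tcrit)

  exhaustive <- 2^n <= n_perm
  flips <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(1, -1)), n)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    fl <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
    # the observed labelling (and its mirror) belongs to the observed
    # statistic, not the null sample: redraw such rows
    is_id <- function(m) abs(rowSums(m)) == n
    while (any(bad <- is_id(fl))) {
      fl[bad, ] <- sample(c(1, -1), sum(bad) * n, replace = TRUE)
    }
    fl
  }
  n_flip <- nrow(flips)
  means_f <- (flips %*% d) / n             # n_flip x np
  null_max <- numeric(n_flip)
  for (f in seq_len(n_flip)) {
    null_max[f] <- max_cluster_stat(t_of_means(means_f[f, ]), nbrs, tcrit)
  }

  clusters <- lapply(obs_clusters, function(cl) {
    stat <- abs(cl$t_sum)
    p <- if (exhaustive) {
      sum(null_max >= stat - 1e-12) / n_flip
    } else {
      (1 + sum(null_max >= stat - 1e-12)) / (n_flip + 1)
    }
    list(members = data.frame(channel = (cl$nodes - 1L) %% nc + 1L,
                              time = (cl$nodes - 1L) %/% nc + 1L),
         t_sum = cl$t_sum, sign = cl$sign, p_value = p,
         significant = p <= fwer_alpha)
  })
  ord <- order(vapply(clusters, function(cl) -abs(cl$t_sum), 0))
  structure(
    list(clusters = clusters[ord],
         tmap = matrix(tmap, nrow = nc, ncol = ntm),
         null_max_stats = null_max, n_perm = n_flip,
         mode = if (exhaustive) "exhaustive" else "montecarlo",
         cluster_alpha = cluster_alpha, fwer_alpha = fwer_alpha,
         tcrit = tcrit, n_subjects = n),
    class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_test_result> %d cluster(s), %s null of %d flips, FWER alpha %g\n",
    length(x$clusters), x$mode, x$n_perm, x$fwer_alpha))
  show <- utils::head(x$clusters, 6L)
  for (cl in show) {
    cat(sprintf("  %s: %d samples, t_sum = %.2f, p = %.4g%s\n",
                cl$sign, nrow(cl$members), cl$t_sum, cl$p_value,
                if (cl$significant) " *" else ""))
  }
  if (length(x$clusters) > length(show)) {
    cat(sprintf("  ... and %d smaller cluster(s)\n",
                length(x$clusters) - length(show)))
  }
  invisible(x)
}

#' Cluster table as a data frame
#'
#' One row per cluster: sign, number of distinct channels, temporal extent
#' in ms, summed t and corrected p.
#'
#' @param x A `cluster_test_result`.
#' @param times_ms Time axis of the tested window (ms); cluster extents
#'   are reported on it.
#' @return A data frame.
#' @export
cluster_table <- function(x, times_ms) {
  stopifnot(inherits(x, "cluster_test_result"))
  if (!length(x$clusters)) {
    return(data.frame(cluster_id = integer(0), sign = character(0),
                      n_channels = integer(0), t_start_ms = numeric(0),
                      t_end_ms = numeric(0), t_sum = numeric(0),
                      p = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    data.frame(cluster_id = i, sign = cl$sign,
               n_channels = length(unique(cl$members$channel)),
               t_start_ms = times_ms[min(cl$members$time)],
               t_end_ms = times_ms[max(cl$members$time)],
               t_sum = cl$t_sum, p = cl$p_value)
  }))
}

#' Mean amplitude over a cluster's members
#'
#' Averages the data over all (channel, time) pairs belonging to a
#' cluster, per subject — the dependent variable of the follow-up ANOVA.
#'
#' @param x Either a `[subject x channel x time]` array or a single
#'   `[channel x time]` matrix.
#' @param cluster One element of a `cluster_test_result`'s `clusters`
#'   list (or any list with a `members` data frame).
#' @return Numeric vector (one value per subject) or a scalar for a
#'   matrix input.
#' @export
cluster_mean_amplitude <- function(x, cluster) {
  members <- cluster$members
  if (is.null(members) || !nrow(members)) {
    stop("empty cluster", call. = FALSE)
  }
  if (is.matrix(x)) {
    return(mean(x[cbind(members$channel, members$time)]))
  }
  stopifnot(length(dim(x)) == 3L)
  vapply(seq_len(dim(x)[1]), function(s) {
    mean(x[s, , ][cbind(members$channel, members$time)])
  }, numeric(1))
}

#' Two-by-two mixed-design ANOVA
#'
#' Classical sums-of-squares decomposition for one within-subject factor
#' (two levels, e.g. familiarity) crossed with one between-subjects factor
#' (two groups), fitted with `stats::aov` using an error stratum per
#' subject. Partial eta squared is `SS_effect / (SS_effect + SS_error)`
#' within each effect's stratum.
#'
#' @param values Numeric matrix `[subject x 2]`, the two within-level
#'   scores per subject.
#' @param group Factor (or character) of length `nrow(values)` with two
#'   levels.
#' @return An object of class `anova_result`: data frame with rows
#'   `group`, `within`, `interaction` and columns `F`, `df_num`, `df_den`,
#'   `p`, `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(values, group) {
  stopifnot(is.matrix(values), ncol(values) == 2L)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required",
                                 call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  n <- nrow(values)
  df <- data.frame(
    y = c(values[, 1], values[, 2]),
    within = factor(rep(c("w1", "w2"), each = n)),
    group = rep(group, 2L),
    subject = factor(rep(seq_len(n), 2L)))
  fit <- stats::aov(y ~ group * within + Error(subject / within),
                    data = df)
  sm <- summary(fit)
  ss_scale <- sum((df$y - mean(df$y))^2)
  between <- as.data.frame(sm[["Error: subject"]][[1L]])
  within <- as.data.frame(sm[["Error: subject:within"]][[1L]])
  row_of <- function(tab, name) tab[trimws(rownames(tab)) == name, ]
  eff <- function(tab, name, err_name = "Residuals") {
    r <- row_of(tab, name)
    e <- row_of(tab, err_name)
    ss_eff <- r[["Sum Sq"]]
    ss_err <- e[["Sum Sq"]]
    tot <- ss_eff + ss_err
    if (tot <= 0 || ss_eff <= 1e-10 * max(ss_scale, 1e-300)) {
      # degenerate stratum (e.g. identical within-level scores):
      # an effect carrying no variance gets F = 0, not a 0/0 artefact
      fv <- 0; pv <- 1; eta <- 0
    } else {
      fv <- (ss_eff / r[["Df"]]) / (ss_err / e[["Df"]])
      pv <- stats::pf(fv, r[["Df"]], e[["Df"]], lower.tail = FALSE)
      eta <- ss_eff / tot
    }
    data.frame(F = fv, df_num = r[["Df"]], df_den = e[["Df"]], p = pv,
               partial_eta_sq = eta)
  }
  out <- rbind(group = eff(between, "group"),
               within = eff(within, "within"),
               interaction = eff(within, "group:within"))
  out$effect <- rownames(out)
  structure(out[, c("effect", "F", "df_num", "df_den", "p",
                    "partial_eta_sq")],
            class = c("anova_result", "data.frame"))
}

#' Dyad-matched control-group bootstrap
#'
#' Builds an H0 distribution by assigning, on each iteration, one randomly
#' drawn control subject to each dyad and averaging their
#' condition-difference scores (already reduced over the region of
#' interest) across dyads. The main group's observed mean difference is
#' then ranked in this distribution.
#'
#' @param main_diffs Numeric vector: per-dyad observed difference scores
#'   of the main group, averaged over the ROI.
#' @param control_pool List (one element per dyad) of numeric vectors:
#'   each control subject's difference score for that dyad.
#' @param n_iter Number of bootstrap iterations.
#' @param seed Integer RNG seed.
#' @param side Tail passed to [interval_mean_pvalue()].
#' @return An [h0_distribution()] with `observed` and `p_value` filled in.
#' @export
dyad_matched_bootstrap <- function(main_diffs, control_pool,
                                   n_iter = 1000, seed = NULL,
                                   side = "two_sided") {
  stopifnot(length(main_diffs) == length(control_pool))
  if (any(!vapply(control_pool, length, 0L))) {
    stop("every dyad needs at least one control subject", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- vapply(seq_len(n_iter), function(i) {
    mean(vapply(control_pool, function(pool) {
      pool[[sample.int(length(pool), 1L)]]
    }, numeric(1)))
  }, numeric(1))
  interval_mean_pvalue(mean(main_diffs),
                       h0_distribution(samples, n_iter = n_iter),
                       side = side)
}
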