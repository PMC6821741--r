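# --- preprocessing ---------------------------------------------------------

test_that("average reference and baseline correction are exact", {
  set.seed(71)
  fs <- 256
  n <- fs * 12
  x <- matrix(rnorm(n * 6, sd = 10), n, 6) +
    outer(sin(2 * pi * 5 * seq_len(n) / fs), rnorm(6, sd = 3))
  onsets <- c(3000, 6000, 9000)
  ep <- preprocess_eeg(x, fs, onsets, c("A", "B", "A"),
                       layout = data.frame(channel = paste0("c", 1:6),
                                           x = 1:6, y = 0))
  expect_equal(ep$fs, 128)
  expect_equal(dim(ep$data), c(3L, 6L, 256L))
  # per-channel mean over the baseline window is 0
  bsel <- ep$times >= -200 & ep$times < 0
  bl <- apply(ep$data[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  expect_error(
    preprocess_eeg(x, fs, c(100), "A",
                   layout = data.frame(channel = paste0("c", 1:6),
                                       x = 1:6, y = 0)),
    "bounds")
})

test_that("average referencing zeroes the across-channel mean", {
  set.seed(72)
  fs <- 256
  x <- matrix(rnorm(fs * 8 * 4), fs * 8, 4)
  ep <- preprocess_eeg(x, fs, c(2500, 5000), c("A", "B"),
                       layout = data.frame(channel = paste0("c", 1:4),
                                           x = 1:4, y = 0),
                       baseline_ms = c(-200, 0))
  # without baseline correction the channel mean would be 0 at every
  # sample; baseline correction subtracts channel-specific constants, so
  # re-add them before checking
  ch_means <- apply(ep$data, c(1, 3), mean)
  expect_lt(max(abs(ch_means - rowMeans(ch_means))), 1e-9)
})

test_that("the filter chain attenuates 50 Hz by 20 dB relative to 10 Hz", {
  fs <- 512
  tt <- seq_len(fs * 20) / fs
  layout <- data.frame(channel = "c1", x = 0, y = 0)
  gain_at <- function(freq) {
    x <- matrix(sin(2 * pi * freq * tt), ncol = 1)
    ep <- preprocess_eeg(cbind(x, -x), fs, seq(3000, 17000, by = 2000),
                         rep(c("A", "B"), 4),
                         layout = data.frame(channel = c("c1", "c2"),
                                             x = 0:1, y = 0),
                         baseline_ms = c(-200, 0))
    sqrt(mean(ep$data[, 1, ]^2))
  }
  g10 <- gain_at(10)
  g50 <- gain_at(50)
  expect_lt(20 * log10(g50 / g10), -20)
})

# --- epoch rejection -------------------------------------------------------

test_that("identical epochs are never rejected", {
  one <- array(rep(sin(seq(0, 4 * pi, length.out = 50)), each = 4),
               dim = c(1, 4, 50))
  data <- one[rep(1, 10), , , drop = FALSE]
  ep <- toy_epochs(data, fs = 100)
  out <- reject_epochs_by_stats(ep, z_threshold = 5)
  expect_equal(dim(out$epochs$data)[1], 10L)
  expect_false(any(out$log$rejected))
})

test_that("a gross amplitude spike is rejected and order does not matter", {
  set.seed(81)
  data <- array(rnorm(20 * 4 * 50), dim = c(20, 4, 50))
  data[7, 2, 25] <- 100 * max(abs(data))
  ep <- toy_epochs(data, fs = 100)
  out <- reject_epochs_by_stats(ep, z_threshold = 5)
  expect_true(out$log$rejected[7])
  expect_equal(sum(out$log$rejected), 1L)
  # permutation equivariance
  perm <- sample(20)
  ep2 <- toy_epochs(data[perm, , , drop = FALSE], fs = 100,
                    conditions = ep$conditions[perm])
  out2 <- reject_epochs_by_stats(ep2, z_threshold = 5)
  expect_equal(out2$log$rejected, out$log$rejected[perm])
  expect_error(reject_epochs_by_stats(toy_epochs(data[1:2, , ,
                                                      drop = FALSE])),
               "3 epochs")
})

# --- adjacency -------------------------------------------------------------

test_that("adjacency edges follow the distance threshold", {
  lay <- data.frame(channel = c("a", "b"), x = c(0, 1), y = c(0, 0))
  g <- build_adjacency(lay, max_dist = 2)
  expect_equal(nrow(g$edges), 1L)
  g0 <- build_adjacency(lay, max_dist = 0)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("grid adjacency equals the pairwise-distance oracle", {
  set.seed(82)
  lay <- data.frame(channel = paste0("c", 1:12),
                    x = runif(12, 0, 3), y = runif(12, 0, 3))
  g <- build_adjacency(lay, max_dist = 1.2)
  oracle <- matrix(FALSE, 12, 12)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      d <- sqrt((lay$x[i] - lay$x[j])^2 + (lay$y[i] - lay$y[j])^2)
      oracle[i, j] <- d <= 1.2
    }
  }
  got <- matrix(FALSE, 12, 12)
  got[g$edges] <- TRUE
  expect_identical(got, oracle)
  # neighbour lists agree with the edge set
  for (i in 1:12) {
    expect_identical(g$neighbors[[i]],
                     sort(which(oracle[i, ] | oracle[, i])))
  }
})

# --- cluster permutation test ----------------------------------------------

test_that("identical conditions yield no clusters", {
  set.seed(83)
  a <- array(rnorm(6 * 4 * 10), dim = c(6, 4, 10))
  adj <- build_adjacency(grid_layout_df(4), max_dist = 1.1)
  res <- cluster_permutation_test(a, a, adj, n_perm = 100, seed = 1)
  expect_length(res$clusters, 0L)
})

test_that("a strong localized effect is recovered at the minimal p", {
  arr <- paired_arrays(8, 9, 20, noise_sd = 1, effect = 10,
                       effect_channels = 1:3, effect_times = 5:14,
                       seed = 84)
  adj <- build_adjacency(grid_layout_df(9), max_dist = 1.1)
  res <- cluster_permutation_test(arr$a, arr$b, adj, n_perm = 200,
                                  seed = 2)
  expect_equal(res$mode, "montecarlo")
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_equal(length(sig), 1L)
  top <- sig[[1L]]
  expect_equal(top$sign, "positive")
  expect_equal(top$p_value, 1 / (200 + 1))
  # the cluster contains the injected block
  block <- expand.grid(channel = 1:3, time = 5:14)
  got <- paste(top$members$channel, top$members$time)
  expect_true(all(paste(block$channel, block$time) %in% got))
})

test_that("cluster p-values equal exhaustive sign-flip enumeration", {
  skip_if_not_installed("igraph")
  n_subj <- 6; n_chan <- 2; n_time <- 5
  arr <- paired_arrays(n_subj, n_chan, n_time, noise_sd = 1, effect = 2.5,
                       effect_channels = 1:2, effect_times = 2:4,
                       seed = 85)
  lay <- grid_layout_df(n_chan)
  adj <- build_adjacency(lay, max_dist = 1.1)
  res <- cluster_permutation_test(arr$a, arr$b, adj, n_perm = 100,
                                  cluster_alpha = 0.05, seed = 3)
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_perm, 64L)

  # ---- independent oracle -------------------------------------------------
  d <- arr$a - arr$b
  tcrit <- qt(0.975, n_subj - 1)
  tmap_of <- function(dd) {
    apply(matrix(dd, nrow = n_subj), 2, function(v) {
      unname(stats::t.test(v)$statistic)
    })
  }
  # clusters via igraph components on the thresholded lattice
  clusters_of <- function(tv) {
    nodes <- data.frame(id = seq_len(n_chan * n_time),
                        ch = rep(seq_len(n_chan), n_time),
                        tm = rep(seq_len(n_time), each = n_chan),
                        t = tv)
    out <- list()
    for (sgn in c(1, -1)) {
      keep <- nodes[sgn * nodes$t > tcrit, ]
      if (!nrow(keep)) next
      edges <- integer(0)
      for (i in seq_len(nrow(keep))) {
        for (j in seq_len(nrow(keep))) {
          if (i >= j) next
          spatial <- keep$tm[i] == keep$tm[j] &&
            abs(keep$ch[i] - keep$ch[j]) == 1
          temporal <- keep$ch[i] == keep$ch[j] &&
            abs(keep$tm[i] - keep$tm[j]) == 1
          if (spatial || temporal) edges <- c(edges, i, j)
        }
      }
      g <- igraph::make_empty_graph(nrow(keep), directed = FALSE)
      if (length(edges)) g <- igraph::add_edges(g, edges)
      comp <- igraph::components(g)$membership
      for (k in unique(comp)) {
        out[[length(out) + 1L]] <- sum(keep$t[comp == k])
      }
    }
    unlist(out)
  }
  obs_sums <- clusters_of(tmap_of(d))
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subj)))
  null_max <- apply(flips, 1, function(fl) {
    cs <- clusters_of(tmap_of(fl * matrix(d, nrow = n_subj)))
    if (length(cs)) max(abs(cs)) else 0
  })
  oracle_p <- vapply(obs_sums, function(s) {
    mean(null_max >= abs(s) - 1e-12)
  }, numeric(1))

  got_sums <- vapply(res$clusters, `[[`, 0, "t_sum")
  got_p <- vapply(res$clusters, `[[`, 0, "p_value")
  ord_g <- order(got_sums)
  ord_o <- order(obs_sums)
  expect_equal(got_sums[ord_g], obs_sums[ord_o], tolerance = 1e-10)
  expect_equal(got_p[ord_g], oracle_p[ord_o], tolerance = 1e-12)
})

test_that("detection frequency grows with effect size and overlaps truth", {
  adj <- build_adjacency(grid_layout_df(9), max_dist = 1.1)
  block <- expand.grid(channel = c(1, 2, 4, 5), time = 6:15)
  detect_at <- function(effect, seed) {
    arr <- paired_arrays(8, 9, 20, noise_sd = 1, effect = effect,
                         effect_channels = c(1, 2, 4, 5),
                         effect_times = 6:15, seed = seed)
    res <- cluster_permutation_test(arr$a, arr$b, adj, n_perm = 100,
                                    seed = seed)
    sig <- Filter(function(cl) cl$significant && cl$sign == "positive",
                  res$clusters)
    if (!length(sig)) return(c(found = 0, jaccard = 0))
    mem <- unique(paste(sig[[1L]]$members$channel,
                        sig[[1L]]$members$time))
    tru <- paste(block$channel, block$time)
    c(found = 1,
      jaccard = length(intersect(mem, tru)) / length(union(mem, tru)))
  }
  weak <- vapply(1:8, function(s) detect_at(0.4, s)["found"], numeric(1))
  strong <- vapply(1:8, function(s) detect_at(3, s), numeric(2))
  expect_gte(mean(strong["found", ]), mean(weak))
  expect_equal(mean(strong["found", ]), 1)
  expect_gte(mean(strong["jaccard", ]), 0.8)
})

# --- cluster means, ANOVA, dyad bootstrap ----------------------------------

test_that("cluster mean amplitude equals the loop oracle", {
  cl <- list(members = data.frame(channel = c(1, 2, 2),
                                  time = c(3, 3, 4)))
  x <- array(rnorm(5 * 3 * 6), dim = c(5, 3, 6))
  got <- cluster_mean_amplitude(x, cl)
  oracle <- vapply(1:5, function(s) {
    vals <- c(x[s, 1, 3], x[s, 2, 3], x[s, 2, 4])
    mean(vals)
  }, numeric(1))
  expect_equal(got, oracle)
  # constant data and single-member clusters
  xc <- array(3, dim = c(2, 3, 4))
  expect_equal(cluster_mean_amplitude(xc, cl), c(3, 3))
  single <- list(members = data.frame(channel = 2, time = 4))
  expect_equal(cluster_mean_amplitude(x, single), x[, 2, 4])
  expect_error(cluster_mean_amplitude(x, list(members = NULL)), "empty")
})

test_that("mixed ANOVA matches the definitional sums-of-squares oracle", {
  # balanced toy: 4 subjects per group, integer scores
  values <- rbind(c(10, 14), c(12, 18), c(11, 15), c(13, 17),  # group g1
                  c(9, 10), c(11, 11), c(10, 12), c(12, 11))   # group g2
  group <- rep(c("g1", "g2"), each = 4)
  res <- mixed_anova_2x2(values, group)

  # ---- definitional decomposition ----------------------------------------
  n_per <- 4; n_subj <- 8; n_lvl <- 2
  subj_mean <- rowMeans(values)
  grand <- mean(values)
  grp_mean <- tapply(subj_mean, group, mean)
  lvl_mean <- colMeans(values)
  cell_mean <- rbind(colMeans(values[1:4, ]), colMeans(values[5:8, ]))
  ss_group <- n_per * n_lvl * sum((grp_mean - grand)^2)
  ss_subj_within <- n_lvl * sum((subj_mean - grp_mean[group])^2)
  ss_within <- n_subj * sum((lvl_mean - grand)^2)
  ss_cells <- n_per * sum((cell_mean - grand)^2)
  ss_int <- ss_cells - ss_group - ss_within
  ss_total <- sum((values - grand)^2)
  ss_err_within <- ss_total - ss_group - ss_subj_within - ss_within - ss_int
  f_group <- (ss_group / 1) / (ss_subj_within / (n_subj - 2))
  f_within <- (ss_within / 1) / (ss_err_within / (n_subj - 2))
  f_int <- (ss_int / 1) / (ss_err_within / (n_subj - 2))

  expect_equal(res["group", "F"], f_group, tolerance = 1e-10)
  expect_equal(res["within", "F"], f_within, tolerance = 1e-10)
  expect_equal(res["interaction", "F"], f_int, tolerance = 1e-10)
  expect_equal(res["group", "df_den"], n_subj - 2)
  expect_equal(res["interaction", "partial_eta_sq"],
               ss_int / (ss_int + ss_err_within), tolerance = 1e-10)
  expect_equal(res["group", "partial_eta_sq"],
               ss_group / (ss_group + ss_subj_within), tolerance = 1e-10)
})

test_that("mixed ANOVA respects its symmetries", {
  set.seed(91)
  base <- rnorm(8)
  values <- cbind(base, base)              # no within-level difference
  res <- mixed_anova_2x2(values, rep(c("a", "b"), each = 4))
  expect_equal(res["within", "F"], 0, tolerance = 1e-12)
  expect_equal(res["interaction", "F"], 0, tolerance = 1e-12)
  # location invariance
  v2 <- matrix(rnorm(16), 8, 2)
  r1 <- mixed_anova_2x2(v2, rep(c("a", "b"), each = 4))
  r2 <- mixed_anova_2x2(v2 + 100, rep(c("a", "b"), each = 4))
  expect_equal(r1$F, r2$F, tolerance = 1e-8)
  expect_error(mixed_anova_2x2(v2[1:3, ], c("a", "a", "b")), "2 subjects")
})

test_that("dyad-matched bootstrap centres on the control pool mean", {
  set.seed(92)
  delta <- 0.8
  pool <- lapply(1:8, function(i) rnorm(12, mean = delta, sd = 0.5))
  res <- dyad_matched_bootstrap(rep(3, 8), pool, n_iter = 500, seed = 93)
  expect_lt(abs(mean(res$samples) - delta), 4 * sd(res$samples))
  expect_lt(res$p_value, 0.05)
  # degenerate pool: H0 collapses to 0 and any effect is minimal-p
  zero_pool <- lapply(1:8, function(i) rep(0, 3))
  rz <- dyad_matched_bootstrap(rep(1, 8), zero_pool, n_iter = 200,
                               seed = 94)
  expect_equal(max(abs(rz$samples)), 0)
  expect_equal(rz$p_value, 2 / 201)      # two-sided doubling of 1/(n+1)
  # seeded reproducibility
  r2 <- dyad_matched_bootstrap(rep(3, 8), pool, n_iter = 500, seed = 93)
  expect_identical(res$samples, r2$samples)
  expect_error(dyad_matched_bootstrap(rep(1, 2), list(1, numeric(0))),
               "control")
})
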