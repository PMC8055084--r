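test_that("CVCR residualization drops degenerate columns and removes
           confound-explained variance", {
  set.seed(1)
  n <- 120
  C <- cbind(a = rnorm(n), b = rnorm(n), const = 5)
  X <- cbind(2 * C[, 1] + rnorm(n, 0, 0.1), rnorm(n))
  train <- seq_len(80)
  R <- cvcr_residualize(X, C, train)
  # the confound-driven column is near-orthogonal to the confound
  expect_lt(abs(cor(R[train, 1], C[train, 1])), 0.05)
  # zero-variance column is dropped: identical to regression without it
  R2 <- cvcr_residualize(X, C[, 1:2], train)
  expect_equal(R, R2, tolerance = 1e-9)
})

test_that("decoder held-out r is invariant to channel scaling and near
           zero for pure noise", {
  set.seed(2)
  s <- tiny_session(formal = 6, seed = 3)
  fwd <- forward_model(n_locations = 3, srate = 120, epoch = c(-0.1, 6.3),
                       amp_p = 0, amp_u = 0, seed = 4)
  rec <- simulate_recording(s, fwd, seed = 5)
  lags <- seq(0, 0.4, by = 4 / 120)
  d1 <- timeresolved_decode(rec, s, "u", lags_s = lags, n_pca = 6)
  rec2 <- rec
  rec2$data <- rec2$data * 3.7
  d2 <- timeresolved_decode(rec2, s, "u", lags_s = lags, n_pca = 6)
  expect_equal(d1$r, d2$r, tolerance = 1e-9)
  # noise-only: mean course within the no-signal band
  n_trials <- sum(rec$trial_info$cycle == "P")
  expect_lt(abs(mean(d1$r)), 2 / sqrt(n_trials))
  expect_error(timeresolved_decode(rec, s, "u", numerosity = "none"),
               "at least 3 trials")
})

test_that("with one informative component and vanishing ridge the
           decoder matches closed-form OLS", {
  set.seed(6)
  s <- manual_session(p = runif(40, 0.1, 0.9), N = rep(500, 40))
  # rank-1 two-channel recording: both channels are scalar multiples of
  # the same display-locked signal
  fwd <- forward_model(n_locations = 1, srate = 120, epoch = c(0, 6.8),
                       amp_p = 0, amp_u = 1, noise_sd = 0, pink_sd = 0,
                       seed = 7)
  rec <- simulate_recording(s, fwd)
  rec$data <- rec$data[, 1:2, , drop = FALSE]
  rec$data[, 2, ] <- 2 * rec$data[, 1, ]
  rec$layout <- rec$layout[1:2, ]
  lag0 <- round(0.419 * 120) / 120
  # single trial cannot be cross-validated; replicate the trial with
  # fresh display sequences
  s3 <- manual_session(p = runif(120, 0.1, 0.9), N = rep(500, 120))
  s3$displays$trial <- rep(1:3, each = 40)
  s3$displays$display <- rep(1:40, 3)
  s3$displays$onset_s <- (s3$displays$display - 1) * 0.15
  s3$trials <- tibble::tibble(trial = 1:3, block = 1L, cycle = "P",
                              numerosity = "small", is_catch = FALSE,
                              n_displays = 40L, duration_s = 6)
  rec3 <- simulate_recording(s3, fwd)
  rec3$data <- rec3$data[, 1:2, , drop = FALSE]
  rec3$data[, 2, ] <- 2 * rec3$data[, 1, ]
  rec3$layout <- rec3$layout[1:2, ]
  dec <- timeresolved_decode(rec3, s3, "u", lags_s = lag0, n_pca = 1,
                             ridge = 1e-10)
  # oracle: leave-one-trial-out OLS on the single underlying regressor
  lf <- lag_features(rec3, s3, "u", lags_s = lag0)
  x_all <- lf$features[, 1, 1]
  y_all <- lf$y
  r_oracle <- vapply(1:3, function(tr) {
    te <- lf$trial == tr
    fit <- lm(y ~ x, data = data.frame(x = x_all[!te], y = y_all[!te]))
    pred <- predict(fit, newdata = data.frame(x = x_all[te]))
    cor(pred, y_all[te])
  }, numeric(1))
  expect_equal(dec$r, mean(r_oracle), tolerance = 1e-8)
})

test_that("cluster detection over lags: none, one band, two ordered
           bands", {
  lags <- seq(0, 900, by = 25)
  flat <- matrix(rnorm(8 * length(lags), 0, 1e-3), 8)
  cl0 <- cluster_permutation_time(flat - 1, lags, n_perm = 100, seed = 1)
  expect_equal(nrow(cl0), 0)
  # one strong contiguous band
  band <- matrix(0, 12, length(lags))
  band[, lags >= 300 & lags <= 450] <- 0.4
  r1 <- band + matrix(rnorm(length(band), 0, 0.05), 12)
  cl1 <- cluster_permutation_time(r1, lags, n_perm = 200, seed = 2)
  big <- cl1[cl1$sum_t == max(cl1$sum_t), ]
  expect_lte(big$p, 1 / 100)
  expect_lte(big$start_ms, 325)
  expect_gte(big$end_ms, 425)
  # two bands: the longer/stronger one has the larger summed t
  band2 <- matrix(0, 8, length(lags))
  band2[, lags >= 100 & lags <= 150] <- 0.3
  band2[, lags >= 500 & lags <= 700] <- 0.5
  r2 <- band2 + matrix(rnorm(length(band2), 0, 0.05), 8)
  cl2 <- cluster_permutation_time(r2, lags, n_perm = 100, seed = 3)
  cl2 <- cl2[cl2$p < 0.05, ]
  expect_equal(nrow(cl2), 2)
  expect_gt(cl2$sum_t[cl2$start_ms > 400], cl2$sum_t[cl2$start_ms < 200])
  expect_error(cluster_permutation_time(flat[1, , drop = FALSE], lags),
               "at least 2 subjects")
})

test_that("peak latency is the t-weighted centroid of the largest
           cluster", {
  lags <- seq(0, 900, by = 20)
  # single supra-threshold lag at 300 ms
  tv <- rep(0, length(lags))
  tv[lags == 300] <- 5
  expect_equal(estimate_peak_latency(tv, lags, threshold = 2), 300)
  # symmetric profile centered at 400 ms
  tv2 <- 5 * exp(-((lags - 400) / 80)^2)
  expect_equal(estimate_peak_latency(tv2, lags, threshold = 1), 400,
               tolerance = 1e-9)
  # nothing in the window: NA
  tv3 <- rep(0, length(lags))
  tv3[lags == 700] <- 5
  expect_true(is.na(estimate_peak_latency(tv3, lags,
                                          window = c(100, 500),
                                          threshold = 2)))
  # matrix input computes group t internally
  r_mat <- matrix(rnorm(6 * length(lags), 0, 0.01), 6)
  r_mat[, lags >= 280 & lags <= 320] <- 0.5
  expect_equal(estimate_peak_latency(r_mat, lags), 300, tolerance = 1)
})

test_that("bootstrap latency differences are shift-equivariant with
           percentile CIs", {
  lat_p <- c(310, 320, 330, 300, 340, 315)
  bt0 <- bootstrap_latency_difference(lat_p, lat_p, n_boot = 200, seed = 1)
  expect_equal(bt0$mean_diff, 0)
  expect_equal(c(bt0$ci_lower, bt0$ci_upper), c(0, 0))
  bt <- bootstrap_latency_difference(lat_p, lat_p + 100, n_boot = 200,
                                     seed = 2)
  expect_equal(bt$mean_diff, 100)
  expect_equal(c(bt$ci_lower, bt$ci_upper), c(100, 100))
  expect_error(bootstrap_latency_difference(1:2, 3:4), "at least 3")
})

test_that("spatial clusters: zero adjacency isolates every location", {
  set.seed(8)
  coords <- sensor_layout(40)
  coords <- unique(coords[, c("location", "x", "y", "z")])
  r_mat <- matrix(0.3, 6, 40) + matrix(rnorm(240, 0, 0.05), 6)
  cl <- cluster_permutation_space(r_mat, as.matrix(coords[, c("x", "y",
                                                              "z")]),
                                  adjacency_m = 0, n_perm = 100, seed = 9)
  expect_true(all(lengths(cl$locations) == 1))
  # with realistic adjacency the supra-threshold locations merge
  cl2 <- cluster_permutation_space(r_mat, as.matrix(coords[, c("x", "y",
                                                               "z")]),
                                   adjacency_m = 0.06, n_perm = 100,
                                   seed = 10)
  expect_lt(nrow(cl2), 40)
  expect_gt(max(lengths(cl2$locations)), 1)
})
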