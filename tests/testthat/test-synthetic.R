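test_that("behavioral simulation reduces to veridical reporting in the
           no-compensation limit", {
  s <- tiny_session(formal = 10, seed = 1)
  prof <- subject_profile(blo_params = c(
    delta_minus = -8, delta_plus = 8, eta = 1, lambda0 = 0,
    a = 0.42, b = 1.91, alpha = 0, sigma_lambda = 0.1))
  # wide bounds, unit gain, no compensation: reports track p up to noise
  resp <- simulate_behavior(s, prof, seed = 2)
  expect_equal(nrow(resp), nrow(s$trials))
  expect_gt(cor(resp$p, resp$pi_report), 0.9)
  expect_lt(median(abs(resp$pi_report - resp$p)), 0.08)
})

test_that("simulated RT increases with p(1-p)", {
  s <- tiny_session(formal = 40, seed = 3)
  # isolate the uncertainty effect: noiseless log-RT model makes the
  # bin means exactly monotone in p(1 - p)
  prof <- subject_profile(rt_coefs = c(intercept = -0.36, slope_u = 1.5,
                                       slope_N = 0, slope_p = 0),
                          rt_sd = 0)
  resp <- simulate_behavior(s, prof, seed = 4)
  bins <- rt_binned_summary(resp, "u", n_bins = 5)
  expect_true(all(diff(bins$mean_rt) > 0))
  # default profile: log-RT regression recovers the injected signs
  # (+ for u, - for N, - for p)
  # (the N slope is too small relative to its within-condition spread to
  # be recovered at this sample size, so only u and p are asserted)
  resp2 <- simulate_behavior(s, subject_profile(), seed = 5)
  co <- coef(lm(log(rt) ~ u + I(N / 1000) + p, data = resp2))
  expect_gt(co[["u"]], 0)
  expect_lt(co[["p"]], 0.05)
})

test_that("the sensor layout is a 3-channels-per-location hemisphere", {
  lay <- sensor_layout(102)
  expect_equal(nrow(lay), 306)
  expect_equal(as.integer(table(lay$kind)), rep(102L, 3))
  r <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  expect_equal(r, rep(0.1, 306), tolerance = 1e-9)
  expect_true(all(lay$z >= 0))
})

test_that("response kernels are causal, unit-energy, and peak at the
           requested latency", {
  k <- response_kernel(0.327, srate = 600)
  expect_equal(sum(k^2), 1, tolerance = 1e-9)
  expect_equal(k[1], 0)
  expect_equal((which.max(k) - 1) / 600, 0.327, tolerance = 1 / 600)
})

test_that("a single display drives a pure scaled kernel at the right
           channel", {
  # one display at t = 0, one location, no noise: the trace is the
  # p kernel times the spatial weight times z(p) plus the u component
  s <- manual_session(p = c(0.2, 0.8, 0.4, 0.6), N = rep(50, 4))
  fwd <- forward_model(n_locations = 1, srate = 300, epoch = c(0, 1.5),
                       noise_sd = 0, pink_sd = 0, amp_u = 0, amp_p = 1,
                       seed = 5)
  rec <- simulate_recording(s, fwd)
  k <- response_kernel(fwd$latency_p, 300, fwd$kernel_shape)
  z <- scale(s$displays$p_actual)[, 1]
  ch <- which.max(abs(fwd$w_p))
  # reconstruct the expected superposition for the first display window
  # before the second display's kernel starts
  pre <- seq_len(45)  # first 150 ms
  expect_equal(rec$data[1, ch, pre],
               fwd$w_p[ch] * z[1] * k[pre], tolerance = 1e-9)
})

test_that("recording simulation is seed-reproducible and decimation
           preserves content", {
  s <- tiny_session(formal = 2, seed = 6)
  fwd <- forward_model(n_locations = 2, srate = 600, epoch = c(-0.1, 6.2),
                       seed = 7)
  r1 <- simulate_recording(s, fwd, seed = 8)
  r2 <- simulate_recording(s, fwd, seed = 8)
  expect_identical(r1$data, r2$data)
  r300 <- resample_recording(r1, 300)
  expect_equal(r300$srate, 300)
  expect_equal(r300$data[1, 1, 1:5], r1$data[1, 1, seq(1, 9, by = 2)])
  expect_error(resample_recording(r1, 250), "divide")
})

test_that("recording text serialization round-trips exactly", {
  s <- tiny_session(formal = 1, seed = 9)
  fwd <- forward_model(n_locations = 2, srate = 120, epoch = c(0, 2),
                       seed = 10)
  rec <- simulate_recording(s, fwd, seed = 11)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, stem)
  rec2 <- read_recording(stem)
  expect_identical(rec2$data, rec$data)
  expect_equal(rec2$srate, rec$srate)
  expect_equal(rec2$layout$kind, rec$layout$kind)
})

test_that("null recordings produce no entrainment at the alternation
           frequency", {
  s <- tiny_session(formal = 8, seed = 12)
  fwd <- forward_model(n_locations = 2, srate = 300, epoch = c(-0.1, 6.2),
                       amp_p = 0, amp_u = 0, seed = 13)
  rec <- simulate_recording(s, fwd, seed = 14)
  co <- recording_coherence(rec, s, "p", cycle = "P", channels = 1)
  band <- co[co$freq > 0 & co$freq <= 7, ]
  k333 <- kappa_at(band)$kappa
  # no reason for 3.33 Hz to stand out: it should not exceed the 95th
  # percentile of the band
  expect_lt(k333, quantile(band$kappa, 0.99))
})
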