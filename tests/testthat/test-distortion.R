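test_that("scale transforms match closed forms and round-trip", {
  expect_equal(scale_transform(0.5, "log_odds"), 0)
  expect_equal(scale_transform(0.9, "log_odds"), log(9))
  expect_equal(scale_transform(exp(-1), "prelec"), 0)
  expect_equal(scale_transform(0.3, "linear"), 0.3)
  p <- seq(0.001, 0.999, length.out = 200)
  for (sc in c("log_odds", "prelec", "linear")) {
    expect_equal(scale_inverse(scale_transform(p, sc), sc), p,
                 tolerance = 1e-12)
  }
  expect_error(scale_transform(0, "log_odds"), "in \\(0, 1\\)")
  expect_error(scale_transform(1.2, "linear"), "in \\[0, 1\\]")
})

test_that("LLO forward model: identity, crossover, and frozen value", {
  expect_equal(llo_forward(0.3, gamma = 1, p0 = 0.7)$median, 0.3)
  expect_equal(llo_forward(0.4, gamma = 0.6, p0 = 0.4)$median, 0.4)
  # direct evaluation of the distortion equation
  expect_equal(llo_forward(0.1, gamma = 0.6, p0 = 0.5)$median,
               0.21109548, tolerance = 1e-7)
  # monotonicity in p for positive slope
  med <- llo_forward(seq(0.05, 0.95, 0.05), gamma = 0.6, p0 = 0.4)$median
  expect_true(all(diff(med) > 0))
})

test_that("sampling variance: boundary zeros, clamping, frozen value,
           unimodal N profile", {
  expect_equal(sampling_variance(c(0, 1), 20, a = 0.42, b = 1.91),
               c(0, 0))
  # ns >= N is clamped to zero variance
  expect_equal(sampling_variance(0.5, 5, variance = "v_ns_const", ns = 10),
               0)
  expect_equal(sampling_variance(0.5, 20, a = 0.42, b = 1.91),
               0.035313768, tolerance = 1e-7)
  expect_equal(sampling_variance(0.5, 1, a = 0.42, b = 1.91), 0)
  # rises from N = 10 to a maximum near N ~ 20, then falls through 900
  N <- c(10, 15, 20, 50, 100, 300, 900)
  V <- sampling_variance(0.5, N, a = 0.42, b = 1.91)
  expect_gt(max(V[2:3]), V[1])
  expect_true(all(diff(V[3:7]) < 0))
  expect_equal(sampling_variance(0.3, 50, variance = "v_const"), 1)
})

test_that("BLO forward model: compensation-off limit and bound
           truncation", {
  spec_key <- "logodds-bounded-vnspow"
  pars <- c(delta_minus = -1.5, delta_plus = 1.5, eta = 1, lambda0 = 0.8,
            a = 0.42, b = 1.91, alpha = 0, sigma_lambda = 0.3)
  out <- blo_forward(c(0.2, 0.5, 0.8), 50, pars, spec_key)
  # alpha = 0 means omega = 1: the anchor drops out, response is the
  # truncated, centered log-odds
  lo <- log(c(0.2, 0.5, 0.8) / (1 - c(0.2, 0.5, 0.8)))
  expect_equal(out$mean_scale, pmin(pmax(lo, -1.5), 1.5))
  # all p below the lower bound map to one response value
  pars2 <- pars
  pars2["delta_minus"] <- 0.5
  low_p <- c(0.2, 0.4, 0.6)  # log-odds all below 0.5... except 0.6
  ms <- blo_forward(low_p, 50, pars2, spec_key)$mean_scale
  expect_equal(ms[1], ms[2])  # both truncated at delta_minus
  # BLO median response non-decreasing in p
  med <- blo_forward(seq(0.05, 0.95, 0.05), 50,
                     c(delta_minus = -1.9, delta_plus = 1.9, eta = 1,
                       lambda0 = 0, a = 0.42, b = 1.91, alpha = 20,
                       sigma_lambda = 0.3), spec_key)$median
  expect_true(all(diff(med) >= -1e-12))
})

test_that("invalid BLO parameters are rejected", {
  expect_error(blo_forward(0.5, 50,
                           c(delta_minus = 2, delta_plus = -2, eta = 1,
                             lambda0 = 0, a = 0.4, b = 2, alpha = 1,
                             sigma_lambda = 0.3),
                           "logodds-bounded-vnspow"),
               "delta_minus")
  expect_error(blo_forward(0.5, 50, c(eta = 1, sigma_lambda = 0.3),
                           "logodds-bounded-vnspow"),
               "missing parameters")
})

test_that("negative log-likelihood: mode value, scale family, and truth
           beats the identity", {
  # single report exactly at the model mode: Gaussian density at its
  # peak, plus the log-odds change-of-variables term
  pars <- llo_to_registry(0.6, 0.5, 0.4)
  pi_mode <- llo_forward(0.3, 0.6, 0.5)$median
  one <- tibble::tibble(p = 0.3, N = 50, pi_report = pi_mode)
  expect_equal(neg_log_likelihood(one, "logodds-free-vconst", pars),
               log(0.4 * sqrt(2 * pi)) + log(pi_mode * (1 - pi_mode)),
               tolerance = 1e-9)
  # doubling sigma with zero residuals raises NLL by log 2 per trial
  pars2 <- pars
  pars2["sigma_lambda"] <- 0.8
  expect_equal(neg_log_likelihood(one, "logodds-free-vconst", pars2) -
                 neg_log_likelihood(one, "logodds-free-vconst", pars),
               log(2), tolerance = 1e-9)
  expect_error(neg_log_likelihood(one[0, ], "logodds-free-vconst", pars),
               "empty")
  # simulated distorted data: truth likelier than no distortion
  resp <- llo_responses(100, gamma = 0.6, p0 = 0.5, sigma = 0.3, seed = 2)
  nll_truth <- neg_log_likelihood(resp, "logodds-free-vconst",
                                  llo_to_registry(0.6, 0.5, 0.3))
  nll_identity <- neg_log_likelihood(resp, "logodds-free-vconst",
                                     llo_to_registry(1, 0.5, 0.3))
  expect_lt(nll_truth, nll_identity)
})

test_that("kernel smoother: constants, wide-bandwidth limit, two-point
           fixture", {
  x <- runif(30)
  expect_equal(kernel_smooth(c(0.2, 0.5), x, rep(2, 30)), c(2, 2))
  y <- rnorm(30)
  expect_equal(kernel_smooth(c(0.1, 0.9), x, y, h = 1e6),
               rep(mean(y), 2), tolerance = 1e-6)
  # two observations far apart relative to h: the near one dominates
  # totally (weight ratio exp(-200))
  v <- kernel_smooth(0.2, c(0.2, 0.8), c(0, 1), h = 0.03)
  expect_lt(v, 1e-80)
  expect_warning(kernel_smooth(500, c(0, 1), c(0, 1), h = 0.01),
                 "underflowed")
})
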