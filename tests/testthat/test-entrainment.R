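test_that("stimulus step functions hold display values at the sampling
           grid", {
  s <- manual_session(p = rep(0.4, 6), N = rep(20, 6))
  x <- stimulus_timeseries(s$displays, "p", srate = 300)
  expect_equal(length(x), 6 * 45)
  expect_true(all(x == 0.4))
  # 40 displays at 300 Hz: 45 samples per display
  s40 <- manual_session(p = runif(40, 0.1, 0.9), N = rep(50, 40))
  x40 <- stimulus_timeseries(s40$displays, "p", srate = 300)
  expect_equal(length(x40), 1800)
  u40 <- stimulus_timeseries(s40$displays, "u", srate = 300)
  expect_equal(u40, x40 * (1 - x40))
  expect_error(stimulus_timeseries(s$displays, "p", srate = 70),
               "integer number of samples")
})

test_that("phase coherence is bounded, maximal for self-coherence, and
           invariant to delay and scaling", {
  set.seed(1)
  stim <- matrix(rnorm(20 * 300), 20)
  resp <- matrix(rnorm(20 * 300), 20)
  k <- phase_coherence(stim, resp, srate = 300, pad_to = 1024)
  expect_true(all(k$kappa >= 0 & k$kappa <= 1 + 1e-12))
  # response = stimulus: kappa = 1 wherever there is power
  k_self <- phase_coherence(stim, stim, srate = 300, pad_to = 1024)
  expect_true(all(abs(k_self$kappa[k_self$freq > 0 & k_self$freq < 100] -
                        1) < 1e-6))
  # constant delay only shifts phase; kappa at the stimulus frequency is
  # unchanged
  t_grid <- seq(0, 0.995, by = 1 / 200)
  stim2 <- t(replicate(15, sin(2 * pi * 10 * t_grid + runif(1, 0, 2 * pi))))
  lagged <- cbind(stim2[, 6:ncol(stim2)], stim2[, 1:5])
  k_a <- phase_coherence(stim2, stim2, srate = 200, pad_to = 512)
  k_b <- phase_coherence(stim2, lagged, srate = 200, pad_to = 512)
  i10 <- which.min(abs(k_a$freq - 10))
  expect_equal(k_b$kappa[i10], k_a$kappa[i10], tolerance = 0.05)
  # scaling the responses changes nothing
  k_c <- phase_coherence(stim, 7.3 * resp, srate = 300, pad_to = 1024)
  expect_equal(k_c$kappa, k$kappa, tolerance = 1e-12)
  expect_warning(phase_coherence(stim[1, , drop = FALSE],
                                 resp[1, , drop = FALSE],
                                 srate = 300, pad_to = 1024),
                 "single trial")
})

test_that("adding independent noise lowers coherence at the stimulus
           frequency", {
  set.seed(2)
  t_grid <- seq(0, 1.995, by = 1 / 100)
  stim <- t(replicate(25, sin(2 * pi * 5 * t_grid + runif(1, 0, 2 * pi))))
  noisy <- stim + matrix(rnorm(length(stim), 0, 2), nrow(stim))
  i5 <- function(k) k$kappa[which.min(abs(k$freq - 5))]
  expect_lt(i5(phase_coherence(stim, noisy, srate = 100, pad_to = 512)),
            i5(phase_coherence(stim, stim, srate = 100, pad_to = 512)))
})

test_that("the coherence permutation test gives valid p and q values", {
  set.seed(3)
  # a clear entrained signal: p ~ 0 at the stimulus frequency
  t_grid <- seq(0, 1.995, by = 1 / 100)
  stim <- t(replicate(12, sin(2 * pi * 4 * t_grid + runif(1, 0, 2 * pi))))
  resp <- stim + matrix(rnorm(length(stim), 0, 0.5), nrow(stim))
  pt <- coherence_permutation_test(stim, resp, srate = 100, pad_to = 512,
                                   n_perm = 100, f_range = c(0, 10),
                                   seed = 4)
  i4 <- which.min(abs(pt$freq - 4))
  expect_lt(pt$p[i4], 0.05)
  expect_true(all(pt$p >= 1 / 101 & pt$p <= 1))
  # q values agree with a brute-force Benjamini-Hochberg oracle
  m <- nrow(pt)
  ord <- order(pt$p)
  qq <- numeric(m)
  qq[ord] <- rev(cummin(rev(pt$p[ord] * m / seq_len(m))))
  expect_equal(pt$q, pmin(qq, 1), tolerance = 1e-12)
  expect_error(coherence_permutation_test(stim, resp, n_perm = 10),
               ">= 100")
})

test_that("an observed coherence below every null draw gets p = 1", {
  set.seed(5)
  # constant response: zero power, kappa = 0 everywhere observed, while
  # shuffled versions stay 0 too -- ties count, p = 1
  stim <- matrix(rnorm(10 * 200), 10)
  resp <- matrix(1, 10, 200)
  pt <- coherence_permutation_test(stim, resp, srate = 100, pad_to = 512,
                                   n_perm = 100, f_range = c(0, 10),
                                   seed = 6)
  expect_true(all(pt$p == 1))
})

test_that("generated P-cycle p sequences have their 0-7 Hz spectral peak
           at 3.33 Hz and the aperiodic variable does not", {
  set.seed(7)
  sp <- stimulus_spectrum(100, "P", "p")
  band <- sp[sp$freq > 0 & sp$freq <= 7, ]
  expect_equal(band$freq[which.max(band$amplitude)], 10 / 3,
               tolerance = 1e-6)
  prominence <- function(b) {
    b$amplitude[which.min(abs(b$freq - 10 / 3))] / median(b$amplitude)
  }
  expect_gt(prominence(band), 3)
  spu <- stimulus_spectrum(100, "P", "u")
  bu <- spu[spu$freq > 0 & spu$freq <= 7, ]
  expect_lt(prominence(bu), 1.5)
})
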