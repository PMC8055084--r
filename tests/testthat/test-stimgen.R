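test_that("P-cycle p sequences alternate across 0.5 and stay in range", {
  set.seed(1)
  for (i in 1:20) {
    p <- sample_p_sequence("P", 40)
    expect_true(all(p > 0 & p < 1))
    pairs <- cbind(p[-40], p[-1])
    expect_true(all((pairs[, 1] - 0.5) * (pairs[, 2] - 0.5) < 0))
  }
})

test_that("U-cycle sequences alternate p(1-p) across 0.21", {
  set.seed(2)
  for (i in 1:20) {
    p <- sample_p_sequence("U", 40)
    u <- p * (1 - p)
    pairs <- cbind(u[-40], u[-1])
    expect_true(all((pairs[, 1] - 0.21) * (pairs[, 2] - 0.21) < 0))
  }
})

test_that("degenerate single-display P-cycle draw lies in one half-range", {
  set.seed(3)
  p <- replicate(50, sample_p_sequence("P", 1))
  expect_true(all((p > 0.1 & p < 0.5) | (p > 0.5 & p < 0.9)))
})

test_that("non-positive display counts are rejected", {
  expect_error(sample_p_sequence("P", 0), "positive integer")
  expect_error(sample_p_sequence("U", -3), "positive integer")
})

test_that("numerosity draws stay inside the condition ranges", {
  set.seed(4)
  expect_true(all(dplyr::between(sample_numerosity("small", 2000), 10, 90)))
  expect_true(all(dplyr::between(sample_numerosity("large", 2000),
                                 100, 900)))
})

test_that("make_display rounds counts and corrects degenerate roundings", {
  d <- make_display(c(0.5, 0.47, 0.333), c(10, 100, 10))
  expect_equal(d$n_target, c(5L, 47L, 3L))
  expect_equal(d$p_actual, c(0.5, 0.47, 0.3))
  expect_true(all(d$n_target + d$n_other == d$N))
  expect_true(all(abs(d$p_actual - d$p_nominal) <= 0.5 / d$N + 1e-12))
  # p*N rounding to 0 or N is moved one count inward
  dd <- make_display(c(0.02, 0.98), c(10, 10))
  expect_equal(dd$n_target, c(1L, 9L))
  expect_true(all(dd$p_actual > 0 & dd$p_actual < 1))
})

test_that("confounds: AvgLumi constant, Mcontrast matches the palette", {
  d <- compute_confounds(make_display(runif(50, 0.1, 0.9),
                                      sample(10:900, 50)))
  expect_length(unique(d$AvgLumi), 1)
  expect_equal(unique(d$Mcontrast), (43 - 56.5) / (43 + 56.5),
               tolerance = 1e-12)
  expect_equal(d$Nt, d$n_target)
  expect_equal(d$No, d$n_other)
})

test_that("color-variance confounds track numerosity, vCIE_a peaks at an
           interior p", {
  set.seed(5)
  d <- compute_confounds(make_display(runif(400, 0.1, 0.9),
                                      c(sample_numerosity("small", 200),
                                        sample_numerosity("large", 200))))
  expect_gt(abs(cor(d$vCIE_L, d$N)), 0.79)
  expect_gt(abs(cor(d$vCIE_a, d$N)), 0.79)
  expect_gt(abs(cor(d$vCIE_b, d$N)), 0.79)
  pg <- seq(0.05, 0.95, by = 0.01)
  v <- compute_confounds(make_display(pg, 400))$vCIE_a
  expect_gt(pg[which.max(v)], 0.1)
  expect_lt(pg[which.max(v)], 0.95)
  expect_gt(v[pg == 0.5], v[pg == 0.1])
})

test_that("unknown palette keys are rejected", {
  expect_error(compute_confounds(make_display(0.5, 10),
                                 palette = list(orange = c(43, 19, 52))),
               "palette must define")
})

test_that("catch durations follow the calibrated truncated exponential", {
  set.seed(6)
  x <- sample_catch_duration(1e5)
  expect_true(all(x >= 1 & x <= 6))
  expect_equal(mean(x), 3, tolerance = 0.02)
  # truncated mean is monotone in the rate: larger target mean, lower rate
  expect_lt(truncexp_rate(3.4, 1, 6), truncexp_rate(3, 1, 6))
  expect_error(truncexp_rate(7, 1, 6))
  expect_error(truncexp_rate(3.6, 1, 6), "midpoint")
})

test_that("generate_session honors the full design", {
  s <- generate_session("s01", c(formal = 50, catch = 10), blocks = 10,
                        seed = 11)
  expect_equal(nrow(s$trials), 240)
  counts <- dplyr::count(s$trials, .data$cycle, .data$numerosity,
                         .data$is_catch)
  expect_true(all(counts$n[!counts$is_catch] == 50))
  expect_true(all(counts$n[counts$is_catch] == 10))
  expect_true(all(table(s$trials$block) == 24))
  # conditions balanced within block
  per_block <- dplyr::count(s$trials, .data$block, .data$cycle,
                            .data$numerosity)
  expect_true(all(per_block$n == 6))
  # formal trials: 40 or 41 displays, duration 6 or 6.15 s
  f <- s$trials[!s$trials$is_catch, ]
  expect_true(all(f$n_displays %in% c(40L, 41L)))
  expect_true(all(abs(f$duration_s - 6) < 1e-9 |
                    abs(f$duration_s - 6.15) < 1e-9))
  # catch durations within [1, 6], display count covers the duration
  ct <- s$trials[s$trials$is_catch, ]
  expect_true(all(ct$duration_s >= 1 & ct$duration_s <= 6))
  expect_equal(ct$n_displays, as.integer(ceiling(ct$duration_s / 0.15)))
})

test_that("sessions are reproducible from their seed and reject bad
           configs", {
  s1 <- generate_session("x", c(formal = 5, catch = 1), blocks = 2,
                         seed = 7)
  s2 <- generate_session("x", c(formal = 5, catch = 1), blocks = 2,
                         seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_session("x", c(formal = 1, catch = 0), blocks = 1)
  expect_equal(nrow(s3$trials), 4)
  expect_error(generate_session("x", c(formal = 5, catch = 0), blocks = 3),
               "cannot be tiled")
})

test_that("display-wise p and p(1-p), and N and p, are uncorrelated over
           a session", {
  s <- tiny_session(formal = 15, seed = 13)
  d <- s$displays
  expect_gt(nrow(d), 2000)
  u <- d$p_actual * (1 - d$p_actual)
  expect_lt(abs(cor(d$p_actual, u)), 0.1)
  expect_lt(abs(cor(d$N, d$p_actual)), 0.05)
})

test_that("session CSV/JSON round-trip preserves the display table", {
  s <- tiny_session(formal = 2, seed = 3)
  stem <- file.path(withr::local_tempdir(), "sess")
  write_session(s, stem)
  s2 <- read_session(stem)
  expect_equal(s2$subject_id, s$subject_id)
  expect_equal(s2$displays$p_actual, s$displays$p_actual)
  expect_equal(s2$trials$duration_s, s$trials$duration_s)
})
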