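#' Behavioral subject profile
#'
#' Bundles a subject's generative BLO parameters with log-RT regression
#' coefficients. Default RT slopes follow the empirically expected signs:
#' RT increases with the representational uncertainty p(1 - p) and
#' decreases with numerosity and with p.
#'
#' @param blo_params Named BLO parameter vector (defaults: a plausible
#'   mid-range subject).
#' @param model_key Registry key for the generative model.
#' @param rt_coefs Named vector `c(intercept, slope_u, slope_N, slope_p)`
#'   for `log(RT)`; `slope_N` applies to `N / 1000`.
#' @param rt_sd Residual SD of log RT.
#' @return List of class `rf_profile`.
#' @export
subject_profile <- function(blo_params = c(delta_minus = -1.9,
                                           delta_plus = 1.9, eta = 1,
                                           lambda0 = 0, a = 0.42, b = 1.91,
                                           alpha = 10, sigma_lambda = 0.5),
                            model_key = "logodds-bounded-vnspow",
                            rt_coefs = c(intercept = -0.36, slope_u = 1.5,
                                         slope_N = -0.15, slope_p = -0.1),
                            rt_sd = 0.25) {
  check_params(blo_params, model_spec(model_key))
  structure(list(blo_params = blo_params, model_key = model_key,
                 rt_coefs = rt_coefs, rt_sd = rt_sd),
            class = "rf_profile")
}

#' Simulate behavioral reports for a session
#'
#' One row per trial: the reported proportion is a BLO-generative draw for
#' the last display's (p, N); RT follows the profile's log-linear model
#' plus Gaussian noise.
#'
#' @param session An `rf_session`.
#' @param profile An `rf_profile` from [subject_profile()].
#' @param seed Optional integer seed.
#' @return Tibble with `trial`, `cycle`, `numerosity`, `is_catch`, `p`,
#'   `N`, `u` (p(1-p)), `pi_report`, `rt`.
#' @export
simulate_behavior <- function(session, profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  last <- session$displays |>
    dplyr::group_by(.data$trial) |>
    dplyr::slice_max(.data$display, n = 1) |>
    dplyr::ungroup()
  p <- last$p_actual
  N <- last$N
  pi_report <- blo_sample(p, N, profile$blo_params, profile$model_key)
  co <- profile$rt_coefs
  u <- p * (1 - p)
  log_rt <- co[["intercept"]] + co[["slope_u"]] * u +
    co[["slope_N"]] * (N / 1000) + co[["slope_p"]] * p +
    rnorm(length(p), 0, profile$rt_sd)
  tibble::tibble(trial = last$trial, cycle = last$cycle,
                 numerosity = last$numerosity, is_catch = last$is_catch,
                 p = p, N = N, u = u, pi_report = pi_report,
                 rt = exp(log_rt))
}

#' Hemispherical sensor layout
#'
#' A synthetic stand-in for a real 306-channel sensor geometry (which is
#' not part of the package): `n_locations` points on the upper unit
#' hemisphere by the Fibonacci spiral, scaled to a 10 cm head radius, with
#' three channels per location (one magnetometer, two orthogonal planar
#' gradiometers).
#'
#' @param n_locations Number of sensor locations (default 102).
#' @param head_radius_m Head radius in meters (default 0.1).
#' @return Tibble with `channel`, `location`, `kind`
#'   (`"mag"`, `"grad1"`, `"grad2"`), `x`, `y`, `z` (meters).
#' @export
sensor_layout <- function(n_locations = 102, head_radius_m = 0.1) {
  i <- seq_len(n_locations)
  z <- (i - 0.5) / n_locations          # upper hemisphere, uniform in z
  phi <- i * pi * (3 - sqrt(5))         # golden angle
  r <- sqrt(pmax(1 - z^2, 0))
  loc <- tibble::tibble(location = i,
                        x = head_radius_m * r * cos(phi),
                        y = head_radius_m * r * sin(phi),
                        z = head_radius_m * z)
  tidyr::expand_grid(loc, kind = c("mag", "grad1", "grad2")) |>
    dplyr::arrange(.data$location) |>
    dplyr::mutate(channel = dplyr::row_number(), .before = 1)
}

#' Unit-energy gamma-shaped response kernel
#'
#' `g(t) ~ t^shape * exp(-t / theta)` with `theta = peak_s / shape`, so the
#' kernel peaks at `peak_s`; it is causal, supported on `[0, support_s]`,
#' and normalized to unit energy.
#'
#' @param peak_s Peak latency in seconds.
#' @param srate Sampling rate (Hz).
#' @param shape Gamma shape exponent (default 6; larger = narrower bump).
#' @param support_s Kernel support in seconds (default 0.9).
#' @return Numeric vector of kernel samples.
#' @export
response_kernel <- function(peak_s, srate, shape = 6, support_s = 0.9) {
  t <- seq(0, support_s, by = 1 / srate)
  g <- t^shape * exp(-t / (peak_s / shape))
  g / sqrt(sum(g^2))
}

# smooth spatial weight map: Gaussian falloff from a center on the
# hemisphere, with per-channel-kind gain and multiplicative jitter
spatial_map <- function(layout, center, sigma_m = 0.05, jitter_sd = 0.2) {
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2 +
    (layout$z - center[3])^2
  gain <- c(mag = 1, grad1 = 0.7, grad2 = 0.7)[layout$kind]
  w <- exp(-d2 / (2 * sigma_m^2)) * gain
  w * exp(rnorm(length(w), 0, jitter_sd))
}

#' Sensor-array forward model for recording simulation
#'
#' Defines how the display-wise stimulus variables are expressed in the
#' simulated sensor signals: smooth spatial weight maps for p, p(1 - p),
#' and a confound component (concentrated over parietal-occipital
#' locations by default), causal gamma-shaped temporal kernels with
#' configurable peak latencies (defaults 0.327 s for p and 0.419 s for
#' p(1 - p)), and a white + 1/f noise model. Amplitudes may be given as a
#' single number or as `c(small = , large = )` to differ between
#' numerosity conditions.
#'
#' @param n_locations Sensor locations (3 channels each).
#' @param srate Sampling rate in Hz. The default 600 divides evenly into
#'   the 300 Hz coherence and 120 Hz decoding analysis rates.
#' @param epoch Epoch limits in seconds relative to trial onset.
#' @param latency_p,latency_u Kernel peak latencies (s).
#' @param amp_p,amp_u,amp_conf Component amplitudes (scalar or per
#'   numerosity condition).
#' @param confound_var Which confound drives the confound component.
#' @param noise_sd White noise SD; `pink_sd` the 1/f component SD.
#' @param kernel_shape Gamma shape of the response kernels.
#' @param seed Seed for the (fixed) spatial weight maps.
#' @return List of class `rf_forward`.
#' @export
forward_model <- function(n_locations = 102, srate = 600,
                          epoch = c(-0.6, 7),
                          latency_p = 0.327, latency_u = 0.419,
                          amp_p = 2, amp_u = 2, amp_conf = 0,
                          confound_var = "N",
                          noise_sd = 0.3, pink_sd = 0.3,
                          kernel_shape = 6, seed = 1) {
  layout <- sensor_layout(n_locations)
  old <- .Random.seed_safe()
  set.seed(seed)
  # parietal-occipital centers (posterior = negative y), slightly offset
  # for the two variables
  w_p <- spatial_map(layout, c(0.00, -0.07, 0.06))
  w_u <- spatial_map(layout, c(0.02, -0.06, 0.07))
  w_conf <- spatial_map(layout, c(-0.02, -0.05, 0.08))
  .Random.seed_restore(old)
  structure(
    list(layout = layout, srate = srate, epoch = epoch,
         latency_p = latency_p, latency_u = latency_u,
         kernel_shape = kernel_shape,
         w_p = w_p, w_u = w_u, w_conf = w_conf,
         amp_p = amp_p, amp_u = amp_u, amp_conf = amp_conf,
         confound_var = confound_var,
         noise_sd = noise_sd, pink_sd = pink_sd, seed = seed),
    class = "rf_forward"
  )
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# per-condition amplitude lookup
cond_amp <- function(amp, numerosity) {
  if (length(amp) == 1) return(rep(unname(amp), length(numerosity)))
  unname(amp[numerosity])
}

# 1/f-amplitude noise via FFT shaping of white noise, scaled to unit SD
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirror for negative frequencies
  X <- X / sqrt(f)
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sd(y)
}

#' Simulate a sensor-array recording for a session
#'
#' Each channel's trace is the linear superposition, over the trial's
#' displays, of the p kernel scaled by the standardized p value, the
#' p(1 - p) kernel scaled by the standardized p(1 - p) value, and
#' (optionally) a confound kernel scaled by the standardized confound,
#' each weighted by the channel's spatial map, plus white and 1/f noise.
#' Standardization (z) is across all included displays of the session.
#'
#' @param session An `rf_session`.
#' @param forward An `rf_forward` from [forward_model()].
#' @param trials Which trials to simulate: `"formal"` (default) or
#'   `"all"`.
#' @param encode_confounds Logical; include the confound-driven component
#'   (requires `forward$amp_conf != 0` to have an effect).
#' @param seed Optional integer seed for noise.
#' @return Object of class `rf_recording`: list with `data` (array
#'   trials x channels x samples), `srate`, `epoch`, `layout`,
#'   `trial_info` (tibble mapping array rows to session trials).
#' @export
simulate_recording <- function(session, forward, trials = c("formal", "all"),
                               encode_confounds = FALSE, seed = NULL) {
  trials <- match.arg(trials)
  if (!is.null(seed)) set.seed(seed)
  tr <- session$trials
  if (trials == "formal") tr <- tr[!tr$is_catch, ]
  n_trials <- nrow(tr)
  srate <- forward$srate
  t_grid <- seq(forward$epoch[1], forward$epoch[2], by = 1 / srate)
  n_samp <- length(t_grid)
  n_chan <- nrow(forward$layout)

  disp <- session$displays[session$displays$trial %in% tr$trial, ]
  z <- function(x) if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
  disp$z_p <- z(disp$p_actual)
  disp$z_u <- z(disp$p_actual * (1 - disp$p_actual))
  if (encode_confounds) {
    cv <- disp[[forward$confound_var]]
    if (is.null(cv)) stop("unknown confound variable: ",
                          forward$confound_var, call. = FALSE)
    disp$z_c <- z(cv)
  }

  k_p <- response_kernel(forward$latency_p, srate, forward$kernel_shape)
  k_u <- response_kernel(forward$latency_u, srate, forward$kernel_shape)
  k_c <- k_p  # confound component shares the early kernel

  data <- array(0, dim = c(n_trials, n_chan, n_samp))
  onset0 <- forward$epoch[1]
  for (i in seq_len(n_trials)) {
    tri <- tr$trial[i]
    d <- disp[disp$trial == tri, ]
    # displays whose onset falls outside the epoch contribute nothing
    d <- d[d$onset_s >= onset0 & d$onset_s <= forward$epoch[2], ]
    idx <- round((d$onset_s - onset0) * srate) + 1
    idx <- pmin(idx, n_samp)
    imp_p <- imp_u <- imp_c <- numeric(n_samp)
    imp_p[idx] <- d$z_p
    imp_u[idx] <- d$z_u
    if (encode_confounds) imp_c[idx] <- d$z_c
    a_p <- cond_amp(forward$amp_p, tr$numerosity[i])
    a_u <- cond_amp(forward$amp_u, tr$numerosity[i])
    sig_p <- conv_causal(imp_p, k_p) * a_p
    sig_u <- conv_causal(imp_u, k_u) * a_u
    M <- outer(forward$w_p, sig_p) + outer(forward$w_u, sig_u)
    if (encode_confounds) {
      a_c <- cond_amp(forward$amp_conf, tr$numerosity[i])
      M <- M + outer(forward$w_conf, conv_causal(imp_c, k_c) * a_c)
    }
    if (forward$noise_sd > 0) {
      M <- M + matrix(rnorm(n_chan * n_samp, 0, forward$noise_sd),
                      n_chan, n_samp)
    }
    if (forward$pink_sd > 0) {
      for (ch in seq_len(n_chan)) {
        M[ch, ] <- M[ch, ] + forward$pink_sd * pink_noise(n_samp)
      }
    }
    data[i, , ] <- M
  }
  structure(
    list(data = data, srate = srate, epoch = forward$epoch,
         layout = forward$layout,
         trial_info = tibble::tibble(row = seq_len(n_trials),
                                     trial = tr$trial,
                                     cycle = tr$cycle,
                                     numerosity = tr$numerosity)),
    class = "rf_recording"
  )
}

# causal FFT convolution truncated to the signal length
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  L <- stats::nextn(n + m - 1, 2)
  y <- Re(fft(fft(c(x, numeric(L - n))) * fft(c(k, numeric(L - m))),
              inverse = TRUE)) / L
  y[seq_len(n)]
}

#' @export
print.rf_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<rf_recording> %d trials x %d channels x %d samples @ %g Hz (%g..%g s)\n",
    d[1], d[2], d[3], x$srate, x$epoch[1], x$epoch[2]))
  invisible(x)
}

#' Decimate a recording to a lower sampling rate
#'
#' Keeps every `srate / srate_out`-th sample (the factor must be an
#' integer). The simulated signal content lies far below the new Nyquist
#' frequency, so plain decimation is used.
#'
#' @param recording An `rf_recording`.
#' @param srate_out Target rate (Hz), an integer divisor of the current
#'   rate.
#' @return A decimated `rf_recording`.
#' @export
resample_recording <- function(recording, srate_out) {
  fac <- recording$srate / srate_out
  if (abs(fac - round(fac)) > 1e-9) {
    stop("srate_out must divide the recording's sampling rate",
         call. = FALSE)
  }
  fac <- round(fac)
  if (fac == 1) return(recording)
  idx <- seq(1, dim(recording$data)[3], by = fac)
  recording$data <- recording$data[, , idx, drop = FALSE]
  recording$srate <- srate_out
  recording
}

#' Serialize a recording to CSV + JSON (text, lossless)
#'
#' Writes `<stem>_data.csv` (long: row, channel columns, per sample) and
#' `<stem>_meta.json`. Doubles are written with 17 significant digits, so
#' the round-trip through [read_recording()] is exact.
#'
#' @param recording An `rf_recording`.
#' @param stem Output path stem.
#' @return Invisibly, the file paths.
#' @export
write_recording <- function(recording, stem) {
  d <- dim(recording$data)
  flat <- matrix(aperm(recording$data, c(3, 2, 1)), ncol = 1)
  con <- file(paste0(stem, "_data.csv"), "w")
  writeLines("value", con)
  writeLines(sprintf("%.17g", flat), con)
  close(con)
  jsonlite::write_json(
    list(dim = d, srate = recording$srate, epoch = recording$epoch,
         layout = recording$layout, trial_info = recording$trial_info),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(stem, c("_data.csv", "_meta.json")))
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  vals <- utils::read.csv(paste0(stem, "_data.csv"))$value
  d <- meta$dim
  data <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  structure(
    list(data = data, srate = meta$srate, epoch = meta$epoch,
         layout = tibble::as_tibble(meta$layout),
         trial_info = tibble::as_tibble(meta$trial_info)),
    class = "rf_recording"
  )
}
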