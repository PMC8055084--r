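#' Display-wise stimulus step function
#'
#' Holds each display's p (or p(1 - p)) constant for its 150 ms duration,
#' sampled at `srate`; the sampling rate must make the per-display sample
#' count an integer (e.g. 45 samples at 300 Hz).
#'
#' @param displays Tibble of one trial's displays (columns `p_actual`,
#'   `onset_s`), in display order.
#' @param variable `"p"` or `"u"` (for p(1 - p)).
#' @param srate Sampling rate in Hz (default 300).
#' @param n_samples Optional output length: the series is truncated or
#'   zero-padded to this many samples.
#' @return Numeric step-function vector starting at the first display
#'   onset.
#' @export
stimulus_timeseries <- function(displays, variable = c("p", "u"),
                                srate = 300, n_samples = NULL) {
  variable <- match.arg(variable)
  spd <- DISPLAY_DURATION_S * srate
  if (abs(spd - round(spd)) > 1e-9) {
    stop("srate must give an integer number of samples per display",
         call. = FALSE)
  }
  v <- displays$p_actual
  if (variable == "u") v <- v * (1 - v)
  out <- rep(v, each = round(spd))
  if (!is.null(n_samples)) {
    if (length(out) >= n_samples) out <- out[seq_len(n_samples)]
    else out <- c(out, numeric(n_samples - length(out)))
  }
  out
}

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Average amplitude spectrum of generated stimulus sequences
#'
#' Samples `n_trials` fresh alternating p sequences, builds each trial's
#' step-function time series, and averages the FFT amplitude spectra of
#' the demeaned series -- the design diagnostic showing that p (in
#' P-cycle trials) or p(1 - p) (in U-cycle trials) carries a spectral
#' peak at the 3.33 Hz alternation frequency while the other variable
#' does not.
#'
#' @param n_trials Number of trials averaged (default 100).
#' @param cycle `"P"` or `"U"`.
#' @param variable `"p"` or `"u"`: which variable's step function to
#'   analyze.
#' @param n_displays Displays per trial (default 40).
#' @param srate Sampling rate of the step function (default 300 Hz).
#' @return Tibble with `freq` (Hz) and `amplitude` (mean |FFT|), up to
#'   the Nyquist frequency.
#' @export
stimulus_spectrum <- function(n_trials = 100, cycle = c("P", "U"),
                              variable = c("p", "u"), n_displays = 40,
                              srate = 300) {
  cycle <- match.arg(cycle)
  variable <- match.arg(variable)
  spd <- round(DISPLAY_DURATION_S * srate)
  n <- n_displays * spd
  amp <- numeric(n)
  for (i in seq_len(n_trials)) {
    p <- as.numeric(sample_p_sequence(cycle, n_displays))
    v <- if (variable == "u") p * (1 - p) else p
    x <- rep(v, each = spd)
    amp <- amp + Mod(fft(x - mean(x)))
  }
  freq <- (seq_len(n) - 1) * srate / n
  keep <- freq <= srate / 2
  tibble::tibble(freq = freq[keep], amplitude = amp[keep] / n_trials)
}

#' Cross-trial phase coherence between stimulus and response
#'
#' For trial-wise stimulus and response series,
#' `kappa(f) = |mean cross-spectrum| / sqrt(mean stim power * mean resp
#' power)`, which lies in `[0, 1]` by the Cauchy-Schwarz inequality and is
#' 1 when the response is a (lagged, scaled) copy of the stimulus on every
#' trial. Each trial is demeaned, Hanning-windowed, and zero-padded to
#' `pad_to` samples (10000 at 300 Hz gives the 0.03 Hz frequency
#' resolution).
#'
#' @param stim,resp Numeric matrices, trials x samples, of equal shape.
#' @param srate Sampling rate (Hz).
#' @param pad_to FFT length after zero padding.
#' @param f_max Highest frequency returned (default the Nyquist).
#' @return Tibble with `freq` (Hz) and `kappa`.
#' @export
phase_coherence <- function(stim, resp, srate = 300, pad_to = 10000,
                            f_max = NULL) {
  stopifnot(is.matrix(stim), is.matrix(resp), all(dim(stim) == dim(resp)))
  n_trials <- nrow(stim)
  n <- ncol(stim)
  if (pad_to < n) stop("pad_to must be >= the series length", call. = FALSE)
  if (n_trials == 1) {
    warning("single trial: kappa is identically 1 wherever power is nonzero",
            call. = FALSE)
  }
  w <- hanning_window(n)
  prep <- function(M) {
    M <- M - rowMeans(M)
    M <- sweep(M, 2, w, "*")
    cbind(M, matrix(0, n_trials, pad_to - n))
  }
  S <- t(apply(prep(stim), 1, fft))
  R <- t(apply(prep(resp), 1, fft))
  if (n_trials == 1) { S <- matrix(S, 1); R <- matrix(R, 1) }
  cross <- colMeans(Conj(S) * R)
  pss <- colMeans(Mod(S)^2)
  prr <- colMeans(Mod(R)^2)
  kappa <- Mod(cross) / sqrt(pss * prr)
  kappa[pss * prr == 0] <- 0
  freq <- (seq_len(pad_to) - 1) * srate / pad_to
  keep <- freq <= (if (is.null(f_max)) srate / 2 else f_max)
  tibble::tibble(freq = freq[keep], kappa = kappa[keep])
}

#' Permutation test for phase coherence
#'
#' The null distribution shuffles the response time series across time
#' points within each trial (destroying phase alignment while preserving
#' the amplitude distribution), recomputes kappa `n_perm` times, and
#' assigns `p = (1 + #\{null >= observed\}) / (1 + n_perm)` per frequency,
#' with Benjamini-Hochberg FDR across the frequencies in `f_range`.
#'
#' @inheritParams phase_coherence
#' @param n_perm Number of permutations (>= 100; default 500).
#' @param f_range Frequency band tested (default 0-7 Hz).
#' @param seed Optional integer seed.
#' @return Tibble with `freq`, `kappa`, `p`, `q`.
#' @export
coherence_permutation_test <- function(stim, resp, srate = 300,
                                       pad_to = 10000, n_perm = 500,
                                       f_range = c(0, 7), seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- phase_coherence(stim, resp, srate, pad_to, f_max = f_range[2])
  keep <- obs$freq >= f_range[1] & obs$freq <= f_range[2]
  obs <- obs[keep, ]
  n <- ncol(stim)
  exceed <- numeric(nrow(obs))
  for (b in seq_len(n_perm)) {
    resp_sh <- t(apply(resp, 1, sample))
    k_null <- phase_coherence(stim, resp_sh, srate, pad_to,
                              f_max = f_range[2])$kappa[keep]
    exceed <- exceed + (k_null >= obs$kappa)
  }
  obs$p <- (1 + exceed) / (1 + n_perm)
  obs$q <- p.adjust(obs$p, method = "BH")
  obs
}

#' Per-channel coherence between a session variable and a recording
#'
#' Convenience wrapper: selects the formal trials of one cycle condition
#' (optionally one numerosity condition), builds the stimulus step
#' functions from the displays actually shown, decimates the recording to
#' `srate_out`, and computes the phase-coherence spectrum for each
#' requested channel.
#'
#' @param recording An `rf_recording`.
#' @param session The matching `rf_session`.
#' @param variable `"p"` or `"u"`.
#' @param cycle `"P"` or `"U"`; defaults to the cycle in which the
#'   variable is periodic.
#' @param numerosity Optional `"small"`/`"large"` filter.
#' @param channels Channel indices (default: all).
#' @param srate_out Analysis rate (default 300 Hz).
#' @param t_range Within-trial window in seconds (default `c(0, 6)`: the
#'   displays common to 40- and 41-display trials).
#' @param pad_to FFT length (default 10000: 0.03 Hz resolution at 300 Hz).
#' @return Tibble with `channel`, `freq`, `kappa`.
#' @export
recording_coherence <- function(recording, session, variable = c("p", "u"),
                                cycle = NULL, numerosity = NULL,
                                channels = NULL, srate_out = 300,
                                t_range = c(0, 6), pad_to = 10000) {
  variable <- match.arg(variable)
  if (is.null(cycle)) cycle <- if (variable == "p") "P" else "U"
  rec <- resample_recording(recording, srate_out)
  info <- rec$trial_info
  sel <- info$cycle == cycle
  if (!is.null(numerosity)) sel <- sel & info$numerosity == numerosity
  rows <- info$row[sel]
  if (length(rows) == 0) stop("no matching trials", call. = FALSE)
  if (is.null(channels)) channels <- seq_len(dim(rec$data)[2])

  n_samp <- round((t_range[2] - t_range[1]) * srate_out)
  s0 <- round((t_range[1] - rec$epoch[1]) * srate_out) + 1
  stim <- t(vapply(info$trial[sel], function(tri) {
    d <- session$displays[session$displays$trial == tri, ]
    d <- d[d$onset_s >= t_range[1] & d$onset_s < t_range[2], ]
    stimulus_timeseries(d, variable, srate_out, n_samples = n_samp)
  }, numeric(n_samp)))

  purrr::map_dfr(channels, function(ch) {
    resp <- rec$data[rows, ch, s0:(s0 + n_samp - 1), drop = FALSE]
    resp <- matrix(resp, nrow = length(rows))
    k <- phase_coherence(stim, resp, srate_out, pad_to, f_max = srate_out / 2)
    k$channel <- ch
    k[, c("channel", "freq", "kappa")]
  })
}

#' Read kappa off a coherence spectrum at a target frequency
#'
#' @param spectrum Tibble with `freq` and `kappa` (optionally `channel`).
#' @param f Target frequency (default 10/3 Hz, the alternation rate).
#' @return For ungrouped input, a scalar; with a `channel` column, a
#'   tibble of per-channel values at the nearest frequency bin.
#' @export
kappa_at <- function(spectrum, f = 10 / 3) {
  if ("channel" %in% names(spectrum)) {
    spectrum |>
      dplyr::group_by(.data$channel) |>
      dplyr::slice_min(abs(.data$freq - f), n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("channel", "kappa")
  } else {
    spectrum$kappa[which.min(abs(spectrum$freq - f))]
  }
}
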