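#' Relative neural encoding strength of p versus p(1 - p)
#'
#' `beta = kappa_p / kappa_u`: the ratio of the phase coherence for p (in
#' P-cycle trials) to that for p(1 - p) (in U-cycle trials). Scale-free:
#' multiplying both coherences by a constant leaves beta unchanged. A
#' larger beta means relatively stronger encoding of relative frequency
#' than of its uncertainty.
#'
#' @param kappa_p,kappa_u Positive coherence values (vectors recycle).
#' @return Numeric vector; `NA` (with a warning) where `kappa_u` is 0.
#' @export
compute_beta <- function(kappa_p, kappa_u) {
  if (any(kappa_p < 0 | kappa_u < 0, na.rm = TRUE)) {
    stop("coherences must be non-negative", call. = FALSE)
  }
  out <- kappa_p / kappa_u
  bad <- kappa_u == 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " value(s) undefined (kappa_u = 0); returned as NA",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Across-subject correlation between behavioral and neural condition
#' effects
#'
#' For each channel, correlates `delta_gamma = ln(gamma_large /
#' gamma_small)` (behavioral slope change across numerosity conditions)
#' with `delta_beta = ln(beta_large / beta_small)` (neural relative-
#' strength change) across subjects: Pearson r, one-tailed p for r > 0
#' (the direction predicted by uncertainty compensation), and
#' Benjamini-Hochberg q across channels. Incomplete subject rows are
#' dropped pairwise, with the count reported.
#'
#' @param link_tbl Tibble with columns `subject`, `channel`,
#'   `delta_gamma`, `delta_beta`.
#' @return Tibble with `channel`, `n`, `r`, `p`, `q`.
#' @export
link_correlation <- function(link_tbl) {
  stopifnot(all(c("subject", "channel", "delta_gamma", "delta_beta") %in%
                  names(link_tbl)))
  out <- link_tbl |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n = sum(complete.cases(.data$delta_gamma, .data$delta_beta)),
      r = {
        ok <- complete.cases(.data$delta_gamma, .data$delta_beta)
        if (sum(ok) < 5) NA_real_
        else cor(.data$delta_gamma[ok], .data$delta_beta[ok])
      },
      .groups = "drop"
    )
  if (any(out$n < 5)) {
    warning("channels with fewer than 5 complete subjects return NA",
            call. = FALSE)
  }
  tval <- out$r * sqrt((out$n - 2) / (1 - out$r^2))
  out$p <- pt(tval, df = out$n - 2, lower.tail = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Equal-count binned summary of RT against p or p(1 - p)
#'
#' Divides trials evenly into `n_bins` by the value of the chosen
#' variable and reports the per-bin mean of the variable and of RT
#' (reaction time, seconds).
#'
#' @param responses Tibble with columns `p` (and `u` if
#'   `variable = "u"`) and `rt`.
#' @param variable `"p"` or `"u"`.
#' @param n_bins Number of equal-count bins (default 5).
#' @return Tibble with `bin`, `mean_value`, `mean_rt`, `n`.
#' @export
rt_binned_summary <- function(responses, variable = c("p", "u"),
                              n_bins = 5) {
  variable <- match.arg(variable)
  if (!"rt" %in% names(responses)) stop("responses need an `rt` column",
                                        call. = FALSE)
  if (nrow(responses) < n_bins) {
    stop("fewer trials than bins", call. = FALSE)
  }
  v <- if (variable == "u") {
    if ("u" %in% names(responses)) responses$u
    else responses$p * (1 - responses$p)
  } else responses$p
  tibble::tibble(value = v, rt = responses$rt) |>
    dplyr::mutate(bin = dplyr::ntile(.data$value, n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     mean_rt = mean(.data$rt), n = dplyr::n(),
                     .groups = "drop")
}

#' Per-subject, per-condition link measures
#'
#' Computes, for one subject, the LLO slope per numerosity condition
#' (cycles collapsed, as cycle has no effect on the slope) and, per
#' channel, the coherence ratio beta per condition, returning the
#' condition log-ratios used by [link_correlation()].
#'
#' @param responses The subject's behavioral table (formal trials).
#' @param recording The subject's `rf_recording`.
#' @param session The subject's `rf_session`.
#' @param channels Channel indices entering the per-channel beta
#'   (default: all magnetometers).
#' @param n_restarts Restarts for the LLO fits.
#' @param srate_out,pad_to Coherence settings.
#' @return Tibble with `channel`, `delta_gamma`, `delta_beta` plus the
#'   per-condition components.
#' @export
subject_link_measures <- function(responses, recording, session,
                                  channels = NULL, n_restarts = 10,
                                  srate_out = 300, pad_to = 10000) {
  if (is.null(channels)) {
    channels <- recording$layout$channel[recording$layout$kind == "mag"]
  }
  gam <- vapply(c("small", "large"), function(nc) {
    resp <- responses[responses$numerosity == nc & !responses$is_catch, ]
    fit <- fit_model(resp, "logodds-free-vconst", n_restarts = n_restarts)
    unname(fit$params["eta"])
  }, numeric(1))
  kap <- purrr::map_dfr(c("small", "large"), function(nc) {
    kp <- recording_coherence(recording, session, "p", cycle = "P",
                              numerosity = nc, channels = channels,
                              srate_out = srate_out, pad_to = pad_to) |>
      kappa_at()
    ku <- recording_coherence(recording, session, "u", cycle = "U",
                              numerosity = nc, channels = channels,
                              srate_out = srate_out, pad_to = pad_to) |>
      kappa_at()
    tibble::tibble(numerosity = nc, channel = kp$channel,
                   kappa_p = kp$kappa, kappa_u = ku$kappa)
  })
  kap$beta <- compute_beta(kap$kappa_p, kap$kappa_u)
  wide <- tidyr::pivot_wider(kap[, c("numerosity", "channel", "beta")],
                             names_from = "numerosity",
                             values_from = "beta")
  tibble::tibble(
    channel = wide$channel,
    gamma_small = gam[["small"]], gamma_large = gam[["large"]],
    beta_small = wide$small, beta_large = wide$large,
    delta_gamma = log(gam[["large"]] / gam[["small"]]),
    delta_beta = log(wide$large / wide$small)
  )
}
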