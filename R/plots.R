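#' Plot a fitted distortion curve over the data
#'
#' Draws reported versus objective relative frequency with the fitted
#' model's median-response curve and the identity line.
#'
#' @param object An `rf_fit`.
#' @param responses The response tibble the model was fitted to
#'   (columns `p`, `N`, `pi_report`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_fit <- function(object, responses, ...) {
  grid <- tibble::tibble(
    p = seq(0.02, 0.98, length.out = 200),
    N = round(median(responses$N))
  )
  grid$median <- blo_forward(grid$p, grid$N, object$params,
                             object$model_key)$median
  ggplot2::ggplot(responses, ggplot2::aes(x = .data$p,
                                          y = .data$pi_report)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$median),
                       color = "#b2182b", linewidth = 0.9) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "objective relative frequency p",
                  y = "reported proportion",
                  title = object$model_key) +
    ggplot2::theme_minimal()
}

#' Plot a time-resolved decoding course
#'
#' @param object An `rf_decoding` tibble from [timeresolved_decode()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_decoding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "time lag (ms)", y = "decoding performance (r)",
                  title = paste("decoding:", attr(object, "variable"),
                                if (isTRUE(attr(object, "cvcr")))
                                  "(confounds regressed out)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot a phase-coherence spectrum
#'
#' Marks the 3.33 Hz alternation frequency; with a `channel` column the
#' spectra are averaged across channels.
#'
#' @param spectrum Tibble with `freq`, `kappa` (optionally `channel`).
#' @param f_max Upper frequency limit shown (default 7 Hz).
#' @return A ggplot object.
#' @export
plot_coherence_spectrum <- function(spectrum, f_max = 7) {
  if ("channel" %in% names(spectrum)) {
    spectrum <- spectrum |>
      dplyr::group_by(.data$freq) |>
      dplyr::summarise(kappa = mean(.data$kappa), .groups = "drop")
  }
  spectrum <- spectrum[spectrum$freq <= f_max, ]
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$freq, y = .data$kappa)) +
    ggplot2::geom_vline(xintercept = 10 / 3, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_line(color = "#1b7837") +
    ggplot2::labs(x = "frequency (Hz)", y = expression(kappa)) +
    ggplot2::theme_minimal()
}

#' Plot one trial's p and p(1 - p) step sequences
#'
#' Visualizes the periodicity dissociation: in a P-cycle trial the p
#' steps alternate around 0.5 while p(1 - p) is aperiodic; in a U-cycle
#' trial p(1 - p) alternates around 0.21.
#'
#' @param session An `rf_session`.
#' @param trial Trial number within the session.
#' @return A ggplot object.
#' @export
plot_trial_sequence <- function(session, trial) {
  d <- session$displays[session$displays$trial == trial, ]
  long <- tibble::tibble(
    time = rep(d$onset_s, 2),
    value = c(d$p_actual, d$p_actual * (1 - d$p_actual)),
    variable = rep(c("p", "p(1-p)"), each = nrow(d))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste0("trial ", trial, " (",
                                 d$cycle[1], "-cycle)")) +
    ggplot2::theme_minimal()
}
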