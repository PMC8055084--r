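#' Draw stimuli matching the session design's marginals
#'
#' Last-display stimuli for simulation studies: p uniform on (0.1, 0.9)
#' (the marginal of both cycle rules), numerosity split evenly between the
#' small and large conditions, counts rounded as on screen.
#'
#' @param n_trials Number of trials.
#' @return Tibble with `p` (actual, after rounding), `N`, `cycle`,
#'   `numerosity`.
#' @export
sample_recovery_stimuli <- function(n_trials) {
  numerosity <- sample(rep_len(c("small", "large"), n_trials))
  cycle <- sample(rep_len(c("P", "U"), n_trials))
  N <- integer(n_trials)
  for (lev in c("small", "large")) {
    idx <- which(numerosity == lev)
    N[idx] <- sample_numerosity(lev, length(idx))
  }
  d <- make_display(runif(n_trials, 0.1, 0.9), N)
  tibble::tibble(p = d$p_actual, N = d$N, cycle = cycle,
                 numerosity = numerosity)
}

#' Plausible generating-parameter sampler
#'
#' Draws one parameter vector for a model cell from documented
#' "plausible" ranges (narrower than the fitting boxes of [param_box()],
#' scale-aware so that bounds and anchors land in the scale's useful
#' range). Used as the default generator for [model_recovery()].
#'
#' @param model_key Registry key.
#' @return Named numeric parameter vector valid for the cell.
#' @export
sample_plausible_params <- function(model_key) {
  spec <- model_spec(model_key)
  rng <- switch(spec$scale,
    log_odds = list(delta_minus = c(-3, -0.8), delta_plus = c(0.8, 3),
                    lambda0 = c(-1, 1), sigma_lambda = c(0.2, 0.6)),
    prelec = list(delta_minus = c(-0.7, -0.1), delta_plus = c(0.9, 2),
                  lambda0 = c(-0.3, 1.2), sigma_lambda = c(0.2, 0.6)),
    linear = list(delta_minus = c(0.05, 0.3), delta_plus = c(0.7, 0.95),
                  lambda0 = c(0.3, 0.7), sigma_lambda = c(0.06, 0.2))
  )
  # sample-size law bracketing the reported median subject (a = 0.42,
  # b = 1.91); the alpha range is chosen so the implied slope-of-
  # distortion change across numerosity conditions matches the ~25%
  # empirically observed for such tasks (alpha ~ 70 for the median
  # subject's V)
  common <- list(eta = c(0.5, 1.5), a = c(0.35, 0.5), b = c(1, 3),
                 ns = c(2, 50), alpha = c(40, 100))
  all_rng <- utils::modifyList(common, rng)
  out <- vapply(spec$params, function(nm) {
    r <- all_rng[[nm]]
    runif(1, r[1], r[2])
  }, numeric(1))
  out <- setNames(out, spec$params)
  if (spec$variance != "v_const") {
    # keep the *observed* distortion slope in the human range: the
    # compensation weight omega shrinks the slope by ~1/(1 + alpha*Vbar),
    # so the Thurstone gain scales up by the typical shrinkage
    vbar <- if (spec$variance == "v_ns_power") {
      mean(sampling_variance(0.5, c(15, 120), a = out["a"], b = out["b"]))
    } else {
      mean(sampling_variance(0.5, c(15, 120), variance = "v_ns_const",
                             ns = out["ns"]))
    }
    out["eta"] <- min(out["eta"] * (1 + out["alpha"] * vbar),
                      param_box()["upper", "eta"])
  }
  if (spec$scale == "linear") {
    # keep the mean response inside the click scale: anchor the intercept
    # so eta * p + lambda0 maps (0, 1) near (0, 1)
    out["eta"] <- runif(1, 0.5, 1.2)
    out["lambda0"] <- (1 - out["eta"]) / 2 + runif(1, -0.05, 0.05)
  }
  out
}

#' Model recovery (identifiability) analysis
#'
#' Generates synthetic datasets from each candidate model with plausible
#' parameters, fits every candidate model to each dataset, declares the
#' model with the lowest summed delta-AICc the winner, and tabulates how
#' often each model wins datasets generated by each model. A well-behaved
#' model set is diagonal-dominant.
#'
#' @param model_keys Registry keys to cross (default: all 18).
#' @param n_datasets Synthetic datasets per generating model (default 50).
#' @param n_subjects Virtual subjects per dataset (default 22).
#' @param n_trials Trials per virtual subject (default 200).
#' @param n_restarts Restarts per fit (desk default 5).
#' @param seed Optional integer seed.
#' @param param_sampler Function `(model_key) -> named params` (default
#'   [sample_plausible_params()]).
#' @return List of class `rf_recovery`: `confusion` (fitted x generating
#'   matrix of win proportions, columns summing to 1) and `n_failures`
#'   (fits that errored, excluded).
#' @export
model_recovery <- function(model_keys = model_space()$model_key,
                           n_datasets = 50, n_subjects = 22,
                           n_trials = 200, n_restarts = 5, seed = NULL,
                           param_sampler = sample_plausible_params) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(model_keys)
  wins <- matrix(0, K, K, dimnames = list(fitted = model_keys,
                                          generating = model_keys))
  n_failures <- 0L
  for (gi in seq_len(K)) {
    gen_key <- model_keys[gi]
    for (d in seq_len(n_datasets)) {
      sum_aicc <- setNames(numeric(K), model_keys)
      for (s in seq_len(n_subjects)) {
        pars <- param_sampler(gen_key)
        stim <- sample_recovery_stimuli(n_trials)
        stim$pi_report <- blo_sample(stim$p, stim$N, pars, gen_key)
        for (fi in seq_len(K)) {
          fit <- tryCatch(
            fit_model(stim, model_keys[fi], n_restarts = n_restarts),
            error = function(e) NULL
          )
          if (is.null(fit)) {
            n_failures <- n_failures + 1L
            sum_aicc[fi] <- sum_aicc[fi] + NA_real_
          } else {
            sum_aicc[fi] <- sum_aicc[fi] + fit$aicc
          }
        }
      }
      dA <- sum_aicc - min(sum_aicc, na.rm = TRUE)
      win <- which.min(dA)
      wins[win, gi] <- wins[win, gi] + 1
    }
    wins[, gi] <- wins[, gi] / n_datasets
  }
  structure(list(confusion = wins, n_failures = n_failures),
            class = "rf_recovery")
}

#' @export
print.rf_recovery <- function(x, ...) {
  cat("<rf_recovery> confusion matrix (columns: generating model):\n")
  print(round(x$confusion, 2))
  invisible(x)
}

#' Parameter recovery for a single model
#'
#' Simulates datasets from known parameters, refits the same model, and
#' returns the recovered parameters per replication, for checking that the
#' fitting machinery can identify the generating parameters.
#'
#' @param model_key Registry key.
#' @param true_params Named generating parameter vector.
#' @param n_trials Trials per replication.
#' @param n_replications Number of simulated datasets.
#' @param n_restarts Restarts per fit.
#' @param seed Optional integer seed.
#' @return Tibble with `replication` and one column per parameter
#'   (recovered values); attribute `"true_params"` carries the truth.
#' @export
parameter_recovery <- function(model_key, true_params, n_trials = 200,
                               n_replications = 20, n_restarts = 20,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_replications), function(r) {
    stim <- sample_recovery_stimuli(n_trials)
    stim$pi_report <- blo_sample(stim$p, stim$N, true_params, model_key)
    fit <- fit_model(stim, model_key, n_restarts = n_restarts)
    tibble::as_tibble(c(list(replication = r), as.list(fit$params)))
  })
  attr(rows, "true_params") <- true_params
  rows
}
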