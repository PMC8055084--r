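#' Representation-scale transforms and their inverses
#'
#' Three candidate internal scales for probability: log-odds
#' `log(p / (1 - p))`, the Prelec scale `-log(-log(p))`, and the linear
#' scale (identity). All are strictly increasing on their domain and
#' round-trip with [scale_inverse()].
#'
#' @param p Numeric vector; in (0, 1) for `log_odds` and `prelec`, in
#'   `[0, 1]` for `linear`.
#' @param scale `"log_odds"`, `"prelec"`, or `"linear"`.
#' @return Numeric vector of transformed values.
#' @export
#' @examples
#' scale_transform(0.9, "log_odds")  # log(9)
scale_transform <- function(p, scale = c("log_odds", "prelec", "linear")) {
  scale <- match.arg(scale)
  switch(scale,
    log_odds = {
      if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
      log(p / (1 - p))
    },
    prelec = {
      if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
      -log(-log(p))
    },
    linear = {
      if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
      p
    }
  )
}

#' @rdname scale_transform
#' @param x Numeric vector on the transformed scale.
#' @export
scale_inverse <- function(x, scale = c("log_odds", "prelec", "linear")) {
  scale <- match.arg(scale)
  switch(scale,
    log_odds = 1 / (1 + exp(-x)),
    prelec = exp(-exp(-x)),
    linear = x
  )
}

#' Sampling variance of the internal relative-frequency estimate
#'
#' If an observer bases the estimate on a random sample of `ns` of the `N`
#' elements, drawn without replacement, the estimate's variance is
#' `V = p (1 - p) / ns * (N - ns) / (N - 1)`, clamped at 0 (so `ns >= N`
#' gives 0). Under `"v_ns_power"`, the sample size grows with numerosity as
#' `ns = b + N^a`; under `"v_ns_const"` it is a free constant; under
#' `"v_const"` the variance is the constant 1 (any scaling being absorbed
#' by the compensation weight).
#'
#' @param p Relative frequency in `[0, 1]`.
#' @param N Numerosity (integer >= 1); `N = 1` returns 0 (degenerate
#'   denominator).
#' @param a,b Sample-size law parameters (used by `"v_ns_power"`).
#' @param variance One of `"v_ns_power"`, `"v_ns_const"`, `"v_const"`.
#' @param ns Constant sample size (used by `"v_ns_const"`).
#' @return Numeric vector of variances, >= 0.
#' @export
#' @examples
#' sampling_variance(0.5, 20, a = 0.42, b = 1.91)  # ~0.0353
sampling_variance <- function(p, N, a = NULL, b = NULL,
                              variance = c("v_ns_power", "v_ns_const",
                                           "v_const"),
                              ns = NULL) {
  variance <- match.arg(variance)
  n <- max(length(p), length(N))
  if (variance == "v_const") return(rep(1, n))
  stopifnot(all(N >= 1))
  p <- rep_len(p, n)
  N <- rep_len(N, n)
  n_s <- switch(variance,
    v_ns_power = b + N^a,
    v_ns_const = rep_len(ns, n)
  )
  V <- ifelse(N == 1, 0, p * (1 - p) / n_s * (N - n_s) / (N - 1))
  pmax(V, 0)
}

#' Linear-in-log-odds (LLO) distortion
#'
#' The LLO model maps objective p to a reported proportion whose log-odds
#' is `gamma * lo(p) + (1 - gamma) * lo(p0)` plus Gaussian noise of SD
#' `sigma_lambda` on the log-odds scale, where `lo` is the log-odds
#' transform. `gamma < 1` gives the classic inverted-S distortion
#' (overestimating small p), `gamma = 1` the identity, `gamma > 1` an
#' S-shape; `p0` is the crossover where the median report equals p.
#'
#' @param p Numeric vector in (0, 1).
#' @param gamma Slope of distortion (> 0).
#' @param p0 Crossover point in (0, 1).
#' @param sigma_lambda Log-odds noise SD (> 0); only used by
#'   [llo_sample()].
#' @return `llo_forward()`: tibble with `p`, `mean_logodds`, and `median`
#'   (the median reported proportion). `llo_sample()`: numeric vector of
#'   sampled reports in (0, 1).
#' @export
#' @examples
#' llo_forward(c(0.1, 0.5, 0.9), gamma = 0.6, p0 = 0.5)
llo_forward <- function(p, gamma, p0, sigma_lambda = NULL) {
  stopifnot(gamma > 0, p0 > 0, p0 < 1)
  m <- gamma * scale_transform(p, "log_odds") +
    (1 - gamma) * scale_transform(p0, "log_odds")
  tibble::tibble(p = p, mean_logodds = m,
                 median = scale_inverse(m, "log_odds"))
}

#' @rdname llo_forward
#' @export
llo_sample <- function(p, gamma, p0, sigma_lambda) {
  stopifnot(sigma_lambda > 0)
  m <- llo_forward(p, gamma, p0)$mean_logodds
  scale_inverse(m + rnorm(length(m), 0, sigma_lambda), "log_odds")
}

# Mean response on the representation scale for any model in the factorial
# family. `params` is a named list/vector; `spec` from model_spec().
blo_mean_scale <- function(p, N, params, spec) {
  pr <- as.list(params)
  s <- scale_transform(p, spec$scale)
  if (spec$bounded) {
    dm <- pr$delta_minus; dp <- pr$delta_plus
    G <- pmin(pmax(s, dm), dp)
    Lam <- pr$eta * (G - (dm + dp) / 2)
  } else {
    Lam <- pr$eta * s
  }
  if (spec$variance == "v_const") {
    # compensation weight constant: absorbed into eta; lambda0 acts as a
    # plain intercept, so this cell reduces to LLO / the two-parameter
    # Prelec / neo-additive family on its scale
    Lam + pr$lambda0
  } else {
    V <- sampling_variance(p, N, a = pr$a, b = pr$b,
                           variance = spec$variance, ns = pr$ns)
    w <- 1 / (1 + pr$alpha * V)
    w * Lam + (1 - w) * pr$lambda0
  }
}

#' Bounded log-odds (BLO) family forward model
#'
#' Computes, for each (p, N) pair, the mean response on the model's
#' representation scale and the median reported proportion. The
#' representation `s = scale(p)` is (optionally) truncated to
#' `[delta_minus, delta_plus]` and mapped to a bounded Thurstone scale
#' `Lambda = eta * (Gamma(s) - (delta_minus + delta_plus) / 2)`; the final
#' estimate shrinks `Lambda` toward the anchor `lambda0` with weight
#' `omega = 1 / (1 + alpha * V(p_hat))`, compensating for the sampling
#' variance `V` of the internal estimate (see [sampling_variance()]).
#' Gaussian noise of SD `sigma_lambda` acts on the representation scale.
#'
#' @param p Numeric vector of relative frequencies.
#' @param N Integer vector of numerosities (recycled).
#' @param params Named vector/list of parameters for the cell (see
#'   [model_spec()] for the names each cell uses).
#' @param model_key Registry key, e.g. `"logodds-bounded-vnspow"` (the
#'   8-parameter BLO model).
#' @return `blo_forward()`: tibble with `p`, `N`, `mean_scale`, `median`.
#'   `blo_sample()`: numeric vector of sampled reports.
#' @export
blo_forward <- function(p, N, params, model_key = "logodds-bounded-vnspow") {
  spec <- model_spec(model_key)
  check_params(params, spec)
  m <- blo_mean_scale(p, N, params, spec)
  if (any(!is.finite(m))) stop("non-finite model mean; check parameters",
                               call. = FALSE)
  med <- scale_inverse(m, spec$scale)
  if (spec$scale == "linear") med <- pmin(pmax(med, 0), 1)
  tibble::tibble(p = p, N = rep_len(N, length(p)), mean_scale = m,
                 median = med)
}

#' @rdname blo_forward
#' @export
blo_sample <- function(p, N, params, model_key = "logodds-bounded-vnspow") {
  spec <- model_spec(model_key)
  check_params(params, spec)
  m <- blo_mean_scale(p, N, params, spec)
  r <- scale_inverse(m + rnorm(length(m), 0, as.list(params)$sigma_lambda),
                     spec$scale)
  if (spec$scale == "linear") r <- pmin(pmax(r, 0), 1)
  r
}

check_params <- function(params, spec) {
  pr <- as.list(params)
  missing <- setdiff(spec$params, names(pr))
  if (length(missing) > 0) {
    stop("missing parameters for ", spec$model_key, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(pr[spec$params])
  if (any(!is.finite(vals))) stop("non-finite parameter", call. = FALSE)
  if (spec$bounded && pr$delta_minus > pr$delta_plus) {
    stop("delta_minus must not exceed delta_plus", call. = FALSE)
  }
  invisible(TRUE)
}

# half a step of a 0-100% click scale at ~1% resolution: keeps boundary
# clicks (0 or 1) at finite log-odds / Prelec values
EPS_CLIP <- 1 / 202

#' Negative log-likelihood of reported proportions under a factorial model
#'
#' Reports are transformed to the model's representation scale (clipped to
#' `[1/202, 1 - 1/202]` first for the log-odds and Prelec scales, so
#' boundary clicks stay finite) and evaluated under a Gaussian with the
#' model's mean (see [blo_forward()]) and SD `sigma_lambda`. The returned
#' value is the negative log density of the *observed report*, i.e. it
#' includes the log-Jacobian of the scale transform; within one scale this
#' only shifts the likelihood by a parameter-free constant, but it is what
#' makes AICc comparable across models that place their noise on
#' different scales. On the linear scale a plain Gaussian density on
#' reports is used (Jacobian 1).
#'
#' @param responses Tibble with columns `p`, `N`, `pi_report`.
#' @param model_key Registry key (see [model_space()]).
#' @param params Named parameter vector for the cell.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(responses, model_key, params) {
  if (nrow(responses) == 0) stop("empty response table", call. = FALSE)
  spec <- model_spec(model_key)
  f <- nll_function(responses, model_key)
  f(unlist(as.list(params))[spec$params])
}

# Factory: precomputes transforms once; returns function(par_vector) -> nll
# with a finite penalty for invalid parameter configurations (used by the
# optimizer).
nll_function <- function(responses, model_key) {
  spec <- model_spec(model_key)
  stopifnot(all(c("p", "N", "pi_report") %in% names(responses)))
  p <- responses$p
  N <- responses$N
  pi_rep <- responses$pi_report
  if (spec$scale != "linear") {
    pi_rep <- pmin(pmax(pi_rep, EPS_CLIP), 1 - EPS_CLIP)
  }
  t_pi <- scale_transform(pi_rep, spec$scale)
  # change-of-variables term: -sum log |d transform / d pi|, constant in
  # the parameters
  neg_log_jac <- switch(spec$scale,
    log_odds = sum(log(pi_rep * (1 - pi_rep))),
    prelec = sum(log(pi_rep) + log(-log(pi_rep))),
    linear = 0
  )
  n <- length(p)
  par_names <- spec$params
  function(theta) {
    pr <- as.list(setNames(theta, par_names))
    if (any(!is.finite(theta))) return(1e10)
    if (spec$bounded && pr$delta_minus > pr$delta_plus) {
      return(1e10 + (pr$delta_minus - pr$delta_plus))
    }
    if (pr$sigma_lambda <= 0) return(1e10)
    m <- blo_mean_scale(p, N, pr, spec)
    if (any(!is.finite(m))) return(1e10)
    n * log(pr$sigma_lambda * sqrt(2 * pi)) +
      sum((t_pi - m)^2) / (2 * pr$sigma_lambda^2) + neg_log_jac
  }
}

#' Nadaraya-Watson kernel smoother
#'
#' Gaussian-kernel regression estimate
#' `M(x) = sum K((x - x_i)/h) y_i / sum K((x - x_i)/h)` with
#' `K(z) = exp(-z^2/2)/sqrt(2*pi)`, used to visualize distortion curves
#' nonparametrically. The default bandwidth is 0.03 (on the probability
#' scale).
#'
#' @param x_query Points at which to evaluate the smooth.
#' @param x_obs,y_obs Observed stimulus/response pairs (equal length >= 1).
#' @param h Bandwidth (> 0).
#' @return Numeric vector of smoothed values; queries where every kernel
#'   weight underflows to zero are `NA` with a warning.
#' @export
kernel_smooth <- function(x_query, x_obs, y_obs, h = 0.03) {
  stopifnot(h > 0, length(x_obs) == length(y_obs), length(x_obs) >= 1)
  out <- vapply(x_query, function(x) {
    w <- exp(-((x - x_obs) / h)^2 / 2) / sqrt(2 * pi)
    sw <- sum(w)
    if (sw == 0) return(NA_real_)
    sum(w * y_obs) / sw
  }, numeric(1))
  if (anyNA(out)) {
    warning("all kernel weights underflowed at ", sum(is.na(out)),
            " query point(s); returning NA there", call. = FALSE)
  }
  out
}
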