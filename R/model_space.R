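#' The 18-model factorial space
#'
#' The probability-distortion model family crosses three independent
#' dimensions: D1, the representation scale (log-odds, Prelec, or linear);
#' D2, whether the representation is truncated to bounds
#' `[delta_minus, delta_plus]`; and D3, the form of the sampling variance
#' that is compensated (`v_ns_power`: `ns = b + N^a`; `v_ns_const`:
#' constant sample size; `v_const`: constant variance, i.e. no
#' numerosity-dependent compensation). The full BLO model is
#' `"logodds-bounded-vnspow"` (8 free parameters); classic LLO is
#' `"logodds-free-vconst"` (3 parameters including the noise SD) and the
#' two-parameter Prelec model is `"prelec-free-vconst"`.
#'
#' @return Tibble with one row per model: `model_key`, `scale`, `bounded`,
#'   `variance`, `n_free_params`.
#' @export
#' @examples
#' nrow(model_space())  # 18
model_space <- function() {
  grid <- tidyr::expand_grid(
    scale = c("log_odds", "prelec", "linear"),
    bounded = c(TRUE, FALSE),
    variance = c("v_ns_power", "v_ns_const", "v_const")
  )
  grid$model_key <- paste(
    c(log_odds = "logodds", prelec = "prelec", linear = "linear")[grid$scale],
    ifelse(grid$bounded, "bounded", "free"),
    c(v_ns_power = "vnspow", v_ns_const = "vnsconst",
      v_const = "vconst")[grid$variance],
    sep = "-"
  )
  grid$n_free_params <- vapply(grid$model_key,
                               function(k) model_spec(k)$k, numeric(1),
                               USE.NAMES = FALSE)
  grid[, c("model_key", "scale", "bounded", "variance", "n_free_params")]
}

#' Resolve one cell of the factorial model space
#'
#' @param model_key String `"<scale>-<bounding>-<variance>"` with tokens
#'   `logodds|prelec|linear`, `bounded|free`, `vnspow|vnsconst|vconst`.
#' @return List with `model_key`, `scale`, `bounded`, `variance`, the
#'   parameter names `params`, the count `k`, and the fitting box `box`
#'   (2 x k matrix of lower/upper limits).
#' @export
#' @examples
#' model_spec("logodds-bounded-vnspow")$params
model_spec <- function(model_key) {
  parts <- strsplit(model_key, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("bad model key: ", model_key, call. = FALSE)
  scale <- switch(parts[1], logodds = "log_odds", prelec = "prelec",
                  linear = "linear",
                  stop("unknown scale token: ", parts[1], call. = FALSE))
  bounded <- switch(parts[2], bounded = TRUE, free = FALSE,
                    stop("unknown bounding token: ", parts[2],
                         call. = FALSE))
  variance <- switch(parts[3], vnspow = "v_ns_power",
                     vnsconst = "v_ns_const", vconst = "v_const",
                     stop("unknown variance token: ", parts[3],
                          call. = FALSE))
  params <- c(
    if (bounded) c("delta_minus", "delta_plus"),
    "eta", "lambda0",
    switch(variance, v_ns_power = c("a", "b"), v_ns_const = "ns",
           v_const = NULL),
    if (variance != "v_const") "alpha",
    "sigma_lambda"
  )
  box <- param_box()[, params, drop = FALSE]
  list(model_key = model_key, scale = scale, bounded = bounded,
       variance = variance, params = params, k = length(params), box = box)
}

#' Fitting boxes for every model parameter
#'
#' Documented default search/recovery ranges; row 1 is the lower and row 2
#' the upper limit. These are package choices (broad enough to cover
#' plausible human parameters): bounds `delta` in \[-4, 4\] log-odds units,
#' Thurstone gain `eta` in \[0.1, 8\] (the upper end accommodates subjects
#' whose strong uncertainty compensation shrinks the observed slope, so
#' the gain must be large for the observed distortion to stay in the
#' human range), anchor `lambda0` in \[-3, 3\],
#' compensation weight `alpha` in \[0, 100\], sample-size law `a` in
#' \[0, 2\] and `b` in \[0, 20\], constant sample size `ns` in \[1, 900\],
#' noise SD `sigma_lambda` in \[0.05, 2\].
#'
#' @return 2 x 9 numeric matrix with named columns.
#' @export
param_box <- function() {
  m <- cbind(
    delta_minus = c(-4, 4), delta_plus = c(-4, 4),
    eta = c(0.1, 8), lambda0 = c(-3, 3),
    a = c(0, 2), b = c(0, 20), ns = c(1, 900),
    alpha = c(0, 100), sigma_lambda = c(0.05, 2)
  )
  rownames(m) <- c("lower", "upper")
  m
}

#' Convert an LLO (gamma, p0) pair to registry parameters and back
#'
#' The `"logodds-free-vconst"` cell parameterizes LLO as
#' `eta * lo(p) + lambda0`; the classic form uses slope `gamma` and
#' crossover `p0` with intercept `(1 - gamma) * lo(p0)`. `llo_to_registry()`
#' maps (gamma, p0, sigma_lambda) to (eta, lambda0, sigma_lambda);
#' `registry_to_llo()` inverts it (`p0` is undefined at `gamma = 1` and
#' returned as `NA` there).
#'
#' @param gamma,p0,sigma_lambda Classic LLO parameters.
#' @return Named numeric vector.
#' @export
llo_to_registry <- function(gamma, p0, sigma_lambda) {
  c(eta = gamma,
    lambda0 = (1 - gamma) * scale_transform(p0, "log_odds"),
    sigma_lambda = sigma_lambda)
}

#' @rdname llo_to_registry
#' @param params Named vector with `eta`, `lambda0`, `sigma_lambda`.
#' @export
registry_to_llo <- function(params) {
  pr <- as.list(params)
  gamma <- pr$eta
  p0 <- if (abs(1 - gamma) < 1e-10) NA_real_ else {
    scale_inverse(pr$lambda0 / (1 - gamma), "log_odds")
  }
  c(gamma = gamma, p0 = p0, sigma_lambda = pr$sigma_lambda)
}
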