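#' Corrected Akaike information criterion
#'
#' `AICc = 2*nll + 2k + 2k(k+1)/(n - k - 1)`; the small-sample correction
#' vanishes as n grows.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of observations; must exceed `k + 1`.
#' @return Scalar AICc.
#' @export
#' @examples
#' aicc(100, 3, 200)  # 206.1224
aicc <- function(nll, k, n) {
  if (n <= k + 1) stop("AICc needs n > k + 1", call. = FALSE)
  2 * nll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# fminsearchbnd-style sin transformation between the box and an
# unconstrained space: x = lo + (hi - lo) * (sin(u) + 1) / 2
box_to_u <- function(x, box) {
  z <- 2 * (x - box["lower", ]) / (box["upper", ] - box["lower", ]) - 1
  asin(pmin(pmax(z, -1), 1))
}
u_to_box <- function(u, box) {
  box["lower", ] + (box["upper", ] - box["lower", ]) * (sin(u) + 1) / 2
}

#' Fit a distortion model by multi-start maximum likelihood
#'
#' Minimizes the negative log-likelihood with bounded Nelder-Mead simplex
#' search (the box constraint imposed through a sine transformation of the
#' coordinates) from Latin-hypercube starting points inside the documented
#' parameter box. Deterministic given `seed`.
#'
#' @param responses Tibble with columns `p`, `N`, `pi_report` (and
#'   optionally `cycle`, `numerosity` for stratified cross-validation).
#' @param model_key Registry key; see [model_space()].
#' @param n_restarts Number of starting points (default 20; the full
#'   protocol would use 1000).
#' @param seed Optional integer seed.
#' @param maxit,reltol Optimizer budget per restart.
#' @return An object of class `rf_fit`: list with `model_key`, `params`
#'   (named, inside the box), `nll`, `n_trials`, `k`, `aicc`,
#'   `n_restarts_used`, `converged`.
#' @export
fit_model <- function(responses, model_key, n_restarts = 20, seed = NULL,
                      maxit = 5000, reltol = 1e-8) {
  if (is.null(responses) || nrow(responses) == 0) {
    stop("empty response table", call. = FALSE)
  }
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  spec <- model_spec(model_key)
  f <- nll_function(responses, model_key)
  box <- spec$box
  k <- spec$k

  starts <- lhs::randomLHS(n_restarts, k)
  starts <- sweep(starts, 2, box["upper", ] - box["lower", ], "*")
  starts <- sweep(starts, 2, box["lower", ], "+")
  # keep sigma_lambda away from its lower edge so early simplices stay
  # numerically sane
  obj <- function(u) f(u_to_box(u, box))

  best <- NULL
  converged <- FALSE
  for (i in seq_len(n_restarts)) {
    u0 <- box_to_u(starts[i, ], box)
    res <- tryCatch(
      optim(u0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)

  params <- setNames(u_to_box(best$par, box), spec$params)
  n <- nrow(responses)
  structure(
    list(model_key = model_key, params = params, nll = best$value,
         n_trials = n, k = k, aicc = aicc(best$value, k, n),
         n_restarts_used = n_restarts, converged = converged),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %s: nll = %.3f, AICc = %.3f (n = %d, k = %d)%s\n",
              x$model_key, x$nll, x$aicc, x$n_trials, x$k,
              if (x$converged) "" else " [not converged]"))
  print(round(x$params, 4))
  invisible(x)
}

#' @rdname fit_model
#' @param x An `rf_fit` object.
#' @param ... Unused.
#' @export
tidy.rf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_model
#' @export
glance.rf_fit <- function(x, ...) {
  tibble::tibble(model_key = x$model_key, nll = x$nll, k = x$k,
                 n = x$n_trials, aicc = x$aicc, converged = x$converged)
}

#' Repeated stratified k-fold cross-validated deviance
#'
#' Splits trials into `n_folds` folds (stratified within each
#' cycle-by-numerosity condition when those columns are present), fits the
#' model on the training folds, evaluates the summed held-out log
#' likelihood, and returns `-2` times the total, averaged over `n_repeats`
#' random partitions -- a metric on the same scale as AICc.
#'
#' @inheritParams fit_model
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of random re-partitions averaged (default 10).
#' @param n_restarts Restarts per training fit.
#' @return Scalar cross-validated `-2 log L`.
#' @export
crossvalidate <- function(responses, model_key, n_folds = 10,
                          n_repeats = 10, n_restarts = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(responses)
  strata <- if (all(c("cycle", "numerosity") %in% names(responses))) {
    interaction(responses$cycle, responses$numerosity, drop = TRUE)
  } else {
    factor(rep(1, n))
  }
  if (any(table(strata) < n_folds)) {
    stop("fewer trials than folds in at least one condition",
         call. = FALSE)
  }
  reps <- vapply(seq_len(n_repeats), function(rep_i) {
    fold <- integer(n)
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    ll <- 0
    for (fi in seq_len(n_folds)) {
      train <- responses[fold != fi, ]
      test <- responses[fold == fi, ]
      fit <- fit_model(train, model_key, n_restarts = n_restarts)
      ll <- ll - neg_log_likelihood(test, model_key, fit$params)
    }
    -2 * ll
  }, numeric(1))
  mean(reps)
}
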