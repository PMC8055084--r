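#' Group-level random-effects Bayesian model selection
#'
#' Estimates the population frequencies of a set of candidate models from
#' per-subject log model evidence (here approximated as `-AICc / 2`) using
#' the variational Dirichlet scheme, and reports each model's protected
#' exceedance probability (PXP): the probability that it is the most
#' frequent model in the population, protected against the possibility
#' that all models are equally frequent via the Bayes omnibus risk (BOR):
#' `PXP_k = (1 - BOR) * XP_k + BOR / K`.
#'
#' @param log_evidence Numeric matrix, subjects x models (>= 2 models),
#'   of log model evidence; column names label the models.
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Monte-Carlo draws from the Dirichlet posterior used
#'   for the exceedance probabilities (default 1e5).
#' @param seed Optional integer seed for the Monte-Carlo step.
#' @param tol,max_iter Variational convergence controls.
#' @return List with `alpha` (posterior Dirichlet counts), `expected_freq`,
#'   `xp` (exceedance probabilities), `bor`, and `pxp`; vectors carry the
#'   model names.
#' @export
#' @examples
#' L <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("m1", "m2")))
#' protected_exceedance(L, seed = 1)$pxp
protected_exceedance <- function(log_evidence, alpha0 = 1,
                                 n_samples = 1e5, seed = NULL,
                                 tol = 1e-8, max_iter = 500) {
  if (!is.matrix(log_evidence) || ncol(log_evidence) < 2) {
    stop("log_evidence must be a subjects x models matrix with >= 2 models",
         call. = FALSE)
  }
  if (any(!is.finite(log_evidence))) {
    stop("non-finite log evidence", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(log_evidence)
  n <- nrow(log_evidence)
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("m", seq_len(K))
  a0 <- rep(alpha0, K)

  # variational updates for the Dirichlet posterior over model frequencies
  alpha <- a0
  g <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # free energy of the random-effects model
  log_beta <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  gl <- g * (log_evidence - log(pmax(g, 1e-300)))
  F1 <- sum(gl) + log_beta(alpha) - log_beta(a0)
  # null model: all frequencies fixed at 1/K
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  F0 <- sum(apply(log_evidence, 1, function(x) lse(x) - log(K)))
  bor <- 1 / (1 + exp(F1 - F0))

  # exceedance probabilities by Monte Carlo over the Dirichlet posterior
  draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
  win <- max.col(draws, ties.method = "random")
  xp <- tabulate(win, nbins = K) / n_samples

  pxp <- (1 - bor) * xp + bor / K
  list(alpha = setNames(alpha, models),
       expected_freq = setNames(alpha / sum(alpha), models),
       xp = setNames(xp, models),
       bor = bor,
       pxp = setNames(pxp, models))
}

#' Marginal protected exceedance probabilities per factorial dimension
#'
#' Sums PXP over the two other dimensions for each level of each dimension
#' of the factorial model space; within each dimension the marginals sum
#' to 1.
#'
#' @param pxp Named numeric vector over the 18 registry keys (names as in
#'   [model_space()]).
#' @return Tibble with `dimension` (`"scale"`, `"bounding"`, `"variance"`),
#'   `level`, and `pxp`.
#' @export
marginal_pxp <- function(pxp) {
  keys <- names(pxp)
  if (is.null(keys)) stop("pxp must be named by model key", call. = FALSE)
  parts <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  tb <- tibble::tibble(
    scale = parts[, 1], bounding = parts[, 2], variance = parts[, 3],
    pxp = unname(pxp)
  )
  dplyr::bind_rows(
    tb |> dplyr::group_by(dimension = "scale", level = .data$scale) |>
      dplyr::summarise(pxp = sum(.data$pxp), .groups = "drop"),
    tb |> dplyr::group_by(dimension = "bounding", level = .data$bounding) |>
      dplyr::summarise(pxp = sum(.data$pxp), .groups = "drop"),
    tb |> dplyr::group_by(dimension = "variance", level = .data$variance) |>
      dplyr::summarise(pxp = sum(.data$pxp), .groups = "drop")
  )
}

#' Fit and compare a set of models across subjects
#'
#' Fits each candidate model to each subject's responses, builds the
#' per-subject delta-AICc table (each subject's best model at 0), and runs
#' group-level Bayesian model selection with log evidence `-AICc / 2`.
#'
#' @param responses_by_subject Named list of response tibbles (one per
#'   subject), each with columns `p`, `N`, `pi_report`.
#' @param model_keys Character vector of registry keys (default: all 18).
#' @param n_restarts Restarts per fit.
#' @param seed Optional integer seed.
#' @return List of class `rf_comparison`: `aicc` (subjects x models
#'   matrix), `delta_aicc`, `summed_delta_aicc`, `bms` (the
#'   [protected_exceedance()] result), and `marginal` (per-dimension PXP
#'   tibble when all 18 models are present).
#' @export
compare_models <- function(responses_by_subject,
                           model_keys = model_space()$model_key,
                           n_restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(NA_real_, length(responses_by_subject), length(model_keys),
              dimnames = list(names(responses_by_subject), model_keys))
  for (s in seq_along(responses_by_subject)) {
    for (m in seq_along(model_keys)) {
      fit <- fit_model(responses_by_subject[[s]], model_keys[m],
                       n_restarts = n_restarts)
      A[s, m] <- fit$aicc
    }
  }
  dA <- A - apply(A, 1, min)
  bms <- protected_exceedance(-A / 2)
  marg <- if (length(model_keys) == 18) marginal_pxp(bms$pxp) else NULL
  structure(
    list(aicc = A, delta_aicc = dA, summed_delta_aicc = colSums(dA),
         bms = bms, marginal = marg),
    class = "rf_comparison"
  )
}

#' @export
print.rf_comparison <- function(x, ...) {
  cat("<rf_comparison>", nrow(x$aicc), "subjects x", ncol(x$aicc),
      "models\nsummed delta-AICc (best first):\n")
  print(round(sort(x$summed_delta_aicc), 2))
  invisible(x)
}
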