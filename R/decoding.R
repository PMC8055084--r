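#' Display-aligned lagged feature tensor
#'
#' For each included trial and display, extracts the multichannel sample
#' at `onset + lag` for every lag in `lags_s`, after decimating the
#' recording to `srate_out`. Displays whose lagged sample falls outside
#' the epoch are dropped.
#'
#' @param recording An `rf_recording`.
#' @param session The matching `rf_session`.
#' @param variable `"p"` or `"u"`: the display variable to decode.
#' @param cycle Trial cycle condition to use; defaults to the cycle in
#'   which `variable` is aperiodic (`"U"` for p, `"P"` for u).
#' @param numerosity Optional numerosity filter.
#' @param lags_s Lag grid in seconds (default 0-0.9 s at 120 Hz).
#' @param srate_out Analysis sampling rate (default 120 Hz; 150 ms = 18
#'   samples exactly, so onsets align to the grid).
#' @return List with `features` (array displays x channels x lags), `y`
#'   (display variable values), `trial` (trial id per display row),
#'   `confounds` (displays x 8 matrix), `lags_s`.
#' @export
lag_features <- function(recording, session, variable = c("p", "u"),
                         cycle = NULL, numerosity = NULL,
                         lags_s = seq(0, 0.9, by = 1 / 120),
                         srate_out = 120) {
  variable <- match.arg(variable)
  if (is.null(cycle)) cycle <- if (variable == "p") "U" else "P"
  rec <- resample_recording(recording, srate_out)
  info <- rec$trial_info
  sel <- info$cycle == cycle
  if (!is.null(numerosity)) sel <- sel & info$numerosity == numerosity
  rows <- info$row[sel]
  if (length(rows) < 3) stop("need at least 3 trials", call. = FALSE)
  n_samp <- dim(rec$data)[3]
  n_chan <- dim(rec$data)[2]
  n_lag <- length(lags_s)

  disp <- session$displays[session$displays$trial %in% info$trial[sel], ]
  # keep displays whose every lagged sample stays inside the epoch
  max_lag <- max(lags_s)
  disp <- disp[round((disp$onset_s - rec$epoch[1] + max_lag) * srate_out) +
                 1 <= n_samp, ]
  v <- disp$p_actual
  if (variable == "u") v <- v * (1 - v)

  n_disp <- nrow(disp)
  feats <- array(NA_real_, dim = c(n_disp, n_chan, n_lag))
  row_of_trial <- setNames(info$row[sel], info$trial[sel])
  base_idx <- round((disp$onset_s - rec$epoch[1]) * srate_out) + 1
  trial_row <- row_of_trial[as.character(disp$trial)]
  for (li in seq_len(n_lag)) {
    idx <- base_idx + round(lags_s[li] * srate_out)
    for (d in seq_len(n_disp)) {
      feats[d, , li] <- rec$data[trial_row[d], , idx[d]]
    }
  }
  conf <- as.matrix(disp[, confound_names()])
  list(features = feats, y = v, trial = disp$trial, confounds = conf,
       lags_s = lags_s)
}

#' Cross-validated confound regression (CVCR) of a feature matrix
#'
#' Regresses the confound columns (plus an intercept) out of each feature
#' column, with coefficients estimated on the training rows only and
#' applied to all rows, so no test-set information leaks into the
#' residualization. Zero-variance and collinear confound columns (e.g.
#' the constant mean luminance) are dropped by rank inspection.
#'
#' @param X Numeric matrix, rows = displays, columns = features.
#' @param C Confound matrix with the same number of rows.
#' @param train Logical or integer index of training rows.
#' @return Matrix of residuals, same shape as `X`.
#' @export
cvcr_residualize <- function(X, C, train) {
  keep <- apply(C[train, , drop = FALSE], 2, function(x) sd(x) > 0)
  D_all <- cbind(1, C[, keep, drop = FALSE])
  D_tr <- D_all[train, , drop = FALSE]
  q <- qr(D_tr)
  cols <- q$pivot[seq_len(q$rank)]
  D_all <- D_all[, cols, drop = FALSE]
  D_tr <- D_tr[, cols, drop = FALSE]
  B <- solve(crossprod(D_tr), crossprod(D_tr, X[train, , drop = FALSE]))
  X - D_all %*% B
}

# PCA (train-only) + ridge + leave-one-trial-out for one lag's features
decode_lag_loo <- function(F_lag, y, trial, n_pca, ridge, confounds = NULL) {
  trials <- unique(trial)
  rs <- numeric(0)
  excluded <- 0L
  for (tr in trials) {
    te <- trial == tr
    if (sum(te) < 2 || sd(y[te]) == 0) {
      excluded <- excluded + 1L
      next
    }
    trn <- !te
    X <- F_lag
    if (!is.null(confounds)) X <- cvcr_residualize(X, confounds, trn)
    Xtr <- X[trn, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    ytr <- y[trn]
    ymu <- mean(ytr)
    ysd <- sd(ytr)
    if (ysd == 0) {
      excluded <- excluded + 1L
      next
    }
    ytr <- (ytr - ymu) / ysd
    ev <- eigen(crossprod(Xtr) / (nrow(Xtr) - 1), symmetric = TRUE)
    k <- min(n_pca, sum(ev$values > 1e-10))
    V <- ev$vectors[, seq_len(k), drop = FALSE]
    Ztr <- Xtr %*% V
    Zte <- Xte %*% V
    W <- solve(crossprod(Ztr) + ridge * diag(k), crossprod(Ztr, ytr))
    pred <- as.numeric(Zte %*% W)
    rs <- c(rs, cor(pred, y[te]))
  }
  c(r = mean(rs), n_excluded = excluded)
}

#' Time-resolved stimulus decoding
#'
#' For every lag in the grid, reconstructs the aperiodic display variable
#' from the multichannel sensor samples at `onset + lag`: channels are
#' reduced by PCA (fit on training trials only, avoiding leakage), the
#' stimulus is regressed on the leading components with ridge penalty
#' `ridge`, and performance is the mean, over held-out trials under
#' leave-one-trial-out CV, of the Pearson correlation between the
#' predicted and true display sequence of the held-out trial.
#'
#' @inheritParams lag_features
#' @param n_pca Number of principal components retained (default 30,
#'   capped at the feature rank).
#' @param ridge Ridge penalty (default 1).
#' @param confounds `NULL`, or `TRUE` to regress the eight stimulus
#'   confounds out of the features within each CV fold (CVCR), or a
#'   custom displays x k confound matrix.
#' @param shuffle_stim Shuffle the display values within each trial before
#'   decoding (used to build permutation nulls).
#' @return Tibble of class `rf_decoding` with `lag_ms`, `r`,
#'   `n_excluded`; attributes record the settings.
#' @export
timeresolved_decode <- function(recording, session, variable = c("p", "u"),
                                cycle = NULL, numerosity = NULL,
                                lags_s = seq(0, 0.9, by = 1 / 120),
                                srate_out = 120, n_pca = 30, ridge = 1,
                                confounds = NULL, shuffle_stim = FALSE) {
  variable <- match.arg(variable)
  lf <- lag_features(recording, session, variable, cycle, numerosity,
                     lags_s, srate_out)
  y <- lf$y
  if (shuffle_stim) {
    for (tr in unique(lf$trial)) {
      idx <- which(lf$trial == tr)
      y[idx] <- y[sample(idx)]
    }
  }
  # the decoded sequence should be (nearly) free of autocorrelation
  rho1 <- mean(vapply(unique(lf$trial), function(tr) {
    v <- y[lf$trial == tr]
    if (length(v) < 3 || sd(v) == 0) return(NA_real_)
    cor(v[-1], v[-length(v)])
  }, numeric(1)), na.rm = TRUE)
  if (is.finite(rho1) && abs(rho1) > 0.2) {
    warning(sprintf(
      "decoded sequence has lag-1 autocorrelation %.2f (> 0.2); %s",
      rho1, "responses to successive displays are not separable"),
      call. = FALSE)
  }
  C <- NULL
  if (isTRUE(confounds)) C <- lf$confounds
  else if (is.matrix(confounds)) C <- confounds

  res <- vapply(seq_along(lf$lags_s), function(li) {
    decode_lag_loo(lf$features[, , li, drop = TRUE], y, lf$trial,
                   n_pca, ridge, C)
  }, numeric(2))
  out <- tibble::tibble(lag_ms = lf$lags_s * 1000,
                        r = unname(res[1, ]),
                        n_excluded = as.integer(res[2, ]))
  class(out) <- c("rf_decoding", class(out))
  attr(out, "variable") <- variable
  attr(out, "n_pca") <- n_pca
  attr(out, "ridge") <- ridge
  attr(out, "cvcr") <- !is.null(C)
  out
}

# maximal runs of TRUE in a logical vector -> list of index ranges
supra_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i) starts[i]:ends[i])
}

# one-sample right-sided t statistics per column
col_tstats <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  se <- apply(M, 2, sd) / sqrt(n)
  t_ <- mu / se
  t_[se == 0] <- 0
  t_
}

#' Cluster-based permutation test over time lags
#'
#' Groups adjacent lags whose group-level decoding performance is
#' significantly positive (one-sample right-sided t test, uncorrected
#' p < `alpha`) into clusters, takes the summed t value as the cluster
#' statistic, and compares each observed cluster with the null
#' distribution of maximal cluster statistics. The reference null is built
#' by re-running the decoding with the stimulus sequence shuffled within
#' each trial and passing the resulting courses as `null_r` (an array
#' subjects x lags x permutations). When `null_r` is absent, a cheaper
#' sign-flip surrogate over subjects is used and the result is flagged
#' (`attr(, "surrogate")`).
#'
#' @param r_mat Numeric matrix, subjects x lags, of decoding performance.
#' @param lags_ms Lag grid in milliseconds.
#' @param null_r Optional array subjects x lags x permutations of
#'   null decoding courses (from `shuffle_stim = TRUE` decodes).
#' @param n_perm Permutations for the sign-flip surrogate (default 500).
#' @param alpha Uncorrected cluster-forming threshold (default 0.05).
#' @param seed Optional integer seed.
#' @return Tibble with `cluster`, `start_ms`, `end_ms`, `sum_t`, `p`;
#'   empty (zero rows) when no lag is supra-threshold.
#' @export
cluster_permutation_time <- function(r_mat, lags_ms, null_r = NULL,
                                     n_perm = 500, alpha = 0.05,
                                     seed = NULL) {
  if (nrow(r_mat) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(r_mat)
  tcrit <- qt(1 - alpha, df = n - 1)
  t_obs <- col_tstats(r_mat)
  runs <- supra_runs(t_obs > tcrit)

  max_stat_of <- function(tv) {
    rr <- supra_runs(tv > tcrit)
    if (length(rr) == 0) return(0)
    max(vapply(rr, function(ix) sum(tv[ix]), numeric(1)))
  }
  surrogate <- is.null(null_r)
  if (surrogate) {
    null_max <- vapply(seq_len(n_perm), function(b) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      max_stat_of(col_tstats(r_mat * flip))
    }, numeric(1))
  } else {
    null_max <- vapply(seq_len(dim(null_r)[3]), function(b) {
      max_stat_of(col_tstats(null_r[, , b, drop = TRUE]))
    }, numeric(1))
  }
  out <- purrr::map_dfr(seq_along(runs), function(ci) {
    ix <- runs[[ci]]
    s <- sum(t_obs[ix])
    tibble::tibble(cluster = ci,
                   start_ms = lags_ms[min(ix)], end_ms = lags_ms[max(ix)],
                   sum_t = s,
                   p = (1 + sum(null_max >= s)) / (1 + length(null_max)))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(cluster = integer(), start_ms = numeric(),
                          end_ms = numeric(), sum_t = numeric(),
                          p = numeric())
  }
  attr(out, "surrogate") <- surrogate
  out
}

#' Peak latency as the t-weighted centroid of the largest cluster
#'
#' Among maximal runs of supra-threshold statistics within the search
#' window, picks the cluster with the largest summed statistic and
#' returns its statistic-weighted mean lag.
#'
#' @param stat Either a subjects x lags matrix of decoding performance
#'   (group t statistics are computed internally, threshold
#'   `qt(0.95, n - 1)`) or a numeric statistic course (then supply
#'   `threshold`).
#' @param lags_ms Lag grid (ms).
#' @param window Search window in ms (default `c(100, 500)`).
#' @param threshold Supra-threshold cutoff when `stat` is a vector.
#' @return Latency in ms, or `NA` if no cluster lies in the window.
#' @export
estimate_peak_latency <- function(stat, lags_ms, window = c(100, 500),
                                  threshold = NULL) {
  if (is.matrix(stat)) {
    threshold <- qt(0.95, df = nrow(stat) - 1)
    stat <- col_tstats(stat)
  }
  if (is.null(threshold)) stop("supply `threshold` for a statistic course",
                               call. = FALSE)
  inside <- lags_ms >= window[1] & lags_ms <= window[2]
  stat_w <- stat[inside]
  lags_w <- lags_ms[inside]
  runs <- supra_runs(stat_w > threshold)
  if (length(runs) == 0) return(NA_real_)
  sums <- vapply(runs, function(ix) sum(stat_w[ix]), numeric(1))
  ix <- runs[[which.max(sums)]]
  sum(stat_w[ix] * lags_w[ix]) / sum(stat_w[ix])
}

#' Bootstrap CI for a paired latency difference
#'
#' Resamples subjects with replacement and returns the mean difference
#' `latencies_u - latencies_p` with its percentile 95% CI.
#'
#' @param latencies_p,latencies_u Paired per-subject latencies (ms).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @return Tibble with `mean_diff`, `ci_lower`, `ci_upper`.
#' @export
bootstrap_latency_difference <- function(latencies_p, latencies_u,
                                         n_boot = 1000, seed = NULL) {
  stopifnot(length(latencies_p) == length(latencies_u))
  n <- length(latencies_p)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- latencies_u - latencies_p
  boots <- vapply(seq_len(n_boot),
                  function(b) mean(d[sample.int(n, replace = TRUE)]),
                  numeric(1))
  ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
  tibble::tibble(mean_diff = mean(d), ci_lower = ci[1], ci_upper = ci[2])
}

#' Spatial decoding at individual sensor locations
#'
#' For each sensor location, uses its three channels at every lag inside
#' `window_s` as features (PCA-reduced to the leading components reaching
#' `var_threshold` of the variance), and evaluates leave-one-trial-out
#' decoding of the display variable as in [timeresolved_decode()].
#'
#' @inheritParams timeresolved_decode
#' @param window_s Lag window in seconds, e.g. the peak window from the
#'   time-resolved course.
#' @param var_threshold Fraction of feature variance the retained
#'   components must explain (default 0.99).
#' @param kinds Channel kinds used (default all three; e.g. `"mag"` for
#'   magnetometers only, `c("grad1", "grad2")` for gradiometer pairs --
#'   these variants skip PCA only if a single feature remains).
#' @return Tibble with `location`, `r`, `n_comp`.
#' @export
spatial_decode <- function(recording, session, variable = c("p", "u"),
                           window_s, cycle = NULL, numerosity = NULL,
                           srate_out = 120, ridge = 1,
                           var_threshold = 0.99,
                           kinds = c("mag", "grad1", "grad2")) {
  variable <- match.arg(variable)
  lags_s <- seq(window_s[1], window_s[2], by = 1 / srate_out)
  lf <- lag_features(recording, session, variable, cycle, numerosity,
                     lags_s, srate_out)
  layout <- recording$layout
  locs <- unique(layout$location)
  purrr::map_dfr(locs, function(loc) {
    ch <- layout$channel[layout$location == loc & layout$kind %in% kinds]
    if (length(ch) == 0) {
      warning("location ", loc, " has no channels of the requested kinds",
              call. = FALSE)
      return(NULL)
    }
    X <- matrix(lf$features[, ch, , drop = FALSE],
                nrow = dim(lf$features)[1])
    # component count from the variance threshold (full-data spectrum,
    # used only to pick the count; fold-wise PCA picks the axes)
    ev <- eigen(crossprod(scale(X)) / (nrow(X) - 1), symmetric = TRUE)
    k <- which(cumsum(ev$values) / sum(ev$values) >= var_threshold)[1]
    res <- decode_lag_loo(X, lf$y, lf$trial, n_pca = k, ridge = ridge)
    tibble::tibble(location = loc, r = res[["r"]], n_comp = k)
  })
}

#' Cluster-based permutation test over sensor locations
#'
#' Locations with significantly positive decoding (one-sample right-sided
#' t, uncorrected p < `alpha`) are grouped into clusters of spatially
#' contiguous sensors (pairwise gaps below `adjacency_m`); the cluster
#' statistic is the summed t, compared against a max-statistic null from
#' subject-level sign flips (or a supplied `null_r` array).
#'
#' @param r_mat Subjects x locations matrix of decoding performance.
#' @param coords Locations x 3 matrix of sensor coordinates (meters).
#' @param adjacency_m Neighbor threshold in meters (default 0.04);
#'   at 0, every location is its own cluster.
#' @param null_r Optional subjects x locations x permutations null array.
#' @param n_perm Sign-flip permutations (default 500).
#' @param alpha Cluster-forming threshold.
#' @param seed Optional integer seed.
#' @return Tibble with `cluster`, `locations` (list-column), `sum_t`, `p`.
#' @export
cluster_permutation_space <- function(r_mat, coords, adjacency_m = 0.04,
                                      null_r = NULL, n_perm = 500,
                                      alpha = 0.05, seed = NULL) {
  if (nrow(r_mat) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(r_mat)
  tcrit <- qt(1 - alpha, df = n - 1)
  D <- as.matrix(dist(coords))
  adj <- D > 0 & D < adjacency_m

  comp_clusters <- function(tv) {
    supra <- which(tv > tcrit)
    if (length(supra) == 0) return(list())
    # connected components among supra-threshold locations
    unseen <- supra
    comps <- list()
    while (length(unseen) > 0) {
      frontier <- unseen[1]
      comp <- frontier
      unseen <- unseen[-1]
      while (length(frontier) > 0) {
        nb <- unseen[colSums(adj[frontier, unseen, drop = FALSE]) > 0]
        frontier <- nb
        comp <- c(comp, nb)
        unseen <- setdiff(unseen, nb)
      }
      comps[[length(comps) + 1]] <- sort(comp)
    }
    comps
  }
  t_obs <- col_tstats(r_mat)
  comps <- comp_clusters(t_obs)

  max_stat_of <- function(tv) {
    cc <- comp_clusters(tv)
    if (length(cc) == 0) return(0)
    max(vapply(cc, function(ix) sum(tv[ix]), numeric(1)))
  }
  surrogate <- is.null(null_r)
  if (surrogate) {
    null_max <- vapply(seq_len(n_perm), function(b) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      max_stat_of(col_tstats(r_mat * flip))
    }, numeric(1))
  } else {
    null_max <- vapply(seq_len(dim(null_r)[3]), function(b) {
      max_stat_of(col_tstats(null_r[, , b, drop = TRUE]))
    }, numeric(1))
  }
  out <- purrr::map_dfr(seq_along(comps), function(ci) {
    ix <- comps[[ci]]
    s <- sum(t_obs[ix])
    tibble::tibble(cluster = ci, locations = list(ix), sum_t = s,
                   p = (1 + sum(null_max >= s)) / (1 + length(null_max)))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(cluster = integer(), locations = list(),
                          sum_t = numeric(), p = numeric())
  }
  attr(out, "surrogate") <- surrogate
  out
}
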