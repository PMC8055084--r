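#' Display timing constant
#'
#' Each dot display is shown for 150 ms, so a two-display alternation cycle
#' runs at 1 / 0.3 s = 3.33 Hz.
#' @keywords internal
DISPLAY_DURATION_S <- 0.15

#' CIELAB palette used for the dot displays
#'
#' The two dot colors are isoluminant (L* = 43); dark gray filler elements
#' (L* = 43) are added between the dots so that every display has the same
#' overall luminance against the lighter gray background (L* = 56.5).
#'
#' @return Named list of length-3 numeric vectors `c(L, a, b)` with keys
#'   `orange`, `blue`, `gray`, `background`.
#' @export
#' @examples
#' cielab_palette()$orange
cielab_palette <- function() {
  list(
    orange     = c(43, 19.06, 52.33),
    blue       = c(43, -15.49, -23.72),
    gray       = c(43, 0, 0),
    background = c(56.5, 0, 0)
  )
}

# Equal-luminance filler model (see the methods vignette): dots have unit
# area, gray fillers half a unit, so n_filler = 2 * (N_REF - N) keeps the
# dark (L* = 43) area equal to N_REF area units on every display. The
# remaining A_TOTAL - N_REF units are background.
N_REF <- 1000
A_TOTAL <- 2400

filler_count <- function(N) 2 * (N_REF - N)

#' Sample an alternating p sequence for one trial
#'
#' In P-cycle trials the relative frequency p alternates between draws from
#' uniform(0.1, 0.5) and uniform(0.5, 0.9), so p itself cycles at 3.33 Hz.
#' In U-cycle trials p alternates between the set (0.1, 0.3) U (0.7, 0.9)
#' (each sub-interval with probability 1/2) and (0.3, 0.7), so p(1 - p)
#' cycles at 3.33 Hz (crossing the boundary 0.21) while p is aperiodic.
#'
#' @param cycle `"P"` or `"U"`.
#' @param n_displays Number of displays (>= 1).
#' @param start_low Logical; whether the first display is in the low phase.
#'   Default `NULL` randomizes the starting phase per trial.
#' @return Numeric vector of length `n_displays`, strictly inside (0, 1),
#'   with attribute `"phase"` (`"low"`/`"high"` per display, relative to the
#'   cycled variable).
#' @export
#' @examples
#' set.seed(1)
#' sample_p_sequence("P", 6)
sample_p_sequence <- function(cycle = c("P", "U"), n_displays,
                              start_low = NULL) {
  cycle <- match.arg(cycle)
  if (!is.numeric(n_displays) || length(n_displays) != 1 ||
      n_displays < 1 || n_displays != round(n_displays)) {
    stop("`n_displays` must be a positive integer", call. = FALSE)
  }
  if (is.null(start_low)) start_low <- runif(1) < 0.5
  idx <- seq_len(n_displays)
  low <- if (start_low) idx %% 2 == 1 else idx %% 2 == 0
  p <- numeric(n_displays)
  if (cycle == "P") {
    p[low]  <- runif(sum(low), 0.1, 0.5)
    p[!low] <- runif(sum(!low), 0.5, 0.9)
  } else {
    # low phase of p(1-p): p in (0.1,0.3) or (0.7,0.9), each with prob 1/2
    n_lo <- sum(low)
    side <- runif(n_lo) < 0.5
    lo_draw <- ifelse(side, runif(n_lo, 0.1, 0.3), runif(n_lo, 0.7, 0.9))
    p[low]  <- lo_draw
    p[!low] <- runif(sum(!low), 0.3, 0.7)
  }
  structure(p, phase = ifelse(low, "low", "high"))
}

#' Sample display numerosity
#'
#' Numerosity N is a linear transform of a Beta(0.1, 10) variable, mapped to
#' \[10, 90\] (`"small"` condition) or \[100, 900\] (`"large"`), rounded to
#' the nearest integer and clamped to the range. The Beta(0.1, 10) shape
#' concentrates N near the range minimum. N is sampled independently of p.
#'
#' @param numerosity `"small"` or `"large"`.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_numerosity <- function(numerosity = c("small", "large"), n = 1) {
  numerosity <- match.arg(numerosity)
  rng <- if (numerosity == "small") c(10, 90) else c(100, 900)
  x <- rbeta(n, 0.1, 10)
  N <- round(rng[1] + (rng[2] - rng[1]) * x)
  as.integer(pmin(pmax(N, rng[1]), rng[2]))
}

#' Build display records from nominal p and numerosity
#'
#' The target-color count is `round(p_nominal * N)`; the actual relative
#' frequency presented is `n_target / N`, which differs from the nominal p
#' by at most 0.5 / N. Degenerate roundings (0 or N target dots, possible
#' only at small N with p near 0.1 or 0.9) are moved one count inward so
#' that the actual p stays strictly inside (0, 1) and its log-odds is
#' finite.
#'
#' @param p_nominal Numeric vector in (0, 1).
#' @param N Integer vector (recycled) of display numerosities, >= 1.
#' @return Tibble with columns `p_nominal`, `N`, `n_target`, `n_other`,
#'   `p_actual`.
#' @export
#' @examples
#' make_display(c(0.5, 0.47, 0.333), c(10, 100, 10))
make_display <- function(p_nominal, N) {
  stopifnot(all(p_nominal > 0 & p_nominal < 1), all(N >= 1))
  n <- max(length(p_nominal), length(N))
  p_nominal <- rep_len(p_nominal, n)
  N <- rep_len(as.integer(N), n)
  n_target <- as.integer(round(p_nominal * N))
  n_target[n_target == 0L] <- 1L
  n_target <- pmin(n_target, N - 1L)
  tibble::tibble(
    p_nominal = p_nominal,
    N = N,
    n_target = n_target,
    n_other = N - n_target,
    p_actual = n_target / N
  )
}

# population variance of a discrete mixture: values v with counts w
mixture_var <- function(v, w) {
  m <- sum(v * w) / sum(w)
  sum(w * (v - m)^2) / sum(w)
}

#' Compute the eight stimulus confound variables
#'
#' For each display, computes the confounds that could covary with p or
#' p(1 - p): total dot count `N`, target-color count `Nt`, other-color count
#' `No`, mean display luminance `AvgLumi` (constant by the equal-luminance
#' filler rule), the per-element CIELAB color variances `vCIE_L`, `vCIE_a`,
#' `vCIE_b` over the display's element mixture (colored dots + gray fillers
#' + background elements), and the Michelson contrast `Mcontrast` between
#' dot and background luminance.
#'
#' @param displays Tibble with columns `N`, `n_target`, `n_other`
#'   (e.g. from [make_display()]).
#' @param palette Named list of CIELAB constants; see [cielab_palette()].
#' @return `displays` with the columns `Nt`, `No`, `AvgLumi`, `vCIE_L`,
#'   `vCIE_a`, `vCIE_b`, `Mcontrast` appended.
#' @export
compute_confounds <- function(displays, palette = cielab_palette()) {
  required <- c("orange", "blue", "gray", "background")
  if (!all(required %in% names(palette))) {
    stop("palette must define keys: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(c("N", "n_target", "n_other") %in% names(displays)))
  pal <- do.call(rbind, palette[required])  # rows: orange, blue, gray, bg

  L_dark <- palette$gray[1]
  L_bg <- palette$background[1]
  # area-weighted mean luminance: dark area fixed at N_REF units
  avg_lumi <- (L_dark * N_REF + L_bg * (A_TOTAL - N_REF)) / A_TOTAL
  mcontrast <- (L_dark - L_bg) / (L_dark + L_bg)

  n_bg <- A_TOTAL - N_REF
  v <- vapply(seq_len(nrow(displays)), function(i) {
    w <- c(displays$n_target[i], displays$n_other[i],
           filler_count(displays$N[i]), n_bg)
    c(mixture_var(pal[, 1], w), mixture_var(pal[, 2], w),
      mixture_var(pal[, 3], w))
  }, numeric(3))

  dplyr::mutate(
    displays,
    Nt = .data$n_target,
    No = .data$n_other,
    AvgLumi = avg_lumi,
    vCIE_L = v[1, ],
    vCIE_a = v[2, ],
    vCIE_b = v[3, ],
    Mcontrast = mcontrast
  )
}

#' Names of the confound columns
#' @return Character vector of the eight confound variable names.
#' @export
confound_names <- function() {
  c("N", "Nt", "No", "AvgLumi", "vCIE_L", "vCIE_a", "vCIE_b", "Mcontrast")
}

# cache for calibrated truncated-exponential rates
.truncexp_cache <- new.env(parent = emptyenv())

#' Calibrate the rate of a truncated exponential by its mean
#'
#' Finds the rate r such that an Exponential(r) variable truncated to
#' `[lo, hi]` has the requested mean. Solved numerically (the truncated mean
#' is strictly decreasing in r) and cached.
#'
#' @param mean_target Desired truncated mean, strictly inside `(lo, hi)`.
#' @param lo,hi Truncation bounds.
#' @return The calibrated rate (positive scalar).
#' @export
truncexp_rate <- function(mean_target = 3, lo = 1, hi = 6) {
  stopifnot(mean_target > lo, mean_target < hi)
  if (mean_target >= (lo + hi) / 2) {
    stop("a positive-rate truncated exponential has mean below the ",
         "interval midpoint ", (lo + hi) / 2, call. = FALSE)
  }
  key <- paste(mean_target, lo, hi, sep = "|")
  if (!is.null(.truncexp_cache[[key]])) return(.truncexp_cache[[key]])
  span <- hi - lo
  tmean <- function(r) lo + 1 / r - span * exp(-r * span) / (1 - exp(-r * span))
  f <- function(r) tmean(r) - mean_target
  rate <- uniroot(f, lower = 1e-3, upper = 50, tol = 1e-12)$root
  .truncexp_cache[[key]] <- rate
  rate
}

#' Sample catch-trial durations
#'
#' Catch-trial durations follow an exponential distribution truncated to
#' \[1, 6\] s with mean 3 s; the rate is calibrated once by
#' [truncexp_rate()] and sampling uses the inverse CDF.
#'
#' @param n Number of draws.
#' @param mean_target,lo,hi Truncated-mean specification (defaults 3 s on
#'   \[1, 6\] s).
#' @return Numeric vector of durations in seconds, all in `[lo, hi]`.
#' @export
sample_catch_duration <- function(n = 1, mean_target = 3, lo = 1, hi = 6) {
  r <- truncexp_rate(mean_target, lo, hi)
  u <- runif(n)
  lo - log(1 - u * (1 - exp(-r * (hi - lo)))) / r
}

#' Generate a full stimulus session
#'
#' Implements the 2 (P-cycle vs U-cycle) x 2 (N-small vs N-large) design:
#' by default 50 formal + 10 catch trials per condition, interleaved over 10
#' blocks of 24 trials with conditions balanced within each block. Formal
#' trials have 40 or 41 displays (6 or 6.15 s at 150 ms per display); catch
#' trials have durations from the truncated exponential on \[1, 6\] s
#' (mean 3 s) and `ceiling(duration / 0.15)` displays, so almost any display
#' could be the last one.
#'
#' @param subject_id Identifier string.
#' @param trials_per_condition Named numeric `c(formal = 50, catch = 10)`.
#' @param blocks Number of blocks; must divide the per-condition trial
#'   count.
#' @param seed Optional integer seed; the same seed reproduces the session
#'   exactly.
#' @return An object of class `rf_session`: a list with `subject_id`,
#'   `seed`, a `trials` tibble (trial, block, cycle, numerosity, is_catch,
#'   n_displays, duration_s) and a `displays` tibble (one row per display
#'   with p, N, counts, onset, phase and the eight confounds).
#' @export
#' @examples
#' s <- generate_session("s01", c(formal = 1, catch = 0), blocks = 1,
#'                       seed = 1)
#' s$trials
generate_session <- function(subject_id = "s01",
                             trials_per_condition = c(formal = 50, catch = 10),
                             blocks = 10,
                             seed = NULL) {
  n_formal <- as.integer(trials_per_condition[["formal"]])
  n_catch <- if ("catch" %in% names(trials_per_condition)) {
    as.integer(trials_per_condition[["catch"]])
  } else 0L
  if (n_formal < 1) stop("need at least 1 formal trial per condition",
                         call. = FALSE)
  per_cond <- n_formal + n_catch
  if (per_cond %% blocks != 0) {
    stop(sprintf(paste0("trials per condition (%d formal + %d catch = %d) ",
                        "cannot be tiled into %d equal blocks"),
                 n_formal, n_catch, per_cond, blocks), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  conds <- tidyr::expand_grid(cycle = c("P", "U"),
                              numerosity = c("small", "large"))
  per_block <- per_cond / blocks

  # allocate catch trials to blocks as evenly as possible, per condition
  catch_alloc <- function() {
    base <- rep(n_catch %/% blocks, blocks)
    extra <- n_catch %% blocks
    if (extra > 0) {
      pick <- sample.int(blocks, extra)
      base[pick] <- base[pick] + 1L
    }
    base
  }

  trial_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    alloc <- catch_alloc()
    for (b in seq_len(blocks)) {
      is_catch <- c(rep(TRUE, alloc[b]), rep(FALSE, per_block - alloc[b]))
      trial_rows[[length(trial_rows) + 1]] <- tibble::tibble(
        block = b,
        cycle = conds$cycle[ci],
        numerosity = conds$numerosity[ci],
        is_catch = is_catch
      )
    }
  }
  trials <- dplyr::bind_rows(trial_rows)
  # interleave: random order within block
  trials <- trials[order(trials$block, sample.int(nrow(trials))), ]
  trials$trial <- seq_len(nrow(trials))

  trials$n_displays <- NA_integer_
  trials$duration_s <- NA_real_
  formal_idx <- which(!trials$is_catch)
  nd <- sample(c(40L, 41L), length(formal_idx), replace = TRUE)
  trials$n_displays[formal_idx] <- nd
  trials$duration_s[formal_idx] <- nd * DISPLAY_DURATION_S
  catch_idx <- which(trials$is_catch)
  if (length(catch_idx) > 0) {
    dur <- sample_catch_duration(length(catch_idx))
    trials$duration_s[catch_idx] <- dur
    trials$n_displays[catch_idx] <-
      as.integer(ceiling(dur / DISPLAY_DURATION_S))
  }

  displays <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    p <- sample_p_sequence(tr$cycle, tr$n_displays)
    N <- sample_numerosity(tr$numerosity, tr$n_displays)
    d <- make_display(as.numeric(p), N)
    d$phase <- attr(p, "phase")
    d$trial <- tr$trial
    d$display <- seq_len(tr$n_displays)
    d$onset_s <- (d$display - 1) * DISPLAY_DURATION_S
    d
  })
  displays <- compute_confounds(displays)
  displays <- dplyr::left_join(
    displays,
    trials[, c("trial", "cycle", "numerosity", "is_catch")],
    by = "trial"
  )
  displays <- dplyr::select(
    displays, "trial", "display", "onset_s", "cycle", "numerosity",
    "is_catch", "phase", "p_nominal", "p_actual", "N", "n_target",
    "n_other", "Nt", "No", "AvgLumi", "vCIE_L", "vCIE_a", "vCIE_b",
    "Mcontrast"
  )

  structure(
    list(subject_id = subject_id, seed = seed,
         trials = tibble::as_tibble(trials[, c(
           "trial", "block", "cycle", "numerosity", "is_catch",
           "n_displays", "duration_s")]),
         displays = displays),
    class = "rf_session"
  )
}

#' @export
print.rf_session <- function(x, ...) {
  cat(sprintf("<rf_session> subject %s: %d trials (%d catch), %d displays\n",
              x$subject_id, nrow(x$trials), sum(x$trials$is_catch),
              nrow(x$displays)))
  invisible(x)
}

#' Serialize a session to CSV + JSON
#'
#' Writes `<stem>_displays.csv` (one row per display) and `<stem>_meta.json`
#' (subject id, seed, trial table).
#'
#' @param session An `rf_session`.
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_session <- function(session, stem) {
  csv <- paste0(stem, "_displays.csv")
  js <- paste0(stem, "_meta.json")
  utils::write.csv(session$displays, csv, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = session$subject_id,
         seed = session$seed,
         trials = session$trials),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}

#' Read a session written by [write_session()]
#' @param stem Path stem used when writing.
#' @return An `rf_session`.
#' @export
read_session <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  displays <- tibble::as_tibble(
    utils::read.csv(paste0(stem, "_displays.csv"), stringsAsFactors = FALSE)
  )
  structure(
    list(subject_id = meta$subject_id, seed = meta$seed,
         trials = tibble::as_tibble(meta$trials), displays = displays),
    class = "rf_session"
  )
}
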