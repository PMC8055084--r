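# shared small fixtures, built in code at test time

tiny_session <- function(formal = 5, catch = 0, blocks = 1, seed = 42) {
  generate_session("test", c(formal = formal, catch = catch),
                   blocks = blocks, seed = seed)
}

# a hand-built one-trial session with explicitly chosen displays, for
# tests that need full control over p, N, and onsets
manual_session <- function(p, N, cycle = "P", numerosity = "small") {
  d <- make_display(p, N)
  d$phase <- rep(c("low", "high"), length.out = length(p))
  d$trial <- 1L
  d$display <- seq_along(p)
  d$onset_s <- (d$display - 1) * 0.15
  d <- compute_confounds(d)
  d$cycle <- cycle
  d$numerosity <- numerosity
  d$is_catch <- FALSE
  trials <- tibble::tibble(
    trial = 1L, block = 1L, cycle = cycle, numerosity = numerosity,
    is_catch = FALSE, n_displays = length(p),
    duration_s = length(p) * 0.15
  )
  structure(list(subject_id = "manual", seed = NULL, trials = trials,
                 displays = d),
            class = "rf_session")
}

llo_responses <- function(n = 150, gamma = 0.6, p0 = 0.4, sigma = 0.3,
                          seed = 1) {
  set.seed(seed)
  stim <- sample_recovery_stimuli(n)
  stim$pi_report <- llo_sample(stim$p, gamma, p0, sigma)
  stim
}
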