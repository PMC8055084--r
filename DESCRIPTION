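Package: uncertrack
Title: Relative Frequency Tracking, Probability Distortion Models, and
    Neural Uncertainty Encoding Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how humans track the relative frequency p
    of a visual feature and its representational uncertainty p(1-p).
    Generates steady-state stimulus sessions in which p or p(1-p)
    alternates at 3.33 Hz while the other variable stays aperiodic;
    implements the linear-in-log-odds (LLO) and bounded log-odds (BLO)
    probability-distortion models and their 18-model factorial family with
    AICc, cross-validated, and group-level Bayesian model selection
    (protected exceedance probability); simulates behavioral reports and
    multichannel sensor-array recordings with known ground truth; and
    provides phase-coherence entrainment analysis, time-resolved and
    spatial stimulus decoding with cross-validated confound regression,
    cluster-based permutation inference, and a brain-behavior linking
    statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
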