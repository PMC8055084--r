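---
title: "Models and methods: tracking relative frequency and its representational uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncertrack)
```

## The scientific problem

People misreport probabilities and relative frequencies in a stereotyped
way: small `p` is overestimated, large `p` underestimated. A prominent
explanation is that the brain compensates for the uncertainty inherent in
its own representation of `p`. For relative-frequency judgments this
*representational uncertainty* behaves like the sampling variance of a
proportion, i.e. it is proportional to `p(1 - p)`: zero at the extremes,
maximal at `p = 0.5`.

`uncertrack` implements a complete simulation-and-analysis chain for
studying this idea with steady-state sensor-array recordings:

1. a stimulus design in which either `p` or `p(1 - p)` alternates at
   3.33 Hz while the other variable stays aperiodic (`generate_session()`);
2. the distortion-model family -- linear-in-log-odds (LLO), bounded
   log-odds (BLO), and their 18-cell factorial generalization -- with
   maximum-likelihood fitting and model comparison (`fit_model()`,
   `compare_models()`, `protected_exceedance()`, `model_recovery()`);
3. a synthetic-data generator with known ground truth for behavior and
   multichannel recordings (`simulate_behavior()`,
   `simulate_recording()`);
4. phase-coherence entrainment analysis with permutation nulls and FDR
   (`phase_coherence()`, `coherence_permutation_test()`);
5. time-resolved and spatial stimulus decoding with cross-validated
   confound regression and cluster-based permutation inference
   (`timeresolved_decode()`, `cvcr_residualize()`,
   `cluster_permutation_time()`, `spatial_decode()`);
6. the brain-behavior linking statistic `beta = kappa_p / kappa_u` and
   the across-subject correlation of its condition change with the
   behavioral slope change (`compute_beta()`, `link_correlation()`,
   `run_pipeline()`).

## Stimulus design

Each trial is a sequence of dot displays refreshed every 150 ms. A
display shows `N` dots, `round(p * N)` of them in the target color. In
*P-cycle* trials `p` is drawn alternately from uniform(0.1, 0.5) and
uniform(0.5, 0.9), so `p` cycles at 1 / 0.3 s = 3.33 Hz while `p(1 - p)`
follows an aperiodic course. In *U-cycle* trials `p` alternates between
the set (0.1, 0.3) with (0.7, 0.9) (each half with probability 1/2) and
(0.3, 0.7), which makes `p(1 - p)` alternate around 0.21 while `p`
itself is aperiodic. The starting phase of the alternation is randomized
per trial; the sources we model do not pin it down, and randomizing
removes a possible phase confound.

Numerosity is an independent linear transform of a Beta(0.1, 10)
variable into [10, 90] (N-small) or [100, 900] (N-large). Because the
Beta is concentrated near its minimum, the correlation between `p` and
the target-color count stays moderate (|r| < 0.5) when displays are
pooled across all four cycle-by-numerosity conditions; within a single
numerosity condition it is necessarily higher, so the package adopts
the pooled reading.

Formal trials have 40 or 41 displays (6 or 6.15 s); catch trials, which
keep the observer attending to every display, draw their duration from
an exponential distribution truncated to [1, 6] s whose rate is solved
numerically so the truncated mean is exactly 3 s, and show
`ceiling(duration / 0.15)` displays. A default session is 10 blocks of
24 trials: 50 formal plus 10 catch trials per condition, conditions
balanced within every block.

Degenerate roundings (`round(p * N)` equal to 0 or `N`, possible only at
`N = 10` with `p` near the range edges) are moved one count inward so
the realized proportion stays strictly inside (0, 1) and its log-odds is
finite.

### Confound variables and the luminance-filler model

Eight per-display confounds are computed: `N`, the two color counts
`Nt`/`No`, mean luminance `AvgLumi`, the CIELAB per-element color
variances `vCIE_L`/`vCIE_a`/`vCIE_b`, and the Michelson contrast
`Mcontrast`. Real displays keep luminance constant by filling dark gray
elements between the dots; pixel-level rendering is out of scope, so the
package uses an abstract element model: dots have unit area, gray
fillers half a unit, and the filler count `2 * (1000 - N)` keeps the
dark area (and hence `AvgLumi`) identical across displays. Color
variances are computed over the element mixture (colored dots + fillers
+ background units), which reproduces the empirically important
structure: all color-variance confounds are strongly correlated with
`N` (|r| > 0.79) and essentially uncorrelated with `p(1 - p)`, while
`AvgLumi` and `Mcontrast` are constants (and are therefore dropped
automatically by the confound-regression step). With the standard
palette the two dot colors have unequal a\* magnitudes (19.06 versus
-15.49), so `vCIE_a` peaks at an interior `p` above 0.5 rather than at
exactly 0.5 -- a direct consequence of the palette constants.

## Distortion models

### LLO

With `lo(p) = log(p / (1 - p))`, the LLO model says the reported
proportion `pi` satisfies

`lo(pi) = gamma * lo(p) + (1 - gamma) * lo(p0) + noise`,

Gaussian noise of SD `sigma_lambda` acting on the log-odds scale.
`gamma < 1` produces the classic inverted-S distortion; `p0` is the
crossover where reports are veridical.

### BLO

BLO derives the distortion from three assumptions: log-odds
representation; truncation of the representation to a bounded Thurstone
scale, `Lambda = eta * (clamp(lo(p), delta_minus, delta_plus) -
(delta_minus + delta_plus) / 2)`; and compensation for the sampling
variance of an internal estimate based on `ns` of the `N` dots drawn
without replacement,

`V = p (1 - p) / ns * (N - ns) / (N - 1)`, `ns = b + N^a`, clamped at 0,

through a reliability weight `omega = 1 / (1 + alpha * V)`:

`lo(pi) = omega * Lambda + (1 - omega) * lambda0 + noise`.

With the reported median sample-size law (`a = 0.42`, `b = 1.91`), `V`
at `p = 0.5` rises slightly from `N = 10` to a maximum near `N ~ 15-20`
and then falls steadily through `N = 900` -- the signature that makes
the distortion slope *increase* with numerosity.

### The 18-cell factorial family

Three dimensions are crossed: representation scale (log-odds, Prelec
`-log(-log p)`, linear), bounded versus bounds-free, and the variance
form (`ns = b + N^a`, constant `ns`, constant `V`). In constant-`V`
cells the compensation weight is a constant absorbed into the gain, and
the anchor acts as a plain intercept, so those cells reduce exactly to
LLO, the two-parameter Prelec model, and the neo-additive (linear)
family on their scales. Parameter counts per cell follow mechanically
(BLO: 8; LLO: 3 including the noise SD) and are enumerated by
`model_space()`.

Two modeling decisions deserve emphasis:

* **Likelihoods are densities of the observed report.** Models place
  their Gaussian noise on different scales, so the likelihood includes
  the log-Jacobian of the scale transform. Within a scale this is a
  parameter-free constant; across scales it is what makes AICc
  comparisons meaningful (without it, the linear-scale cells win any
  comparison spuriously, because log-odds residuals are measured in
  inflated units).
* **Reports are clipped to [1/202, 1 - 1/202]** before the log-odds or
  Prelec transform -- half a step of a 0-100% click scale -- so boundary
  clicks keep finite likelihood. Linear-scale cells use a plain Gaussian
  density without truncation; this is a deliberate simplification,
  matching how the neo-additive family is used descriptively.

Only `eta` (the ratio of the Thurstone half-range to the bound
half-width) is identifiable; the Thurstone half-range itself has no
independent role and is absorbed, which is why it is not a parameter.

### Fitting, comparison, identifiability

`fit_model()` minimizes the negative log-likelihood with Nelder-Mead
simplex search under box constraints imposed by a sine transformation of
the coordinates (the same device the MATLAB `fminsearchbnd` uses), from
Latin-hypercube starting points; desk-scale default 20 restarts,
tolerance 1e-8, 5000 evaluations per restart. The full protocol value
(1000 restarts) is available via `pipeline_config(paper_protocol =
TRUE)`. The search boxes are documented in `param_box()`; the gain box
extends to 8 because strongly compensating subjects need a large gain
for their observed slope to stay in the human range.

Models are compared by AICc, by repeated stratified 10-fold
cross-validated deviance, and at the group level by random-effects
Bayesian model selection: log evidence is approximated as `-AICc / 2`
(common practice when no better evidence approximation is available),
a variational Dirichlet posterior over model frequencies is estimated,
exceedance probabilities are computed by Monte Carlo (1e5 draws), and
the Bayes omnibus risk converts them to *protected* exceedance
probabilities, `PXP = (1 - BOR) * XP + BOR / K`. Marginal PXPs per
factorial dimension sum the 18 cell values across the other two
dimensions.

`model_recovery()` generates synthetic datasets from each candidate
model with plausible parameters (`sample_plausible_params()`), refits
every candidate, and tabulates summed-AICc wins. The plausible ranges
are generator conditions chosen once: the sample-size law brackets the
median estimates above, and the compensation weight range (alpha in
[40, 100]) is derived by inverting the ~25% numerosity effect on the
distortion slope that motivates the whole enterprise; weaker
compensation produces datasets in which the 8-parameter model is
genuinely indistinguishable from its constant-variance reduction, which
is an identifiability fact, not a fitting failure.

Parameter recovery at desk scale identifies the sample-size exponent
`a` to a median absolute error below 0.3 (200 trials, 50 restarts).
`alpha` and `b` individually trade off against each other through
`omega`; the jointly identified quantity `omega(p = 0.5, N = 20)` is
recovered with median absolute error below 0.35 (tolerance calibrated
once from the recovery oracle and frozen). This limitation matters
little downstream, since the neural analyses use `p(1 - p)` rather than
fitted `V`.

## Synthetic recordings

`forward_model()` defines a synthetic sensor array: `n_locations`
points on a Fibonacci hemisphere of 10 cm radius, three channels per
location (one magnetometer, two planar gradiometers; 102 locations =
306 channels at full scale). Each display adds, to every channel, a
causal gamma-shaped kernel (`t^6 * exp(-t / theta)`, unit energy,
support 0-900 ms) scaled by the standardized display value and the
channel's spatial weight; weights are smooth maps concentrated over
posterior locations with seeded jitter. Kernel peak latencies default
to 327 ms for `p` and 419 ms for `p(1 - p)`, the empirically motivated
values. Noise is white plus 1/f, per channel and trial.

Package choices to note:

* The simulation rate defaults to 600 Hz rather than a hardware-like
  1000 Hz so that both analysis rates (300 Hz for coherence, 120 Hz for
  decoding) are integer decimations; at 120 Hz a 150 ms display is
  exactly 18 samples, so display onsets align to the lag grid without
  interpolation.
* Default SNR (`amp = 2`, `noise_sd = pink_sd = 0.3`) was calibrated
  once so that desk-scale sessions detect 3.33 Hz entrainment against
  the permutation null in roughly 90% of simulated subjects, then
  frozen.
* The layout is an explicit stand-in, not real sensor geometry;
  adjacency for spatial cluster tests derives from its coordinates
  (< 4 cm rule).

What the generator deliberately does not emulate: artifacts (blinks,
cardiac activity), head movement, realistic forward fields, or
correlated sensor noise. Passing tests therefore demonstrate that the
analysis chain recovers known ground truth under its own assumptions,
not that it is robust to everything real recordings contain.

## Entrainment analysis

For trial-wise stimulus and response series, the phase coherence is

`kappa(f) = |mean cross-spectrum| / sqrt(mean stim power * mean resp power)`,

computed after per-trial demeaning, Hanning windowing, and zero-padding
to 10000 samples at 300 Hz (0.03 Hz resolution). The denominator uses
the product of trial-averaged power spectra -- the only reading under
which the Cauchy-Schwarz inequality guarantees `kappa` in [0, 1].
`kappa` is invariant to response scaling and to a constant delay.

The null shuffles the response across time points within each trial
(destroying phase alignment, preserving amplitudes), with
`p = (1 + #{null >= obs}) / (1 + n_perm)` -- never exactly zero -- and
Benjamini-Hochberg FDR across the 0-7 Hz bins or across locations.
Stimulus step functions use the *actual* (rounded) proportions, since
those are what was displayed.

## Decoding analysis

`timeresolved_decode()` reconstructs the aperiodic variable (`p` from
U-cycle trials, `p(1 - p)` from P-cycle trials) from the multichannel
samples at `onset + lag`, lag grid 0-900 ms at 120 Hz: channels are
standardized and reduced by PCA (default 30 components), the stimulus
is ridge-regressed on the components (penalty 1), and performance is
the mean over held-out trials, under leave-one-trial-out CV, of the
Pearson correlation between the predicted and true display sequence of
that trial (per-trial correlation, then averaged -- the adopted reading
of sequence-level evaluation). PCA is refit inside every training fold;
whether the original procedure did so is unclear, and the fold-wise
choice is the one that cannot leak test information. Decoded sequences
are checked for autocorrelation (|lag-1 rho| <= 0.2) because the
superposition argument requires separable display responses; raw `r`
(not Fisher-transformed) enters the group tests.

Cluster-based permutation inference groups adjacent lags with
significantly positive group decoding (right-sided one-sample t,
uncorrected 0.05), sums the t values, and compares against the maximal
cluster statistic under a null built by re-running the decoding with
within-trial shuffled stimulus sequences (`shuffle_stim = TRUE`). A
sign-flip surrogate over subjects is available and clearly flagged in
the result; it is used where hundreds of full null decodes would be
disproportionate, e.g. the type-I-rate checks in the test suite. Peak
latency is the t-weighted centroid of the largest cluster within
100-500 ms; subject-resampling bootstrap gives the CI of the u - p
latency difference.

`cvcr_residualize()` implements cross-validated confound regression:
per sensor and lag, the eight confounds (plus intercept; constant
columns dropped by rank inspection) are regressed out with coefficients
estimated on training folds only and applied to train and test alike.
It is exposed as a feature-matrix operation and as the `confounds=`
argument of the decoder because the residualization is fold-specific --
a single "residualized recording" object cannot represent it without
leaking fold information.

`spatial_decode()` repeats the decoding per sensor location (3 channels
x lags within the peak window, PCA to 99% variance) and applies the
cluster test over the sensor adjacency graph.

## Brain-behavior linking

Per subject and numerosity condition, `beta = kappa_p / kappa_u` (each
kappa read at 3.33 Hz from its cycle condition) measures the relative
neural strength of `p` versus `p(1 - p)`; the behavioral slope `gamma`
is fitted with cycle conditions collapsed (cycle has no effect on the
slope) but numerosity conditions separate. The linking statistic
correlates `delta_gamma = ln(gamma_large / gamma_small)` with
`delta_beta = ln(beta_large / beta_small)` across subjects, one-tailed
for positive correlation -- the direction fixed a priori by the
compensation account -- with BH-FDR across channels. Both measures are
within-subject log-ratios, hence unitless and robust to scaling
differences between subjects.

The pipeline's ground-truth coupling: each simulated subject has a
latent compensation strength that sets both the behavioral `alpha` and
the condition contrast of the neural uncertainty amplitude (stronger
uncertainty encoding in N-small than N-large for strong compensators;
coupling default 0.8, calibrated once so the cohort-level correlation
is positive in median over meta-replications). `run_pipeline()` chains
simulate - fit - entrain - link, writes CSV tables plus a JSON
manifest, and records built-in checks.

## Numerical choices and degenerate inputs

* Truncated-exponential rate: solved by `uniroot` on [1e-3, 50]; the
  truncated mean is strictly decreasing in the rate, and means at or
  above the interval midpoint are rejected (they would need a
  non-positive rate).
* `kappa` at zero-power frequencies is defined as 0; a single trial
  yields `kappa = 1` wherever power is nonzero and warns.
* `sampling_variance(p, 1, ...)` is 0 (degenerate denominator).
* Decoding folds whose held-out trial has constant stimulus are
  excluded and counted (`n_excluded`).
* Optimizer failures are caught; a fit where no restart converged is
  flagged `converged = FALSE`.
* Session/recording serialization is plain text (CSV + JSON) with
  17-significant-digit doubles, so round-trips are exact.

## Problem sizes used by the tests

The test suite runs everything at desk scale, chosen to exercise each
property at adequate power: sessions of 10-50 trials per condition;
LLO/BLO recovery on 200-trial subjects with 20 replications (10-50
restarts); model identifiability on a 5-model subset of the factorial
space with 5 datasets x 4 virtual subjects per generating model; 100
null simulations for each type-I-rate check; decoding on 5-6 location
arrays; 20 meta-replications of 8-subject cohorts for the linking
property. Full-protocol counts (1000 restarts, 500 permutations, 102
locations, 50 formal trials per condition) are a configuration flag,
not a different code path.

## Known limitations

* The sensor geometry and spatial weight maps are synthetic; spatial
  results demonstrate the inference machinery, not anatomy.
* Group-level evidence uses the AICc approximation; with strongly
  non-Gaussian posteriors a better evidence estimate would change PXP
  values, though rarely rankings.
* `alpha` and `b` are weakly identified individually (see above).
* The linear-scale likelihood ignores censoring at the response-scale
  boundaries; cells of that family are mildly misspecified for subjects
  who click the extremes often.
* Real-data ingestion is limited to the documented session/recording
  text formats; no acquisition-system formats are parsed.
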