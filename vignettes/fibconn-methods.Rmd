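---
title: "Methods: from Fibonacci-grammar sequence learning to directed EEG connectivity"
author: "fibconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Fibonacci-grammar sequence learning to directed EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibconn)
```

## What this package models

`fibconn` implements an analysis chain for a question in cognitive
neuroscience: does the degree of a person's bilingual experience modulate
how their brain's directed functional connectivity reorganizes around a
domain-general sequence-learning task?  The chain has two arms.

The **behavioral arm** builds a serial reaction-time task from the
Fibonacci grammar, a two-symbol Lindenmayer system (rules `0 -> 1`,
`1 -> 01`, all symbols rewritten simultaneously).  Each generation's
length and symbol counts are Fibonacci numbers; under the axiom `0`,
generation 11 has 144 symbols and is the block length used in sessions.
Because the grammar's strings are aperiodic and self-similar, a
participant can only predict upcoming items by exploiting two surface
regularities (a `0` is always followed by a `1`; `11` is always followed
by a `0`) and, beyond those, by implicitly chunking the string into
constituents that reproduce an earlier generation.  The package annotates
every position with its **ambiguity level**: the minimal chunking level
at which the position becomes deterministically predictable from the
preceding constituents.

The **connectivity arm** analyses resting multichannel recordings taken
before and after the task ("task-driven resting state").  Recordings are
band-passed, resampled to 128 Hz, cut into 10-s segments, screened by
four automatic artifact criteria, averaged into eight scalp
region-of-interest series, and summarized as an 8 x 8 matrix of pairwise
time-domain Granger causality — 56 directed edges per participant and
condition.  Edge strength is then regressed on the continuous
bilingualism score (an LSBQ-style composite) with a penalized
factor-smooth model: one cubic B-spline smooth of the score per directed
connection, plus parametric covariates and ridge-penalized random
intercepts, followed by per-connection Wald tests and Benjamini-Hochberg
correction over the 56 edges.

Because the underlying human data are not redistributable, the package
ships a first-class synthetic-data module: cohorts, trial-level reaction
times and vector-autoregressive (VAR) recordings with *known* directed
ground truth, so that every downstream stage can be validated by
parameter recovery rather than by assertion.

## Ambiguity levels: the operationalization

The grammar's determinism rules are order-2 at every level of its
hierarchy, a consequence of self-similarity: the label string of the
level-k constituents *is* a grammar string (generation `n - k`).  The
classifier therefore uses, at every level, at most the two labels
preceding the (lifted) transition:

* prefix ends in `0`, or in `11` — deterministic;
* prefix ends in a single `1` — ambiguous; the position necessarily
  starts a constituent at the next level, so the transition lifts to the
  label string one level up and the rules are applied again.

The recursion terminates with the minimal resolving level, or with
`unresolved` when the position runs out of preceding context or the
configured `max_level` (default 5, covering analysis levels 0-4) is
exceeded.  An independent brute-force oracle
(`oracle_min_resolving_level()`) re-derives the level for any position by
collecting every occurrence of the same two-label context in a long
reference generation (default generation 15) and checking whether the
following symbol is unique; the test suite verifies exact agreement on
all positions of generations 5-11.

Two conventions are deliberate choices rather than claims about prior
work: each experimental block is annotated independently (positions
lacking context at some level are `unresolved`, not inherited across
block boundaries — participants are not assumed to track cross-block
continuity), and "disambiguated at level L" means *exactly* L, with
`pool_below = TRUE` available to pool lower levels.

## The synthetic generators and what they do (not) emulate

`sample_cohort()` draws the demographic marginals of a 28-participant
bilingual adult cohort: the bilingualism composite from a truncated
normal (mean 9.01, SD 2.69, bounds 5.05-14.05), age (33.11, 9.57, bounds
18-57), L2 age of acquisition, an ordinal education level, gender,
handedness and task-order labels with realistic frequencies.  Note that
truncation makes the realized moments differ from the untruncated
parameters (the realized SD of the score is about 2.15); tests compare
against the analytic truncated-normal moments.

`simulate_behavior()` composes expected reaction times from a baseline
(450 ms), a per-block learning slope (-12 ms/block, i.e. -84 ms from the
first to the eighth block for an average participant), a per-unit score
offset (-12 ms), a positive block-by-score interaction on hierarchically
ambiguous material (+2 ms/block per score unit — flatter learning for
higher scores), and small point-class penalties.  Noise is mean-one
multiplicative log-normal (sigma 0.12) — right-skewed and strictly
positive, the standard choice for reaction times; accuracy is Bernoulli
with rate 0.97.  These magnitudes are generator configuration chosen to
produce realistic effect directions and sizes, not estimates of any
empirical dataset.

`simulate_rest_recording()` draws a stationary VAR process over the
eight region series (default VAR(1), diagonal coefficient 0.4,
innovation SD 5 uV, 300 s at 128 Hz — a five-minute resting recording at
the working rate).  Directed edges can be made score-dependent through
modulators; `lsbq_bump()` parameterizes a Gaussian bump
(baseline + height * exp(-(score - center)^2 / 2 width^2)), so both
"peak at mid experience" and "peak at high experience" shapes can be
emulated.  Stationarity is enforced by refusing any participant-specific
coefficient set whose companion-matrix spectral radius reaches 1.

What the generator does **not** emulate: volume conduction and field
spread, 1/f spectral shape, non-stationarity within a recording, or any
claim about true effect sizes.  A passing recovery test therefore shows
that the estimator chain is correct and adequately powered under clean
VAR dynamics — not that real scalp recordings carry effects of this
size.

## Preprocessing choices

The four rejection criteria are applied per channel and segment at the
working rate: gradient above 10 uV/ms between consecutive samples
(scaled by the inter-sample interval, since a sample spacing is not a
millisecond at 128 Hz), amplitude range above 100 uV within any 200 ms
window, absolute amplitude beyond +-150 uV, and amplitude range below
0.5 uV within any 100 ms window.  Windows are rounded to whole samples
(26 and 13 samples at 128 Hz).  Filtering is 4th-order Butterworth,
applied forward-backward for zero phase; the semi-automatic manual
review step of lab practice is replaced by the fully automatic criteria,
and offline re-referencing is available only as an optional
common-average reference.

One practical caveat discovered during validation and worth knowing
about: any temporal mixing of samples — low-pass filtering, and
especially resampling/temporal aggregation — induces a small *spurious
reverse* Granger component for strongly coupled edges (measured here at
roughly 0.018 nats after a 256-to-128 Hz chain versus 6e-5 at the native
rate).  The preprocessing API keeps the conventional band-pass/resample
defaults, but the demonstration configuration simulates directly at the
working rate with a high-pass only, so that "exactly the injected edges
are recovered" is a clean statement.  With real recordings this is one
more reason to interpret weak reverse edges conservatively.

## Granger causality

`granger_pair()` implements time-domain bivariate Granger causality:
`ln(RSS_restricted / RSS_full)` from least-squares autoregressions of
the target on its own past (restricted) and on both pasts (full).  The
estimator is non-negative by construction, invariant to channel
rescaling, and close to `p/N` under the null (the small-sample bias of
the log variance ratio).  Lagged regressors are built strictly within
segments so that artifact-rejection gaps never fabricate transitions.
The shared model order is selected by BIC on the full eight-channel VAR
(capped at 20) or fixed by configuration; the pipeline default fixes
p = 1, matching the synthetic ground truth's order.  The test suite
checks the estimator against a closed-form oracle: the restricted
residual variance derived from the stationary Yule-Walker
autocovariances of the true VAR (companion-form Lyapunov solution),
fully independent of the estimation code.  Conditional (multivariate)
GC is out of scope; with eight regions and minutes of data the bivariate
estimator is the robust default, at the cost of possible indirect-path
effects.

## The penalized factor-smooth model

For each condition the model is fitted to the 28 x 56 edge rows:

```
gc ~ connection + age + l2_aoa + education + gender
     + s(lsbq, by = connection, k = 15, fixed penalty 0.02)
     + (1 | participant) + (1 | task_order)
```

implemented as penalized least squares.  Each smooth uses a cubic
B-spline basis of dimension 15, reduced to 14 columns by a sum-to-zero
constraint (so the connection main effect carries the level means), with
a second-order difference penalty on the coefficients multiplied by the
fixed smoothing parameter 0.02.  Smoothness is deliberately *not*
selected from the data: a single fixed penalty shared by all 56 smooths
keeps every connection on the same wiggliness budget and makes the fit a
plain linear estimator.  Random intercepts enter as ridge-penalized
indicator blocks (default ridge 1).

Inference per connection uses a Wald statistic on the smooth's
coefficient block.  Because the fit is linear in the response, the exact
sampling covariance of the penalized estimator is
`sigma^2 (X'X + S)^-1 X'X (X'X + S)^-1`; the statistic uses the block of
this matrix and a chi-square reference with the block's rank as degrees
of freedom, which is exact under Gaussian noise up to the estimated
scale.  The scale estimate divides the residual sum of squares by
`n - 2 tr(H) + tr(HH')` (unbiased for a penalized smoother, where the
more familiar `n - edf` is too large a denominator and was measurably
anticonservative in simulation).  With this construction the per-smooth
type-I error at alpha = 0.05 and the Benjamini-Hochberg behaviour under
a global null are correct to Monte-Carlo accuracy in the acceptance
suite (500 replicates).  Model comparison for nested specifications
(e.g. adding handedness) uses the deviance difference against a
chi-square with the difference in effective degrees of freedom, plus an
AIC comparison (`-2 loglik + 2 edf`); the IQR screen
(`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) is provided for outlier checks such as
cohort score screening.

Numerical notes: the penalized normal equations are solved by Cholesky
factorization; refitting the same design to new responses
(`fs_refit()`) reuses the factorization, which is what makes the
500-replicate calibration runs cheap.  A rank-deficient smooth-block
covariance falls back to an eigen pseudo-inverse with the numerical rank
as degrees of freedom.  Evaluating a fitted smooth outside the observed
score range extrapolates the B-spline basis and is not meaningful; the
default evaluation grid spans the observed range only.

## Problem sizes used by the test and acceptance suites

The suites run the study-scale design wherever it is cheap (cohorts of
28, full 1058-trial sessions, 56-edge models, 500 null replicates) and
scale down only the simulated recording durations (60-120 s instead of
300 s) in the end-to-end recovery loops, where the GC estimator's noise
at those lengths is already far below the injected effects.  All
generators are bit-reproducible given a seed, and the pipeline writes a
manifest (seed, config hash, file list) next to its outputs.

## Known limitations

* The ambiguity-level operationalization is one consistent reading of
  hierarchical disambiguation in this grammar; other chunking strategies
  (and human deviations from canonical chunking) are not modeled.
* Bivariate GC cannot distinguish direct from indirect influence and,
  after aggressive filtering, can show small spurious reverse edges (see
  above).
* The factor-smooth inference assumes Gaussian residuals and a fixed,
  shared penalty; it approximates, rather than replicates, any specific
  GAM toolbox's test machinery.
* The behavioral mixed models use a participant random intercept only;
  random slopes are left to the user.
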