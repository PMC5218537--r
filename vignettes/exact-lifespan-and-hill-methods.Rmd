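---
title: "Methods: exact convolution lifespan tests and Hill dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact convolution lifespan tests and Hill dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeconv)
```

## Why an exact test for the mean lifespan

A whole-life dietary trial with a control cohort of several hundred mice and
supplemented groups of only 15 animals sits in an awkward statistical
regime: the control mean is known almost exactly, while the treated mean is
an average of very few, strongly right-skewed lifespans. Normal-theory
two-sample tests lean on asymptotics that 15 animals do not supply.

The exact route exploits the fact that lifespans are recorded on a discrete
grid. Mice are inspected daily, so every lifespan is an integer number of
days, and the empirical control distribution is a probability mass function
on that grid. Under the null hypothesis that treated animals die like
control animals, the lifespans of the $n$ treated animals are $n$
independent draws from the control pmf, and the sum $S_n$ of those draws has
an exactly computable distribution: the $n$-fold convolution of the pmf with
itself. Dividing the support by $n$ gives the distribution of the mean, but
the package works on the sum grid, where every support point is an integer
and the observed treated total $n\bar m$ can be compared to the grid without
floating-point tolerance games.

The p-value is the inclusive directional tail: with control mean $\mu$ and
treated mean $\bar m$,

$$p = \begin{cases}
P(S_n \ge n\bar m) & \bar m > \mu\\
P(S_n \le n\bar m) & \bar m < \mu\\
1 & \bar m = \mu.
\end{cases}$$

The boundary mass is included — the hypothesis is "the same or more extreme"
— and a treated mean exactly at the control mean yields $p = 1$ with
direction `none`, since zero deviation makes the extreme set the whole
sample space.

### What the convolution means, exactly

Convolving the empirical pmf corresponds to i.i.d. sampling *with*
replacement from the observed control lifespans. The Monte-Carlo validator
`monte_carlo_mean_test()` therefore resamples with replacement; the test
suite checks the exact and resampled p-values agree to within three binomial
standard errors at 200&nbsp;000 replicates, and that the exact values equal
brute-force enumeration over all ordered with-replacement tuples on small
problems.

### Calibration of the directional p-value

The direction of the tail is chosen from the data (away from the control
mean). That choice has a statistical price: under the null, the probability
that the *directional* p-value falls below $\alpha$ is approximately
$2\alpha$, because either tail can produce the exceedance. Simulation in the
test suite confirms the size is $\approx 0.10$ at $\alpha = 0.05$. This is a
property of the procedure itself, not of its implementation; it is the
procedure this package sets out to reproduce, so the one-sided directional
p-value is the default and is reported together with its direction. Users
who want a conventionally calibrated test can pass `two_sided = TRUE`, which
doubles the tail and caps at 1; the suite verifies that variant has size
$\approx \alpha$. Per-group p-values are reported uncorrected (matching how
such trial tables are usually printed); `stats::p.adjust` can be applied
downstream when a family-wise guarantee is wanted.

### Numerical choices

* **Grid.** Integer days, step 1. Fractional inputs are rounded half-to-even
  before building the pmf.
* **Convolution backend.** The reference path is direct dense convolution
  (exact up to double rounding), used whenever the operand-length product is
  at most $10^6$. Larger convolutions — e.g. the 60-fold convolution for a
  dietary-restriction group against a 335-animal control, whose support
  exceeds 60&nbsp;000 days — go through an FFT path, zero-padded to a highly
  composite length; round-off negatives (at the $10^{-15}$ scale) are
  clipped to zero and the mass renormalized. Tests require the two paths to
  agree to $10^{-9}$ per mass point and the moments of the $n$-fold
  convolution to equal $n\mu$ and $n\sigma^2$ to $10^{-9}$ relative.
* **n-fold convolution** uses binary exponentiation, so $n = 60$ costs about
  ten convolutions.
* **Pooling** concatenates raw lifespans — equivalent to the size-weighted
  mean — before testing with the pooled $n$.
* **Censoring.** The exact test refuses censored records outright rather
  than silently dropping them; Kaplan–Meier and log-rank (delegated to the
  `survival` package) handle censoring as usual.
* **Percent of control** is displayed rounded to the nearest integer; the
  unrounded value is kept in the summary table (`percent_of_control_raw`).

## The synthetic trial generator

Raw per-animal lifespans for trials of this design are generally not
published, so the package ships a generator whose defaults *are* the design
it targets: control $n = 335$ with mean 886 days, dietary restriction
$n = 60$ at 125% of control, three Mg²⁺-supplemented groups of $n = 15$ at
110% of control, and an $n = 15$ group with no effect.

Mortality follows the Gompertz law, $h(t) = a e^{bt}$ — the standard
description of adult rodent mortality — with treatment effects as
proportional multipliers $k$ on the hazard:
$S(t) = \exp\!\big(-(ka/b)(e^{bt} - 1)\big)$. Sampling is by inversion,
$T = \frac{1}{b}\log\!\big(1 - \frac{b}{ka}\log U\big)$, rounded to the
nearest day and floored at one day.

Defaults and why:

* $b = 0.006\,/\mathrm{day}$, a typical laboratory-mouse actuarial ageing
  rate; it implies a lifespan standard deviation of roughly
  $\pi/(\sqrt 6\, b) \approx 210$ days, realistic for a long-lived hybrid
  strain.
* $a$ is calibrated by root-finding so the analytic mean
  $\int_0^\infty S(t)\,dt$ hits the 886-day control target within 0.5 day
  (`calibrate_gompertz()`).
* Group multipliers are solved from the same analytic mean
  (`multiplier_for_mean()`) to hit the 125% / 110% targets, never set ad
  hoc.
* Seeding: one master integer seed, split deterministically per group by a
  fixed affine map modulo $2^{31}-1$ (`lifeconv:::split_seed`, versioned
  with the package), so every cohort is reproducible in isolation.

What the generator does *not* emulate: only the mean structure is anchored.
The true variance, skew, censoring pattern and any cohort heterogeneity of a
real trial are unknown, so passing parameter-recovery and calibration tests
on these synthetic cohorts demonstrates correctness of the *statistics*, not
fidelity to any particular colony's mortality.

## Hill dose-response analysis

Whole-cell current block by intracellular Mg²⁺ or MgATP is modelled with the
four-parameter Hill curve in the form

$$E(C) = E_{\min} + \frac{E_{\max} - E_{\min}}{1 + 10^{(IC_{50} - C)\,h}},$$

with $C$ in mM on the *linear* scale inside a base-10 exponent. Two
consequences are worth noting: $E(IC_{50})$ is exactly the midpoint
$(E_{\min}+E_{\max})/2$, and the transition width in concentration is
$\sim 1/|h|$ mM regardless of where $IC_{50}$ sits — which is why the
simulated concentration panels place points across $IC_{50} \pm 2/|h|$.

### Fitting

`fit_hill()` minimizes the unweighted residual sum of squares with
Levenberg–Marquardt iterations (`minpack.lm::nls.lm` as the optimizer
engine), with:

* $\log_{10} IC_{50}$ as the internal parameter, enforcing positivity and
  conditioning the search; results are reported in mM,
* a data-driven start ($E_{\max}$ = max response, $E_{\min}$ = min response,
  $IC_{50}$ = concentration nearest the half-maximal response, $h = -1$)
  plus two restarts at $IC_{50}\times 3$ and $IC_{50}/3$, best residual SS
  winning,
* convergence at relative SS change $< 10^{-15}$ (effectively machine
  precision) or 500 iterations,
* asymptotic standard errors from the Jacobian at the optimum, delta-method
  transformed for $IC_{50}$.

Preconditions: at least 5 points spanning a ≥ 3-fold range of positive
concentrations, and more points than free parameters. $C = 0$ is allowed —
the formula is finite there. A dense two-parameter grid search with analytic
linear sub-fits for $E_{\min},E_{\max}$ serves as the independent oracle in
the test suite.

### Comparing two curves

`compare_curves()` implements the extra sum-of-squares F test at the 0.05
threshold convention. The full model fits each dataset separately (8
parameters). Two nested null models are offered because published analyses
rarely state which parameters were shared:

* `"all-shared"` (default): one 4-parameter curve for the pooled data — the
  cleanest nested pair, asking "is there any difference at all?";
* `"ic50-and-slope-shared"`: common $IC_{50}$ and $h$, separate
  $E_{\min}/E_{\max}$ per dataset (6 parameters) — asking whether *potency*
  differs while allowing different current amplitudes.

$F = \frac{(SS_{null} - SS_{full})/(df_{null} - df_{full})}{SS_{full}/df_{full}}$
with the upper-tail F p-value. Nesting guarantees
$SS_{null} \ge SS_{full}$; a violation beyond $10^{-9}$ relative signals an
optimizer failure and raises an error rather than reporting a negative F.
When $SS_{full} = 0$ exactly (noiseless data) with $SS_{null} > 0$, p is
reported at the machine floor with a `degenerate` flag. Under the null
(both datasets from one curve, Gaussian noise) the F p-values are uniform;
the suite checks this over 500 simulations.

### The reference parameter presets

`hill_presets()` encodes the four reported inhibition fits used as
generating truths for parameter-recovery experiments: MgATP block with
$IC_{50} = 3.17$ mM, $h = -1.81$ (wild type) and $1.45$ mM, $-1.95$
(Trpm6-deficient); free-Mg²⁺ block with $0.60$ mM, $-1.14$ and $0.72$ mM,
$-1.18$. Only $IC_{50}$ and $h$ are published; $E_{\min}$ is set to 0
(complete block) and $E_{\max}$ to synthetic current densities (45 pA/pF
wild type, 18 pA/pF mutant, reflecting the smaller mutant currents). The
noise default is homoscedastic Gaussian with SD = 3% of the dynamic range —
a stand-in for unreported patch-clamp variability. Recovery results depend
on $IC_{50}$, $h$ and the *relative* noise, not on the synthetic amplitude.

## Problem sizes used in the shipped tests

The test suite exercises the package at the design scale it targets: a
335-animal control with treated groups of 15–60; enumeration oracles up to
$5^4$ tuples; 200&nbsp;000-replicate resampling checks; 500-trial null
calibration; 100 noiseless and 25-replicate noisy Hill recoveries; 500-run
F-test null uniformity. A complete simulate–test–summarize pipeline run on
the default design takes a few seconds.

## Known limitations

* The exact test assumes fully observed lifespans; trials with heavy
  administrative censoring need the survival-curve route instead.
* The directional default is intentionally uncalibrated at $\alpha$ (size
  $2\alpha$; see above) because it reproduces the procedure as practised;
  the doubled variant is the calibrated alternative.
* Asymptotic Hill-fit standard errors are Jacobian-based; with few
  concentration levels or a poorly covered transition they understate the
  real uncertainty. Profile or bootstrap intervals are out of scope.
* The Gompertz generator anchors means only; it is a testbed, not a
  mortality model for any particular strain.
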