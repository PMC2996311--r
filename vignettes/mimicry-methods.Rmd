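---
title: "When multi-exponential bout distributions mimic power laws: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When multi-exponential bout distributions mimic power laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutlaw)
```

## The problem

Hypnograms score sleep and wake in 30-second epochs, and the durations of
uninterrupted bouts of each state are the basic currency of sleep-architecture
analysis. Sleep bouts are conventionally described as exponentially
distributed (consistent with a constant per-epoch transition probability,
i.e. a first-order Markov process), while wake bouts are often reported to
follow a power law, `f(x) = c x^(-alpha)`. The mechanistic implications
differ sharply: a power law suggests self-organized, scale-free dynamics, an
exponential a simple probabilistic switch.

The difficulty is that a *sum of a few exponentials* — which arises naturally
when several sleep- or wake-promoting circuits each contribute their own time
constant — can look strikingly like a power law on the log-log
frequency-duration histograms used in this literature, especially at the
sample sizes a clinical polysomnogram provides (tens of bouts per night).
This package provides the simulation machinery to map *when* that mimicry
happens: generators for the competing bout processes, the fitting routines,
a parametric-bootstrap Kolmogorov-Smirnov (KS) goodness-of-fit test, Vuong's
model-choice test, and sweep drivers that chart the "zone of mimicry" across
decay constants, mixing proportions and sample sizes.

## Units, truncation and binning

All durations are measured in epochs (1 epoch = 30 s). Clinical scoring never
records a state shorter than one epoch, so every generator enforces a >= 1
epoch rule by rejection: a component asked for `n_draws` accepted values
redraws any value below 1 until the quota is met. Quotas rather than
probabilistic mixing keep the sweep axes exact — a landscape cell labelled
"75% fast draws" contains exactly that share. The rule is applied to all
generator families by default (`truncate_at_one = TRUE`); the alternative
reading, in which only power-law samples are truncated, is available through
the switch.

Draws are continuous; discretization happens only in
`bin_histogram()`, which floor-bins durations into unit-width bins.
Constant (not logarithmic) bin widths are used deliberately: they leave rare
long bouts in sparsely populated bins, which is the conservative setting for
an exponential fit to heavy-tailed data. The histogram container stores only
occupied bins; the least-squares machinery reconstructs the interior
zero-count bins analytically (they are genuine observations of zero
frequency), using geometric-series closed forms so that a fitted slow
component with an absurdly long tail cannot blow up memory or time.

## The three fitting routines

**Power-law maximum likelihood.** `fit_power_law_mle()` implements the
continuous MLE `alpha = 1 + n / sum(log(x_i / x_min))` on the *raw* durations
with the threshold fixed at `x_min = 1`. A threshold scan is deliberately
omitted: on simulated bouts it discards most of the sample and produces
good-but-meaningless fits, and a fixed threshold keeps cells of a parameter
sweep comparable.

**Constrained multi-exponential least squares.**
`fit_exponentials_nls()` fits `f(x) = sum a_i exp(-x / tau_i)` (one to three
components, zero offset — a constant floor of infinitely long bouts has no
biological basis) to the binned counts by unweighted nonlinear least squares.
Numerically the problem is separable: for fixed decay constants the
amplitudes solve a linear least-squares system, so the optimizer searches
only over the `tau`s (variable projection), with a Nelder-Mead pass refined
by BFGS. Two implementation choices deserve a note:

* the `tau` search runs in log space. Decay constants live on a ratio scale,
  and the log parametrization removes the flat invalid region at `tau <= 0`
  that otherwise strands a simplex. The biologically motivated screen —
  only decaying components with positive contribution are admissible — is
  enforced on the *amplitudes*, which remain unconstrained in the linear
  stage: a converged fit with any `a_i <= 0` is discarded as a constraint
  violation, never projected back into the feasible region.
* multi-exponential least squares is initialization-sensitive, so the
  deterministic start (`tau` spanning 1 to the histogram range in geometric
  progression) is followed by seed-jittered restarts, up to 20. Two restarts
  agreeing on the same constraint-violating optimum, or six consecutive
  optimizer failures, end the search early: at that point the outcome is a
  property of the data, not of the start.

The bin representative defaults to the midpoint (`bin + 0.5`), which
minimizes discretization bias for decaying densities; the left edge is
available for sensitivity analysis. For a single component the two choices
give identical fitted shapes (the amplitude absorbs the shift).

A fitted mixture is a frequency curve, not yet a distribution;
`normalize_to_pdf()` divides by `Z = sum a_i tau_i exp(-1/tau_i)` (its
integral over `[1, Inf)`) and exposes the closed-form CDF used by the KS
distance, the bootstrap sampler and the Vuong likelihood. The component
weights under the normalized density are `w_i = a_i tau_i exp(-1/tau_i) / Z`.

**Log-log ordinary least squares.** `fit_power_law_ols()` regresses
`log(count)` on `log(bin midpoint)` over positive-count bins (zero counts
have no logarithm and are necessarily excluded *here*, though they do enter
the nonlinear fits). Its `R^2` is the "explained variation" statistic common
in the bout-duration literature; the OLS sweep exists precisely to show that
this number stays high (0.8-0.95) across the fast-to-moderate decay region
where the bootstrap KS test rejects the power law essentially always, i.e.
that `R^2` is not a goodness-of-fit test. In the slowest corner of the
landscape (`tau2` of 30-60 epochs at moderate mixing) scattered single-count
tail bins do pull `R^2` down to 0.5-0.75, so the "always high" caricature
has limits of its own.

## The parametric-bootstrap KS test

For a fitted model with estimated parameters the null distribution of the KS
distance is not the textbook one, so it is built by simulation
(`ks_bootstrap_p()`): fit the candidate family; compute the observed
distance `d_o` between the sample's empirical CDF (raw durations) and the
fitted CDF; draw 100 reference samples *of the same size* from the fitted
model restricted to `[1, Inf)`; re-fit each reference sample to the same
family and measure its distance `d_s` against its *own* re-fitted CDF, so
the reference distances carry the same estimation optimism as `d_o`; report
`p = (# of d_s >= d_o) / 100`.

Conventions fixed here, stated explicitly because they matter at the margin:

* the model is rejected iff `p < 0.05`; `p = 0.05` exactly is *not*
  rejected, consistent with reporting "the fraction of iterations with
  p > 0.05" as failure to reject;
* a reference sample whose re-fit fails the convergence or positivity screen
  is redrawn with a fresh child seed up to 10 times, after which its `d_s`
  is recorded as `Inf` — a conservative choice that can only favour
  non-rejection;
* the KS distance is always computed on raw durations against the continuous
  fitted CDF; binning is a fitting device only.

`mimicry_probability()` iterates the whole procedure over fresh samples from
a known generator and reports the fraction of iterations in which the
*wrong* family survives. Iterations whose initial fit fails are excluded
from the primary denominator (the convergence count is reported); the
fraction over all iterations is also returned, since the two conventions
differ when convergence is poor. `run_table1()` additionally implements the
stricter inclusion criterion — keep only samples for which all three
exponential fits converge — whose denominator is exact by construction.

## Seeds

Every stochastic entry point takes one integer seed. Internally
`derive_seeds()` expands a seed into child seeds (a seeded draw of distinct
integers), and the tree bottoms out at one seed per sweep cell, per
iteration, per reference sample and per redraw attempt. Any cell of a
thousand-iteration landscape can therefore be replayed in isolation from the
`cell_seed` column of its results, and sweeps resume per-cell from
checkpoints without disturbing finished cells.

## What the generators emulate — and what they do not

The synthetic world is deliberately minimal: independent draws from
stationary mixtures (or a two-state Markov chain scored epoch by epoch),
with exact per-component quotas. Real hypnograms violate most of this —
bout durations are serially correlated, non-stationary across the night,
subject to scorer disagreement on brief arousals, and pooled across
heterogeneous subjects. A green test here therefore establishes a *best
case*: if power-law and multi-exponential models cannot be told apart on
clean i.i.d. data at clinical sample sizes, they certainly cannot on real
data. It does not establish that either family describes any particular
dataset.

Default parameter choices follow the published experiment design: generation
exponent `alpha = 3` (dispersed enough for unit-width binning), sample sizes
40-640 spanning one night to multiple nights of transitions, fast decay
fixed at 1 epoch with the slow component at 2-60 epochs, three-component
sweeps at `tau = (1, 5, 25)` with draw-ratio grids, and 1000 iterations by
100 references. Grid spacings were not published; the defaults here
(`tau2` in {2, 3, 5, 8, 10, 15, 20, 30, 45, 60}, proportions in steps of
0.1, log-spaced ratio grids over 0.25-16) are coarser desk-scale stand-ins,
and every driver accepts finer grids. The Markov illustration defaults to
`p_stay = 0.9` per state (mean bout 10 epochs), a value in the range of
human sleep-wake persistence; it is configurable and nothing downstream
depends on it.

## Numerical choices

* Mixture sampling on `[1, Inf)` uses memorylessness (`1 + Exponential(tau)`)
  rather than rejection, and component choice uses the normalized weights
  `w_i`; both are exact.
* The KS distance evaluates both sides of every empirical step
  (`max(|i/n - F|, |(i-1)/n - F|)`), verified against a brute-force scan to
  1e-12.
* Histograms with fewer total bins (including implied zeros) than free
  parameters (`2k`) are declared underdetermined rather than interpolated.
* `p`-values are computed as integer counts over `n_ref` so their `1/n_ref`
  granularity is exact in floating point.
* Ties in the largest-remainder quota rule break toward the first-listed
  component; quotas always sum exactly to `n`.

## Known limitations

The headline mimicry fractions are *implementation-sensitive* in a way the
landscape shapes are not. The constrained multi-exponential least-squares
problem has, for heavy-tailed samples, optima with extreme components (for
example `tau` below a tenth of an epoch, or in the thousands of epochs), and
how often a Levenberg-Marquardt-style optimizer reaches them depends on
starting values, scaling and termination rules that published work rarely
records. This package's fitter is deliberately well-defined — variable
projection with multi-start, so "converged" means "reached the least-squares
optimum within the positivity constraints" — and its test is correctly
calibrated (the correct-model rejection rate sits at the nominal 5%). But a
fitter that reaches the global optimum fits wrong-family samples *better*
(smaller observed KS distance) and re-fits sparse reference samples more
tightly (smaller reference distances) than a fragile local optimizer would,
and both effects move the middle of the mimicry-versus-sample-size curve by
tens of percentage points while leaving its extremes unchanged. Comparisons
with mimicry fractions produced by other implementations should therefore be
made at the level of the landscape's shape — which parameter regions mimic,
how mimicry decays with sample size — rather than cell by cell. The same
sensitivity affects Vuong verdicts in the zone of mimicry, where the two
candidate likelihoods are nearly tied and any handicap to the exponential
side flips the decision.

Bout durations are treated as continuous; a fully discrete treatment
(integer durations with discrete-law MLEs) is out of scope, as are threshold
estimation, weighted or Poisson-likelihood histogram fitting, and
alternative heavy-tail families (log-normal, stretched exponential).

## A worked example

```{r example, eval = FALSE}
library(boutlaw)

# a three-exponential mixture built to look like a power law
demo <- fig2_demo(seed = 1)
demo$ols_fit$r_squared        # 0.93: "linear" on the log-log plot

# ... and the bootstrap KS test is not fooled at this sample size
s <- demo$sample
ks_bootstrap_p(s, "powerlaw", n_ref = 100, seed = 2)$p_value  # 0

# but at one night of data it usually is
s40 <- draw_exponential_mixture(
  mixture_spec(c(1, 6, 60), allocate_quotas(c(0.474, 0.342, 0.184), 40)),
  seed = 3)
ks_bootstrap_p(s40, "powerlaw", n_ref = 100, seed = 4)$p_value  # > 0.05
```
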