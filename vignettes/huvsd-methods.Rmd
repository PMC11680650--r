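---
title: "Hierarchical unequal-variance signal detection for binary responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical unequal-variance signal detection for binary responses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huvsd)
```

## The estimation problem

In a yes/no detection or discrimination task, participant $i$ produces
$h_i$ hits out of $s_i$ signal trials and $f_i$ false alarms out of $n_i$
noise trials.  Gaussian signal detection theory places a noise distribution
$N(-d_i/2,\,\sigma_n^2)$ and a signal distribution $N(+d_i/2,\,\sigma_s^2)$
on a common decision axis (we fix $\sigma_n = 1$ as the unit), with a
response criterion at distance $c_i$ from the midpoint between the two
means, so that

$$\theta^h_i = \Phi\!\left[\frac{d_i/2 - c_i}{\sigma_s}\right], \qquad
  \theta^f_i = \Phi\!\left[\frac{-d_i/2 - c_i}{\sigma_n}\right].$$

For a single participant observed in a single condition, the
unequal-variance model is not identified: three unknowns
$(d_i, c_i, \sigma_s)$, two observables.  The model implemented here makes
it identifiable *at the population level* by a hierarchical assumption:
sensitivities and criteria are independent normal draws,
$d_i \sim N(\mu_d, \sigma_d^2)$ and $c_i \sim N(\mu_c, \sigma_c^2)$, and
$\sigma_s$ is (approximately) common to all participants.  The
z-transformed rates are then bivariate normal with

$$E\!\begin{pmatrix} z^h \\ z^f \end{pmatrix} =
  \begin{pmatrix} (\mu_d/2-\mu_c)/\sigma_s \\ -\mu_d/2-\mu_c \end{pmatrix},
  \qquad
  \mathrm{Cov} = \begin{pmatrix}
  (\sigma_c^2+\sigma_d^2/4)/\sigma_s^2 & (\sigma_c^2-\sigma_d^2/4)/\sigma_s \\
  (\sigma_c^2-\sigma_d^2/4)/\sigma_s   & \sigma_c^2+\sigma_d^2/4
  \end{pmatrix}.$$

Five observable moments, five population parameters: in particular
$\mathrm{Var}[z^f]/\mathrm{Var}[z^h] = \sigma_s^2$, so the *ratio of
between-participant variances* of the z-rates carries the signal-variance
information that a single participant's data cannot.  `momentMap()`
computes this mapping, `momentEstimate()` inverts it in closed form, and
`zrateMoments()` supplies empirical moments (with the edge-stabilising
rate correction $(h+\tfrac12)/(s+1)$, which exists only for this
closed-form path — the Bayesian model treats the rates as latent and needs
no correction).

## Model variants and priors

`fitSDT()` fits three variants selected by `modelSpec()`:

* **huvsd** — the five-parameter unequal-variance model.  Priors:
  $\mu_d, \mu_c \sim N(0, 1000)$ (variance 1000, i.e. precision 0.001 in
  BUGS convention); precisions $\lambda_d, \lambda_c \sim$ gamma(0.5, 0.5)
  (shape/rate, equivalent to a unit-scale $\chi^2_1$ recommendation for
  hierarchical variances); signal variance
  $\sigma_s^2 \sim N(1, 2)$ truncated to $(0,\infty)$.  The truncated
  normal is deliberately centred on the equal-variance value 1, so any
  departure of $\hat\sigma_s$ from 1 is evidence in the data overwhelming
  a conservative prior.  Alternatives gamma(0.5, 0.5) and uniform(0, 5)
  are selectable (`prior_sigma_s`), as is reading the "2" as an SD rather
  than a variance (`truncnorm_spread`); the source models do not pin this
  down, and at realistic sample sizes the choice is immaterial — which is
  exactly why it is exposed rather than hard-coded.
* **hevsd** — equal variance ($\sigma_s = 1$ fixed).  Its precision prior
  is not pinned by the source models either; the default gamma(0.5, 0.5)
  matches huvsd so that model comparisons vary only in the constraint of
  interest, with gamma(0.1, 0.1) selectable.
* **hevsd_expanded** — the linearly expanded equal-variance model
  $d_i = \mu_d + \xi_d\,\delta^d_i$ with auxiliary scales
  $\xi_d, \xi_c \sim$ beta(1, 1) and gamma(0.1, 0.1) precision priors on
  the deviations.  The $\xi$'s exist to help mixing and are not
  identified; only products like $\xi_d/\sqrt{\lambda_d}$ are
  interpretable.

Internally the precisions $\lambda$ are the authoritative representation;
$\sigma_d, \sigma_c$ are derived views computed draw-wise in summaries.
The sampler parameterises $\sigma_s$ directly and evaluates the variance
prior through the change of variables, including the Jacobian $2\sigma_s$
(unit-tested by integrating the transformed density).  Likelihood rates
are clamped to $[10^{-12}, 1-10^{-12}]$ so extreme latent states during
early sampling stay finite; the bound is far below anything binomial data
can resolve.

## The sampler

`fitSDT()` runs a self-contained Metropolis-within-Gibbs scheme:

1. **Individual parameters.**  Joint random-walk proposals on each
   $(d_i, c_i)$ pair, vectorised across participants, with per-participant
   proposal scales.
2. **Conjugate hyperparameters.**  $(\mu_d \mid d, \lambda_d)$,
   $(\mu_c \mid c, \lambda_c)$ are exact normal Gibbs draws;
   $(\lambda_d \mid d, \mu_d)$, $(\lambda_c \mid c, \mu_c)$ exact gamma
   draws.
3. **Signal SD.**  A scalar random walk on $\sigma_s$, *plus* a
   likelihood-invariant rescale move: propose $\sigma_s'$ and remap every
   individual as $d_i' = \sigma_s' z^h_i - z^f_i$,
   $c_i' = -(\sigma_s' z^h_i + z^f_i)/2$, which leaves all response
   probabilities exactly unchanged.  The acceptance ratio is the prior
   ratio times the Jacobian $(\sigma_s'/\sigma_s)^n$.  This move travels
   along the posterior ridge that couples $\sigma_s$ to the whole latent
   field — without it the $\sigma_s$ effective sample size collapses by
   two orders of magnitude.  Being likelihood-free it is cheap and is
   applied three times per sweep.
4. **Translation moves.**  Shift $\mu_d$ and every $d_i$ (and separately
   $\mu_c$ and every $c_i$) by a common amount.  The population prior
   depends only on the differences, so the ratio reduces to likelihood
   times the $\mu$ hyperprior.  These traverse the hierarchical funnel and
   make the sampler exact even for zero-information data, where the
   posterior must reproduce the prior (a property the test suite checks
   against numerically integrated prior moments).

Proposal scales adapt by Robbins–Monro recursion toward 0.23 (bivariate
blocks) or 0.44 (scalars) during burn-in only and are frozen afterwards,
so retained draws come from a fixed kernel.  Chains are initialised from
edge-corrected empirical rates with precisions drawn from their priors —
dispersed starting points that make the between-chain diagnostic
meaningful.  One master seed spawns per-chain seeds; a fit is
bit-reproducible from (data, spec, config).

Defaults mirror the simulation protocol: 4 chains of 10000 iterations
with 4000 burn-in.  Well-behaved applications need less (burn-in 1000 is
the `fitDataset()` default).

Convergence is reported as split-$\hat R$ (each chain halved before the
between/within comparison — stricter than the original statistic; the
conventional 1.01 cutoff is used throughout), with effective sample sizes
from `coda`.  `dic()` uses the plug-in deviance at the posterior means of
the likelihood-level parameters $(d_i, c_i, \sigma_s)$ — the focus
matching the binomial likelihood and the default deviance monitor of
BUGS-family samplers, though exact numeric parity with any particular
sampler's $p_D$ is not guaranteed.  `waic()` computes pointwise terms at
the grain where the likelihood factorises exactly: one signal and one
noise term per participant.

Correctness is established three independent ways in the test suite: the
conjugate updates against hand-derived closed forms; the population
posterior against an independent JAGS fit of the same model (via `rjags`);
and the individual-level posterior means against a sampler-free
grid-integration Bayes estimator under the true population, which the fit
matches to three decimals in recovery correlation.

## The synthetic-data generator

`simulateSDT()` draws $(d_i, c_i)$ (and under heterogeneity
$\sigma_{s,i}$) from a multivariate normal and binomial counts from the
implied rates, with **no** edge correction — participants at 0 or maximal
counts are retained verbatim.  Violation modes:

* `sigma_s_heterogeneity`: $\sigma_{s,i} \sim N(\sigma_s, 2\sigma_s^4/n)$,
  the spread matched to the standard error of a sample variance at sample
  size $n$, truncated at zero by rejection.  Whether the original
  simulations truncated is unstated; at the regimes of interest negative
  draws are vanishingly rare, so the choice is immaterial but documented.
* `rho_dc`, `rho_ds`, `rho_cs`: latent correlations violating the
  independence assumptions, constructed directly in the trivariate
  covariance (positive semi-definiteness is validated up front).

`simulateLadder()` produces the halving design $n = k = 512, 256, \dots,
16$, re-scaling the heterogeneity spread to each level's $n$ and deriving
per-level seeds from the base seed.

What the generator emulates is exactly the model's own sampling structure
(plus the controlled violations).  What it does **not** emulate: sequential
dependencies between trials, item effects, non-Gaussian latent
distributions, or participant-specific noise variance.  Green tests
therefore certify the estimator under its stated assumptions and graded
departures from them — not robustness to every failure mode of real data.

## Experiment runners and study scales

`runRecovery()`, `runBias()` and `runRobustness()` wrap
generate-fit-report loops; `fitDataset()` fits external count tables
(comma/tab-delimited, one row per participant) and compares variants by
DIC/WAIC.  `dichotomizeRatings()` converts long-format confidence ratings
to yes/no counts with the midpoint rule (ratings $\le 3$ on a 6-point
scale count as Yes), exposed as a pure, exhaustively tested function.

The package's reference experiments use the scales of the simulation
program it reproduces: recovery at $n = 500$ participants with 200 signal
and 200 noise trials; a word-recognition replay at $n = 97$ with 240
signal and 240 noise trials (the recognition experiment presented 240
targets and 240 foils per participant); misspecification bias at
$n = 200$, $100 + 100$; calibration over 50 replicates at $n = 100$,
$50 + 50$ with shorter chains.  The full recovery fit takes about a
minute on one core; the test suite completes in a few minutes.

A note on attainable recovery: the Pearson correlation between
posterior-mean and generating individual sensitivities is bounded by the
binomial information in the counts.  A sampler-free oracle (grid
integration of $E[d_i \mid h_i, f_i]$ under the true population) gives
$r_d = 0.946$, $r_c = 0.975$ at $200+200$ trials and $n = 500$; the MCMC
fit reproduces the oracle to about $3\times 10^{-4}$.  Published values
around $r_d = 0.975$ for this design correspond to the oracle at
$400+400$ trials; the package reports what the stated design supports and
documents the gap rather than adjusting the conditions toward the larger
numbers.

## ROC analytics

In z-coordinates the model's operating characteristic is the line
$z(\theta^h) = z(\theta^f)/\sigma_s + \mu_d/\sigma_s$ (`zrocLine()`):
slope $1/\sigma_s$ — below 1 exactly when the signal distribution is
wider than noise — and x-intercept $-\mu_d$.  `rocCurve()` maps the line
back through $\Phi$, and `sdtAUC()` evaluates
$\Phi\!\left(\mu_d/\sqrt{1+\sigma_s^2}\right)$, the probability that a
random signal-trial strength exceeds a random noise-trial strength; the
tests verify it against trapezoid integration of the curve.

## Numerical choices and degenerate inputs

* Rates of exactly 0/1 are *rejected* by `paramsFromRates()` and
  corrected only in `zrateMoments()` — one documented home for the edge
  policy.
* Sample moments use the unbiased $n-1$ denominators throughout.
* A zero-variance generating population ($\sigma_d = \sigma_c = 0$) makes
  recovery correlations undefined; `runRecovery()` records the degenerate
  case instead of erroring.
* Zero-trial rows contribute no likelihood and are tolerated by
  `fitSDT()`; this is what makes prior-recovery checks possible.
* Split-$\hat R$ of identical constant chains is 1 by convention; chains
  that agree within machine precision but differ in mean report `Inf`.

## Known limitations

The model fixes the d–c correlation at zero; fitting it is out of scope
(the robustness runner quantifies the bias when the assumption fails
instead: $\hat\mu_d$ and $\hat\sigma_s$ drift up, $\hat\mu_c$ down, as
`rho_dc` grows, while equal-variance estimates are insensitive but
constantly biased).  Confidence-rating likelihoods with multiple
thresholds, item/lag random effects, and non-Gaussian latent axes are not
implemented.  The expanded equal-variance variant mixes slowly — that is
the historical motivation for preferring the unequal-variance
parameterisation, and the package keeps it mainly for comparability.
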