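---
title: "Modelling practice effects in longitudinal verbal learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling practice effects in longitudinal verbal learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctpe)
```

## The scientific problem

Verbal-learning tests (three immediate free-recall trials of a 12-word
list plus one delayed trial, scored 0–12 words) are administered annually
in clinically characterized aging cohorts. Scores change across occasions
for two confounded reasons: genuine change in ability, and practice —
incidental retention of the list and test format from earlier visits.
`ctpe` models the practice effect (PE) as its own latent process so that
the retest gain per occasion, its compounding or decay over visits, and
per-trial mean performance can be estimated jointly, together with how
each shifts under MCI or dementia diagnoses and demographic covariates.

## Latent dynamics

The four trials are modelled as deviation processes around per-trial
manifest means $\mu_1,\dots,\mu_4$:

$$\mathrm{d}x(t) = a\,x(t)\,\mathrm{d}t + G\,\mathrm{d}W(t),$$

a four-dimensional Ornstein–Uhlenbeck system with one shared
self-feedback rate $a$ (per year) and diffusion covariance
$GG^\top = \mathrm{diag}(s)\,R\,\mathrm{diag}(s)$ with per-trial diffusion
SDs $s_m$ (words·yr$^{-1/2}$) and correlation $R$. A strongly negative
$a$ means unpredicted performance shifts do not persist to the next
annual visit; the within-occasion correlation $R$ is what makes a
fluctuation on one trial informative about the other trials of the same
visit — the feature that separates diffusion from measurement error.

The practice level $p(t)$ is deterministic between occasions,
$\mathrm{d}p = b\,p\,\mathrm{d}t$, and receives the increment $\gamma$
(words) at the *end* of each occasion, so an occasion's own observation
uses the pre-increment level and baseline scores are practice-free:

$$p_k = e^{b\,\Delta_k}\,(p_{k-1} + \gamma), \qquad p_1 = 0 .$$

Positive $b$ compounds retest gains across visits; negative $b$ makes the
total PE asymptote at $\gamma e^{b\Delta}/(1-e^{b\Delta})$ for a fixed
interval $\Delta$. Observed scores add measurement error:
$y_{mk} = \mu_m + p_k + x_m(t_k) + \varepsilon_{mk}$,
$\varepsilon \sim N(0, \sigma^2)$, i.i.d. across trials and occasions.
Carrying within-visit dependence on the diffusion side (not on a
correlated error matrix) is deliberate: a single error SD is reported, and
correlated disturbances are the quantity with predictive meaning.

Exact discretization over an arbitrary step uses
$\Phi(\Delta) = e^{A\Delta}$ and the integrated diffusion from the
augmented-matrix (Van Loan) exponential (`discretize_matrix()`); the
scalar closed forms (`discretize()`) switch to the series limit
$q\,\Delta$ when $|a| < 10^{-8}$ to avoid 0/0. The baseline latent state is
drawn from the stationary trial covariance $GG^\top / (-2a)$, optionally
rescaled by `initial_state_sd_scale` (default 1); this requires $a < 0$,
which the estimation link (negative softplus) enforces by construction.
The practice row carries no diffusion: within-subject stochastic
variation in PE would not be separately identified from trial diffusion
with at most four occasions, so individual differences in PE enter
through the random-effect layer instead.

## Likelihood

Two independent evaluations of the same Gaussian marginal likelihood are
implemented: a sequential Kalman filter over the 5-dimensional state
(`kalman_loglik()`), with missing trials handled by row-deleting the
observation equation and the practice pulse applied to the state mean
after each update, and a joint multivariate-normal evaluation over all
observed entries (`joint_gaussian_oracle()`). They agree to $10^{-8}$ on
randomized instances; the test suite enforces this. A variance floor of
$10^{-8}$ is added to the measurement variance in both routes so that
noise-free degenerate configurations remain well defined — implemented
identically in both so the equivalence is exact, not approximate.

## Hierarchy and estimation

Each subject's unconstrained parameter vector is
$\theta + B d_i + J u_i$: population means $\theta$, covariate-effect
matrix $B$ acting on a design row $d_i$ (MCI and DAT indicators; for
sensitivity models also a standardized covariate and its diagnosis
interactions; for subgroup models the covariate alone), and random
effects $u_i \sim N(0, D)$ on the four manifest means and the practice
gain with a fully correlated $D$ — exactly the random-effect correlations
the analysis reports. Links: identity for means, deviations, practice gain
and practice self-feedback; softplus for SDs; negative softplus for the
trial self-feedback; tanh-based canonical partial correlations for
correlation matrices. Covariate effects act on the unconstrained scale;
for constrained parameters the summary additionally reports the
natural-scale contrast $g(\theta + \beta) - g(\theta)$, since either
reading of such published effects is defensible.

A design point worth stating plainly: the random-effect subset enters the
observation mean *linearly* ($\mu$-shifts directly; the gain through the
per-unit accumulation factors $g_k$), and the practice process is
noise-free, so the random effects integrate out of the Gaussian
likelihood exactly:

$$y_i \sim N\!\big(\mu_i,\; \Sigma_i + A_i D A_i^\top\big),$$

with $\Sigma_i$ the occasion-level covariance implied by the dynamics and
$A_i$ the loading of $u_i$ onto the observations. We therefore optimize
the *exactly marginal* posterior over roughly sixty population parameters
instead of a penalized joint mode over a thousand-plus subject effects:
it is both more accurate (no Laplace or penalized-likelihood
approximation for $u_i$) and far better conditioned. Subject-level
random-effect modes are recovered afterwards in closed form
(`random_effect_modes()`), and a numeric check in the test suite confirms
they maximize the conditional posterior. The practical cost is that
random effects are restricted to the location parameters — the family for
which this marginalization is exact; the reported correlation structure
concerns exactly these.

Optimization is L-BFGS from a deterministic, data-driven start with a
small seed-controlled jitter; the gradient is analytic for the location
block (means, gain and their covariate rows — the closed-form Gaussian
score) and central finite differences elsewhere, and the reported
Gaussian approximation covariance is the inverse of a central-difference
Hessian at the mode. `summarize_fit()` draws from that Gaussian on the
unconstrained scale, transforms each draw, and reports means, SDs and
2.5/97.5% quantiles, flagging intervals that exclude zero at 95% (`*`)
and 90% (`+`).

### Priors

Priors are broad where the data are rich and shrinking where they are
not: manifest means $N(9, 10^2)$ words, trial deviations and practice
gain $N(0, 5^2)$, trial self-feedback $N(0, 2^2)$ pre-transform, diffusion
and error SDs $N(0, 2^2)$ on the softplus scale, covariate effects
$N(0, 2^2)$, random-effect SDs half-normal(1) with the softplus Jacobian
included, correlation parameters $N(0, 1)$.

The practice self-feedback prior is deliberately informative,
$N(0, 0.25^2)$. With one to four occasions per subject the pair
$(\gamma, b)$ sits on a pronounced likelihood ridge: a larger increment
with decaying feedback produces nearly the same expected trajectory as a
smaller increment with none, and only the handful of four-occasion
subjects separate them. Under a diffuse $b$ prior the MAP wanders along
this ridge and the recovered increment inherits that wander. A rate
beyond $\pm 0.5$/yr would imply implausible compounding or collapse of
retest gains within a three-year window, so the tight prior encodes real
subject-matter knowledge rather than convenience; the same weak
identification is visible in the published intervals for this parameter,
which are essentially prior-width. All widths are configurable through
`model_config(priors = ...)`.

## The synthetic cohort

The generator (`default_cohort_config()`, `generate_cohort()`) emulates
the design of the motivating memory-clinic cohort, which is restricted by
a data-use agreement: 126 CU / 85 MCI / 45 DAT subjects; the exact
per-group distribution of one to four annual occasions (dropout is fixed
by design, not outcome-dependent); inter-occasion intervals
$N(1.09, 0.15^2)$ years truncated below at 0.25 (the source design
reports only the 1.09-year mean; the jitter keeps the continuous-time
machinery honestly exercised, and the truncation only guards against
pathological draws — its effect on the mean is below $10^{-6}$); per-group
age, sex (Bernoulli at the reported proportions of women, coded −1/+1)
and education distributions; and generating dynamics equal to the
published diagnosis-groups population estimates with the significant
diagnosis effects applied on the unconstrained scale and non-significant
effects set to zero, keeping recovery targets identifiable.
`sensitivity_generating_effects()` supplies the published significant
covariate moderation for simulating under sensitivity designs.

Two generating quantities are not published and are the package's own
choices, stated once: random-effect SDs of 2.0 words for the immediate
trial means, 2.4 for delayed recall (between-person HVLT trial SDs within
diagnosis groups plausibly sit near 2–2.5 words, delayed recall wider)
and 0.25 words/occasion for the practice gain; and a 0.5 off-diagonal
diffusion correlation (the published correlations concern random effects,
not diffusion — the value is a documented stand-in). The published 5×5
random-effect correlation matrix is used as-is (it is positive definite).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: informative missingness (dropout is
fixed), diagnosis conversion over time, integer score granularity and
floor/ceiling effects (scores are Gaussian by default; integer clipping
to 0–12 is available but off so the generative and fitted models stay
conjugate), and any battery beyond the four recall trials.

## Numerical choices and problem sizes

Tolerances: filter/oracle equivalence $10^{-8}$; discretization
identities $10^{-9}$; transform round-trips $10^{-10}$; innovation
variance floor $10^{-8}$; near-zero-drift switch $10^{-8}$. Ties and
degenerate inputs: empty observation rows are skipped (the practice pulse
still applies); non-positive-definite innovation or marginal covariances
raise errors naming the occasion or subject; a singular Gaussian
approximation advises a ridge rather than silently regularizing.

The test suite exercises the full 256-subject design once (the recovery
checks) and otherwise uses scaled-down cohorts of roughly 20–40 subjects
with the same group structure, occasion pattern and noise levels — the
package's choice of a problem size at which every property is still
informative. The truly noise-free recovery example is run at small but
non-degenerate noise (SDs of 0.02 words): at exactly zero noise the
likelihood surface is a spike on a boundary and no general-purpose
optimizer traverses it reliably; at 0.02 the means are identified to
better than 0.01 words, which is what the check asserts. For the same
reason the fitted-curve overlay check uses a 0.02-word tolerance.

## Known limitations

The Gaussian observation model ignores the 0–12 score bounds, which
matters most for DAT delayed recall near floor. Trial self-feedback and
the diffusion/error split are weakly identified at one to four occasions;
their point estimates shrink materially toward the prior and should be
read with the reported intervals, not as point facts. The MAP/Gaussian
approximation understates skew in the practice-gain posterior on the
ridge described above. Random effects on non-location parameters (e.g.,
per-subject diffusion) are out of scope of the exact-marginalization
design. The fourteen-model suite applies no multiple-testing correction,
mirroring the analysis it reproduces.
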