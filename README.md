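# ctpe — continuous-time dynamic modelling of practice effects

Repeated neuropsychological testing is contaminated by practice effects
(PE): people improve on a memory test partly because they have seen the
same test before. In aging cohorts spanning cognitively unimpaired (CU)
adults, mild cognitive impairment (MCI) and Alzheimer's-type dementia
(DAT), that retest gain is itself clinically informative — reduced or
absent practice gains track diagnostic severity. `ctpe` implements a
continuous-time latent dynamic model that treats the four recall trials of
a 12-word verbal-learning test (three immediate trials and one delayed
trial, scores 0–12 words) as coupled stochastic processes and estimates the
practice effect as a separate latent process, rather than removing it as a
nuisance.

## The model

For subject *i*, the four trial deviations `x(t) ∈ R⁴` follow an
Ornstein–Uhlenbeck system with a shared self-feedback rate and correlated
disturbances, and the practice level `p(t)` is a deterministic process
pulsed at the end of each measurement occasion `t_k`:

    dx(t) = a x(t) dt + G dW(t)              (trial deviations, a < 0)
    dp(t) = b p(t) dt,   p(t_k⁺) = p(t_k) + γ (practice pulse)
    y_m(t_k) = μ_m + p(t_k) + x_m(t_k) + ε,  ε ~ N(0, σ²)

where `γ` is the practice gain in words per occasion, `b` the practice
self-feedback (positive: compounding gains; negative: decaying gains),
`μ_m` the per-trial manifest means, `GG' = diag(s) R diag(s)` the diffusion
covariance and `σ` the measurement-error SD. Observations at irregular
occasion times use the exact discrete-time translation
`Φ(Δ) = exp(AΔ)` with integrated diffusion from the matrix-exponential
(Van Loan) construction.

The hierarchy lets every parameter shift with diagnosis group and
(optionally) standardized age, education, or sex (−1 men / +1 women) on an
unconstrained scale, with correlated subject random effects on the four
manifest means and the practice gain. Because those random effects enter
the observation mean linearly, they are integrated out of the Gaussian
likelihood exactly, and population parameters are estimated by maximum a
posteriori (MAP) with a Gaussian posterior approximation for intervals.
See the methods vignette (`vignettes/practice-effect-dynamics.Rmd`) for
assumptions, priors and numerical choices.

Because the motivating cohort is restricted by a data-use agreement, the
package ships a synthetic-cohort generator that emulates the study design
(256 subjects split 126 CU / 85 MCI / 45 DAT, one to four annual occasions
with a fixed dropout pattern, mean inter-occasion interval 1.09 years,
matched covariate distributions) with generating dynamics set to the
published population estimates.

## Worked example

```r
library(ctpe)

spec <- dynamic_spec(
  drift_trial = -3.47, drift_practice = 0.01,
  diffusion_sd = c(3.8, 3.5, 2.8, 5.5),
  diffusion_corr = matrix(c(1, .5, .5, .5, .5, 1, .5, .5,
                            .5, .5, 1, .5, .5, .5, .5, 1), 4),
  manifest_mean = c(6.1, 8.8, 9.8, 8.5),
  meas_error_sd = 0.3, practice_gain = 0.4
)
spec
#> Continuous-time practice-effect dynamic specification
#>   trial self-feedback      -3.470 /yr
#>   practice self-feedback    0.010 /yr
#>   practice gain             0.400 words/occasion
#>   manifest means         6.10 8.80 9.80 8.50 words
#>   diffusion sd           3.80 3.50 2.80 5.50
#>   measurement error sd      0.300 words

practice_expectation(0.4, 0.01, c(0, 1.09, 2.18, 3.27))
#> [1] 0.000 0.404 0.813 1.226
```

The practice level entering each occasion's observation starts at zero
(baseline performance is practice-free) and accumulates roughly 0.4 words
per occasion; with near-zero self-feedback the gains neither compound nor
decay.

```r
cohort <- generate_cohort(default_cohort_config(), seed = 1)
cohort
#> synthetic cohort: 256 subjects (CU 126, DAT 45, MCI 85)
cohort_descriptives(cohort)[, c(1:4, 8:12)]
#>   group   n pct_women age_mean occ_1 occ_2 occ_3 occ_4 mean_interval
#> 1    CU 126      75.4     70.8    20    45    40    21          1.10
#> 2   MCI  85      60.0     72.7    34    23    20     8          1.09
#> 3   DAT  45      66.7     70.5    20    19     6     0          1.12
```

Fitting the diagnosis-groups model and summarizing (a few minutes for the
full 256-subject cohort):

```r
fit  <- fit_map(cohort, model_config(), seed = 1)
smry <- summarize_fit(fit, n_draws = 4000, seed = 1)
smry[smry$parameter %in% c("practice_gain", "trial_1", "dat:trial_4"), ]
#>       parameter    mean     sd   ci2.5  ci97.5 flag
#> 8 practice_gain  0.6331 0.2356  0.1620  1.1001    *
#> 9       trial_1  5.8507 0.2214  5.4338  6.2865    *
#> 48  dat:trial_4 -5.4610 0.4967 -6.4315 -4.5052    *
```

`practice_gain` is the estimated population retest gain in words per
occasion (generating value 0.399 — well inside the interval; with at most
four occasions per subject its posterior is genuinely wide), `trial_1` the
Trial-1 manifest mean for the CU reference group, and `dat:trial_4` the
shift in delayed-recall mean associated with a DAT diagnosis. The `flag`
column marks 95% intervals excluding zero (`*`) and 90% intervals
excluding zero (`+`). `run_plan(study_plan(), cohort)` fits the full
fourteen-model suite (diagnosis groups, three sensitivity models, nine
subgroup models, the reparametrized variant), and `expectation_curves()`
produces the tidy per-scenario expected-score trajectories behind the
usual expectation plots.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/ctpe simulate --seed 7 --out cohort.csv
Rscript inst/scripts/ctpe fit cohort.csv --model diagnostic --out summary.csv
```

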