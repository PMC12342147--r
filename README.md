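# rrstpipe

Simulation and analysis pipeline for two-alternative forced-choice (2AFC)
respiratory resistance discrimination experiments in clinical group
designs — the respiratory resistance sensitivity task (RRST) as used to
compare interoception between patients with functional neurological
disorder (FND) and healthy controls (HC).

The package is aimed at researchers who run (or re-analyse) breathing-
obstruction discrimination tasks and want a fully testable, reproducible
version of the complete analysis chain:

* **psi adaptive staircase** — Bayesian stimulus placement on a gridded
  joint posterior over threshold and slope, minimising expected posterior
  entropy each trial;
* **Weibull psychometric fitting** — maximum (optionally penalised)
  likelihood for
  `P(correct | x) = γ + (1 − γ − λ)(1 − exp(−(x/α)^β))`
  with γ = 0.5, the per-subject threshold at the 75 %-correct point and
  **respiratory sensitivity = 17 − threshold** (17 = device ceiling);
* **metacognition** — the type-II ROC area (AUROC2): how well trialwise
  confidence (0–100) separates a subject's correct from incorrect trials,
  with an exhaustive pairwise oracle as an independent cross-check;
* **drift-diffusion modelling** — Wiener first-passage likelihood,
  exact-bridge simulator, closed-form EZ inversion, and a hierarchical
  Bayesian fit with group-varying drift rate *v*, boundary separation *a*
  and non-decision time *t*, DIC model comparison, and posterior group
  contrasts such as P(v&#8201;HC > v&#8201;FND);
* **group statistics** — Welch *t* with Cohen's *d*, Mann–Whitney *U*,
  Pearson χ², odds ratios, correlations, Bonferroni / Benjamini–Hochberg
  adjustment, and interaction regressions (HC as reference level);
* **synthetic cohorts** — a generator calibrated to published cohort
  summary statistics (43 FND / 48 HC; sensitivity means 2.88 / 3.53;
  median AUROC2 ≈ 0.57; RT medians ≈ 1 s; a drift-rate deficit in FND; an
  SDQ-20–sensitivity correlation of ≈ −0.38 in FND only), carrying full
  latent ground truth for parameter-recovery testing.

## Worked example

Group contrast from published summary statistics (mean, SD, n per group):

```r
library(rrstpipe)

welch_t(mean1 = 3.527, sd1 = 1.128, n1 = 48,   # HC sensitivity
        mean2 = 2.882, sd2 = 1.619, n2 = 43)   # FND sensitivity
#> # A tibble: 1 × 10
#>   test    estimate statistic    df p_value ci_low ci_high effect_size    n1    n2
#>   <chr>      <dbl>     <dbl> <dbl>   <dbl>  <dbl>   <dbl>       <dbl> <dbl> <dbl>
#> 1 welch_t    0.645      2.18  74.0  0.0324 0.0557    1.23       0.467    48    43
```

The HC group is 0.645 sensitivity units better; Welch's t(74) = 2.18 gives
p = 0.032 and a pooled-SD Cohen's d of 0.47 — a moderate deficit in the
patient group.

A small end-to-end synthetic study — generate a cohort, run one adaptive
session per subject, fit everything, and score recovery against the
latent truth:

```r
study <- simulate_study(cohort_spec(n_fnd = 10, n_hc = 10),
                        session_config(), seed = 42, mode = "lognormal")
rep <- run_analysis(study$trials, study$subjects, seed = 42, ddm = FALSE)
rep
#> RRST analysis report
#>   subjects: 20 included / 20 total (0 excluded)
#>   sensitivity: HC 3.59 (2.85) vs FND 3.49 (3.33), d = 0.03, p = 0.942
#>   metascore medians: HC 0.568 vs FND 0.586, p = 0.734

recovery_report(rep, study$truth)
#> # A tibble: 3 × 5
#>   quantity       bias  rmse correlation     n
#>   <chr>         <dbl> <dbl>       <dbl> <int>
#> 1 threshold75 -0.0496 3.58        0.241    20
#> 2 sensitivity  0.496  3.09        0.202    20
#> 3 log_slope   -0.209  0.537       0.474    20
```

At 50 trials per session and 10 subjects per group the fitted thresholds
are unbiased but noisy (see the recovery RMSE), so the latent group effect
is attenuated in the measured contrast — exactly the behaviour the
recovery report is there to quantify. Longer sessions
(`session_config(n_trials_total = 150)`) roughly halve the threshold
error; the methods vignette (`vignettes/rrst-methods.Rmd`) discusses the
measurement-precision ceiling imposed by the 0–17 stimulus range.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (psychometric curve, type-II ROC, staircase
posterior, drift-rate posteriors). A thin command-line wrapper lives at
`inst/cli/rrst_pipeline.R`:

```sh
Rscript inst/cli/rrst_pipeline.R all --seed 1 --out runs/demo
```

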