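---
title: "Models and methods behind rrstpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rrstpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrstpipe)
```

`rrstpipe` implements the full analysis chain for a two-alternative
forced-choice (2AFC) respiratory resistance sensitivity task (RRST) in a
clinical two-group design (patients with functional neurological disorder,
FND, versus healthy controls, HC), together with a synthetic-cohort
generator that makes every stage testable by parameter recovery. This
vignette explains the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic tests can show.

## The task and its measures

Each trial presents two paced inhalations, one of which is obstructed by a
stimulus level between 0 and 17 units (17 = maximal compression of the
breathing tube). The participant reports which breath felt more obstructed
and rates confidence on a 0–100 visual scale within a 6 s deadline.
Sessions default to 50 measured trials in three blocks after six practice
trials. Four subject-level measures are derived:

* **Respiratory sensitivity** — 17 minus the obstruction level at which
  the fitted psychometric function reaches 75 % correct; higher is more
  sensitive.
* **Decision precision** — the slope of the fitted psychometric function.
* **Metascore** — the area under the type-II ROC curve (AUROC2):
  how well confidence discriminates the subject's own correct from
  incorrect trials, independently of first-order accuracy.
* **Drift-diffusion parameters** — drift rate *v* (evidence accumulation
  efficiency), boundary separation *a* (decision caution) and non-decision
  time *t* (sensory/motor delay), estimated hierarchically from choices
  and response times.

## Weibull psychometric model

Performance is modelled as
\[
P(\text{correct} \mid x) \;=\; \gamma + (1 - \gamma - \lambda)
  \bigl(1 - e^{-(x/\alpha)^{\beta}}\bigr),
\]
with guess rate \(\gamma = 0.5\) (2AFC), lapse rate \(\lambda\), scale
\(\alpha\) and shape (slope) \(\beta\). The reported threshold is the 75 %
point of the full fitted curve (analytic inversion; equal to
\(\alpha(\ln 2)^{1/\beta}\) when \(\lambda = 0\)), and sensitivity is
\(17 - \text{threshold}\).

`fit_weibull_mle()` maximises the Bernoulli likelihood from eight
deterministic starts (scale starts at data quantiles crossed with two
slope starts), so fits are seedless and reproducible. Two estimation
choices deserve comment:

* **Lapse handling.** The general-purpose fitter estimates
  \(\lambda \in [0, 0.1]\) by default. With stimuli capped at 17 — close
  to typical scale values — the upper asymptote is unsampled and
  \(\lambda\) trades off against \(\alpha\) along a likelihood ridge; at
  10 000 uniform trials this widens the scale error to roughly ±0.6 units,
  against ±0.2 when the lapse is fixed. Both modes are supported.
* **Slope regularisation in the pipeline.** Staircase sessions concentrate
  trials near the threshold, leaving the slope weakly identified; an
  unpenalised refit occasionally collapses the slope and extrapolates the
  threshold far outside the tested range (the same instability shows up in
  published slope distributions from this task, whose interquartile ranges
  span orders of magnitude). The per-subject pipeline refit
  (`fit_subjects()`) therefore fixes the lapse at the staircase's 0.02 and
  adds a weak log-normal penalty on the slope
  (meanlog \(\log 3\), sdlog 0.7). In head-to-head recovery on staircase
  sessions this penalised fit dominates the pure MLE (threshold RMSE
  ≈ 1.4 versus 1.9–3.1 units at 150 trials). Pure maximum likelihood
  remains the default of `fit_weibull_mle()` itself and is what the
  grid-search oracle tests check.

## Psi adaptive staircase

`init_psi()` builds a gridded joint posterior over \(\alpha\) (60 points,
0.5–17) and \(\beta\) (30 log-spaced points, 0.5–32), with \(\gamma\)
fixed at 0.5 and \(\lambda\) at 0.02 during the staircase. Each trial
presents the candidate level (61 levels, 0–17) that minimises the expected
Shannon entropy of the joint posterior under the current posterior
predictive; exact ties resolve to the lower, less aversive level. After
the outcome the posterior is renormalised Bayes-fashion. The staircase
provides stimulus placement; the reported per-subject parameters come from
the separate refit described above.

Two properties of this procedure matter for interpretation:

* A guessing observer (50 % correct everywhere) drives the posterior
  towards the top of the threshold grid — the correct inference that no
  threshold lies within the tested range — rather than leaving it at the
  prior. The staircase cannot conjure an *interior* threshold from noise.
* At 150 trials the posterior SD for a threshold near 14 units is about
  1 unit, and this matches the across-seed spread of the posterior mean
  (the inference is calibrated). This is close to the information-theoretic
  floor: even with the slope known and trials placed optimally, the Fisher
  bound for \(\alpha^* = 14\) under this design is an error SD of ≈ 0.8.
  Single-session thresholds from this task are honest but noisy;
  group-level contrasts inherit that attenuation (see below).

## Metacognition: type-II ROC

`type2_roc()` sweeps thresholds over the unique confidence values
(inclusion by \(\ge\)); the area under the (false-alarm, hit) polyline is
computed by the trapezoid rule. This equals the Mann–Whitney-type pairwise
statistic — the probability that a random correct trial carries higher
confidence than a random incorrect one, ties counting one half — which is
implemented independently as `auroc2_pairwise_oracle()` and checked to
1e-12 in the tests. Confidence is used raw (no binning). When a subject
has no errors (or no correct trials) the score is undefined and is
reported as missing, never silently imputed at 0.5.

## Drift-diffusion model

Choices and response times are decomposed with an unbiased accuracy-coded
Wiener diffusion: start point \(a/2\), diffusion scale 1, upper boundary =
correct. The first-passage density uses the standard small-time /
large-time series expansions with adaptive truncation to an absolute
tolerance of 1e-7. The simulator is Euler–Maruyama at \(dt \le 10^{-3}\) s
with a Brownian-bridge crossing correction per step, which removes the
leading \(O(\sqrt{dt})\) boundary-miss bias; simulated choice fractions
match the closed-form absorption probability \(\mathrm{logit}^{-1}(va)\)
and the simulated RT histogram matches the analytic density in the tests.
The closed-form EZ moment inversion (`ez_diffusion()`) serves as an
independent cross-check and supplies starting values; accuracy exactly at
chance is nudged by half a trial (\(1/2n\)) before the logit.

`fit_hierarchical_ddm()` estimates subject parameters under group-level
normal populations. Any subset of \(\{v, a, t\}\) may vary by group; the
rest share one population mean. Sampling is component-wise
Metropolis-within-Gibbs with random-walk proposals whose scales adapt
during burn-in (target acceptance ≈ 0.35); the drift population mean has a
conjugate Gibbs update. Priors are weakly informative: \(\mu_v \sim
N(2, 3)\), \(\mu_a \sim \text{Gamma}(\text{mean } 1.5)\), \(\mu_t\) a
truncated normal within (0.05 s, min RT), population SDs half-normal(0, 1).
RTs below 0.15 s or at the 6 s deadline are excluded as contaminants, and
subjects left with fewer than 30 usable trials (e.g. a subject with no
recorded RTs) are dropped from this stage only. Convergence is declared
only when every stored parameter's batch-means Monte-Carlo error is below
10 % of its posterior SD; a non-converged fit is returned flagged, never
silently accepted. Model comparison uses
\(\mathrm{DIC} = \bar D + p_D\) with \(p_D = \bar D - D(\hat\theta)\),
and `compare_models()` refuses fits whose data fingerprints differ.
Default fits keep 2 000–2 500 samples after 500–600 burn-in — smaller than
the 10 000/1 000 a production analysis would use, chosen so the full suite
runs on one CPU in minutes; the MC-error rule is met at this size.

## Group statistics

The statistics layer mirrors the analysis conventions of clinical
interoception studies: Welch's *t* (accepting raw samples or summary
statistics through one code path, so the two agree exactly) with pooled-SD
Cohen's *d*; Mann–Whitney *U* with exact enumeration for small untied
samples; Pearson's \(\chi^2\) without continuity correction; odds ratios
with log-scale Wald intervals and a flagged Haldane–Anscombe correction
for zero cells; Pearson correlations; Bonferroni adjustment with an
explicit family size (the pipeline uses a family of 4 for the two
interoceptive measures × two clinical scores) and Benjamini–Hochberg FDR
for the four discomfort ratings; and OLS regression with treatment coding
and HC as the reference level, so the main sensitivity effect is the HC
slope and the interaction is the FND-specific slope difference. Test
routing (t versus Mann–Whitney) is configured per variable rather than
auto-detected, for reproducibility.

The cohort-level outlier rule flags subjects whose score deviates strictly
more than 2.5 SD from the pooled (both-groups) mean; flags are recorded,
data are never silently dropped, and the pipeline applies the rule to
sensitivity, the primary outcome.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defines the generative study conditions; its defaults are
calibrated once to the published cohort summary statistics:

| parameter | default | calibration target |
|---|---|---|
| group sizes | 43 FND / 48 HC | recruited cohort after one exclusion |
| threshold means (SD) | 14.12 (1.62) / 13.47 (1.13) | sensitivity 2.88 / 3.53 |
| slope | log-normal, median 3 | interior-range discriminability |
| lapse | 0.02 | conventional |
| confidence coupling | 0.6 | 50-trial median AUROC2 ≈ 0.57–0.59 |
| drift means (SD 0.25) | 0.53 / 0.60 | P(HC > FND) ≈ 0.89 under ideal estimation |
| boundary means (SD 0.30) | 1.75 / 1.85 | RT medians ≈ 1 s; weak caution contrast |
| non-decision time | 0.33 (0.08) s | plausible sensory–motor delay |
| SDQ-20 coupling (FND) | −2.86 per unit | r ≈ −0.38 in FND, 0 in HC |
| medication prevalence | 44 % / 4 % | printed 2×2 counts |

Because those targets are *post-exclusion* statistics, the latent
threshold population carries the upstream screen: draws outside the pooled
±2.5 SD band are redrawn. Re-applying the exclusion rule to a generated
cohort then flags 0–1 subjects in ≈ 93 % of seeds, matching the single
exclusion reported in this design's reference cohort.

Responses come in two modes serving the two analysis layers. In
`"lognormal"` mode correctness is Bernoulli with probability \(P(x)\) from
the same Weibull evaluator the fitter uses (single source of truth) and
RTs are a fast lognormal: use this mode to study the staircase, the
psychometric fits and the group-statistics layer. In `"ddm"` mode (the
session default, matching the generator's role of providing
drift-diffusion ground truth) choice and RT are drawn jointly from the
subject's diffusion process, so accuracy is \(\mathrm{logit}^{-1}(va)\) —
about 0.72–0.75 under the default calibration, stimulus-independent — and
the fitted drift carries the configured group deficit; psychometric
thresholds estimated from ddm-mode sessions are correspondingly not
meaningful. In both modes the trial's internal evidence is
\(E \sim N(\Phi^{-1}(p), 1)\) conditioned on \(\mathrm{sign}(E)\) matching
the trial's correctness (with \(p\) the mode's accuracy), and confidence
is a logistic transform of \(|E|\) times the coupling plus noise, scaled
to 0–100; zero coupling gives AUROC2 = 0.5 in expectation.

Features of real data the generator does **not** emulate: breath-by-breath
airflow physiology and its serial dependence, fatigue and attention drift
across blocks, discomfort-driven response biases, item-level questionnaire
structure, and any stimulus-dependence of the diffusion drift within a
session. Passing recovery tests therefore demonstrates the pipeline's
internal correctness under its stated assumptions, not robustness to these
real-world effects.

## Measurement attenuation, by design

At the default 50 trials per session the threshold estimate carries an
error of ≈ 2 units RMSE (≈ 1.4 at 150 trials), dominated by subjects whose
true threshold lies near the 17-unit device ceiling, where no estimator
can identify the 75 % point. Fitted sensitivity therefore correlates
≈ 0.6–0.7 with the generating truth, and cohort-level contrasts are
attenuated relative to the latent effect (a latent standardised difference
of 0.47 typically measures as ≈ 0.25–0.35 with wider SDs). The
session-size phrase "three blocks of a total of 50 trials" is ambiguous
(50 total versus 50 per block); the default is 50 total with
`session_config(n_trials_total = ...)` as the override, and the recovery
report quantifies the gain from longer sessions.

## Reproducibility choices

Every stochastic stage takes an explicit integer seed; `simulate_study()`
expands its seed into independent per-subject substreams so single
sessions reproduce in isolation, and `run_analysis()` re-running on the
same inputs yields byte-identical reports. CSV artefacts are plain comma-
separated UTF-8 with empty cells for missing values (a subject whose RTs
were recorded by the experimenter on their behalf simply has blank RT
cells and is excluded from the DDM stage only). `run_simulation()` never
overwrites outputs without `force = TRUE`.
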