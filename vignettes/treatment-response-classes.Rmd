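---
title: "Model-based treatment response classes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based treatment response classes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcfit)
```

This vignette documents the statistical model behind `trcfit`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the design
choices that were genuinely open.

## The mixture model

Serial HAM-D totals are analysed on the scale $y = \ln(\text{HAM-D} + 0.5)$;
the offset keeps a score of 0 finite and the log makes the predominantly
exponential-looking symptom decline approximately linear. Patient $i$'s
regularized trajectory $y_{it}$, $t = 0, \dots, T_i$ (weeks, baseline $= 0$)
is assumed to follow one of $K$ latent classes. Class $k$ is a line with
intercept $I_k$, slope $S_k$ (ln-units per week) and i.i.d. Gaussian
residuals with SD $\sigma_k$; $\pi_k$ is its prevalence. The observed-data
log-likelihood is

$$\ell = \sum_i \log \sum_k \pi_k \prod_t
  \mathcal{N}\!\left(y_{it};\, I_k + S_k t,\, \sigma_k^2\right),$$

with one responsibility $z_{ik}$ per *patient*: whole trajectories are the
exchangeable units. This is deliberately the simplest member of the
mixture-of-regressions family — per-class fixed intercept and slope, no
random effects by default. A per-patient random intercept is available in
the generator (`random_intercept_sd`) as a robustness lever, but the
fitting model keeps patients exchangeable within class; with it, both EM
steps reduce to six sufficient statistics per patient
($n_i, \sum t, \sum t^2, \sum y, \sum ty, \sum y^2$), which is what the
compiled EM core iterates on. Consequences of the simplification: within-
class heterogeneity inflates $\sigma_k$ rather than being attributed to
individual baselines, and residual autocorrelation (not modelled; see
limitations) makes the effective number of observations per patient
smaller than nominal.

## EM, restarts, degeneracy

* **E-step.** $z_{ik} \propto \pi_k e^{\ell_{ik}}$, normalized per patient
  in log space (log-sum-exp); the result is exact relative to the naive
  computation whenever no underflow occurs. If every component underflows
  for a patient, a uniform posterior is assigned with a warning.
* **M-step.** Per component, weighted least squares of all ln values on
  week, each patient's rows weighted by $z_{ik}$; $\sigma_k^2$ is the
  weighted mean squared residual; $\pi_k$ the mean responsibility.
* **Initialization.** A seeded random hard partition of patients. Simple,
  reproducible, and appropriate for a multi-restart design
  (`fit_restarts()`, default 200 restarts; the best converged
  log-likelihood wins).
* **Convergence.** Relative log-likelihood change below `tol` (default
  `1e-8`), at most `max_iter = 500` iterations. The per-iteration
  log-likelihood trace is retained; monotonicity (within `1e-9`) is
  asserted in the test suite.
* **Degeneracy guards.** $\sigma$ floor `1e-4` ln-units; a component whose
  effective weight falls below one patient aborts the run. Such runs count
  as non-converged, which is also how the fitting reproduces the
  qualitative behaviour that extreme class counts fail to converge on
  realistic cohorts.

## Model selection by ICL

With $p = 3K + (K - 1)$ free parameters,
$\mathrm{BIC} = -2\ell + p\ln N$,
$\mathrm{ENT} = -\sum_{ik} z_{ik}\ln z_{ik}$, and
$\mathrm{ICL} = \mathrm{BIC} + 2\,\mathrm{ENT}$; the selected $K$ minimizes
ICL among class counts with a converged solution. Two open choices were
resolved as follows and are switchable:

* **$N$ in the BIC** is the number of *patients*, not observations —
  trajectories are the units being clustered
  (`information_criteria(n_unit = "observations")` for the alternative).
* **Parameter count** includes $\sigma_k$ per component
  ($3K$ line parameters plus $K-1$ free weights).

Components are reported sorted ascending by slope (C1 = fastest
improvement), ties broken ascending by intercept.

## Projection, proportions, shortened windows

`assign_fixed()` classifies any regularized cohort under frozen
coefficients (a single E-step; no refitting) and reports the fixed-model
log-likelihood, the classification log-likelihood (complete-data
log-likelihood at the hard labels), entropy and ICL. Class proportions of
two samples are compared with a Pearson χ² test of **homogeneity** on the
$K \times 2$ count table ($df = K - 1$): both samples are random draws, so
neither defines fixed expected proportions (a goodness-of-fit reading
would treat the discovery proportions as known). `truncate_and_assign()`
restricts each patient's likelihood to their first $m$ weekly values —
"using fewer coefficients" is read as shortening the observation window,
the only reading consistent with a weeks axis — and `truncation_curve()`
traces the Pearson correlation between cluster-derived slopes under the
truncated and full windows, which is exactly 1 at the full window.

## Outcome markers and validation statistics

Response (≥ 50% raw-score decrease) and remission (raw < 10) are evaluated
at the last observed week; the *discharge visit*, not the best value of
the course, is used. The episode-mean severity is the mean over all
regularized weekly values up to discharge — including interpolated ones —
since an "average of the episode" is otherwise undefined on an irregular
grid. One-way ANOVAs report Cohen's
$f = \sqrt{\eta^2 / (1 - \eta^2)}$ with labels negligible/small/medium/
large at 0.10/0.25/0.40; univariate item–class associations use the
likelihood-ratio test of a Gaussian linear model against the intercept-only
model ($\chi^2_{K-1}$).

## The prediction layer

Random-forest regression (the `ranger` implementation) with
`mtry = floor(sqrt(D))` and 2,000 trees by default. Feature sets: model 0 =
50 baseline items; model 1 = +21 baseline HAM-D single items (71); model
2 = +early partial response, a ≥ 25% decrease by week 2 (51); model 3 =
both (72). Categorical items keep their integer coding, as in the item
catalogue. Decisions taken where the procedure was underdetermined:

* **Explained variance** uses out-of-bag predictions (squared Pearson
  correlation with the target, then the usual
  $1-(1-R^2)\frac{n-1}{n-D-1}$ adjustment): the analysis is a single
  pooled-sample fit, and OOB avoids resubstitution optimism without a
  held-out split.
* **Overall model p-value** comes from a seeded target-permutation null of
  $R^2$ — distribution-free and forest-compatible, since no parametric
  null for forest $R^2$ exists.
* **Permutation importance** is Altmann-style: the target is permuted
  `n_perm` times, the forest refitted, and each feature's null importance
  distribution collected; $p = (1 + \#\{null \ge obs\})/(1 + n_perm)$,
  so $1/(n_{perm}+1)$ is the estimator floor. 10,000 permutations is the
  full-scale setting; calibration tests use far fewer.
* **Classes from slopes.** Slope-target regressions are turned into class
  predictions by mapping each predicted slope to the nearest component
  slope (ties to the lower class index); per-class accuracies are
  one-vs-rest $(TP+TN)/(TP+FP+TN+FN)$.
* **Fisher-Z comparison** of two $R^2$ values treats the samples as
  independent; with $r = +\sqrt{R^2}$,
  $Z = (\operatorname{atanh} r_a - \operatorname{atanh} r_b) /
  \sqrt{1/(n_a-3) + 1/(n_b-3)}$. For two models fitted on the same
  patients this is conservative in neither direction guaranteed — a
  dependent-sample variant would need the cross-model correlation, which
  the OOB machinery does not provide.

## The synthetic-cohort generator

`generate_cohort()` draws each patient's class from the mixing weights and
emits ln-scale values $I_k + S_k t + \varepsilon$ at the scheduled visit
weeks of the design — weekly to week 6 then bi-weekly to 16 with a maximum
total of 63 (MARS-like inpatient design), or weekly to week 12 with
maximum 52 (GENDEP-like trial design). Raw scores are
$\operatorname{round}(e^y - 0.5)$ clipped to the score range: the exact
inverse of the forward transform, keeping scores integer and bounded.
Choices worth knowing:

* **Default components.** Seven classes with slopes −0.30 to −0.005
  ln-units/week, intercepts near $\ln 22$ (moderate-to-severe baselines),
  residual SD 0.15 and weights 0.16/0.18/0.16/0.10/0.15/0.14/0.11 — spanning
  fast, essentially complete response (discharge around week 4–5, all
  remitted) to treatment resistance (full stay, no remission), the range a
  naturalistic inpatient cohort shows.
* **Eligibility** (baseline ≥ 14) is enforced by redrawing a patient's
  noise while keeping the drawn class, so label frequencies match the
  weights exactly; the induced truncation of the intercept distribution is
  negligible for intercepts well above $\ln 14.5$.
* **Discharge** is an invented censoring rule — raw score below 10 at two
  consecutive scheduled visits from week 2 on ends the series there — that
  reproduces the coupling of class and length of stay (fast class ≈ 4–5
  weeks, resistant class the full window) without extra parameters. Real
  discharge decisions involve unmodelled clinical judgement.
* **Missingness**: 7.1% of week 1–6 interior visits, missing completely at
  random; baseline and the discharge visit are never removed.
* **Clinical items** are unit-variance Gaussians with per-class mean
  shifts; dichotomous/categorical items threshold the latent Gaussian.
  The informative items follow the observed direction patterns
  (neuroticism, harm avoidance, episode duration, weighted life events and
  the SCL scales increase from fast to slow classes; extraversion
  decreases) and each shift vector is rescaled so the population Cohen's
  $f$ equals its target (0.355 neuroticism, 0.341 harm avoidance, 0.153
  episode duration, …) under the mixing weights. The 21 baseline HAM-D
  single items are generated uninformative — matching the observation that
  unfolding baseline psychopathology adds no predictive signal beyond the
  summary scales.
* **Residuals are independent** within patient; the true error structure
  of weekly ratings is plausibly autocorrelated and is left as a
  configuration extension. No medication assignment, center effects or
  randomization scheme is simulated.

What passing tests on this generator show — and do not show. They show the
estimator machinery is correct (oracle equivalence, EM monotonicity),
that the ICL procedure recovers a true class count under realistic
separations, sample sizes and censoring, and that the qualitative
prediction patterns (cluster-derived slopes better predicted than
individual slopes; early partial response adding signal) follow from
class-coupled covariates. They do not certify behaviour under model
misspecification — nonlinear trajectories, autocorrelated or heavy-tailed
residuals, informative dropout — all of which real cohorts contain.

## Numerical choices and degenerate inputs

* Interpolation of missing and bi-weekly-skipped visits is **linear on the
  raw scale**, then transformed; ln-scale interpolation differs by
  Jensen's inequality and is available via `scale = "ln"`. No
  extrapolation: trailing missingness truncates the series.
* A series with a single observed visit is kept (the mixture likelihood
  handles any length) but flagged unusable for individual-slope OLS.
* Posterior ties take the lowest class index; slope-sorting ties break by
  intercept.
* Model JSON serializes floats with 17 significant digits, so round trips
  are bit-exact.
* Seeds: every stochastic operation takes an explicit integer seed;
  derived sub-seeds stay below $2^{31}$.

## Problem sizes in the test suite

The suite exercises the estimators at the sizes the procedures are meant
for while staying quick to run: recovery checks use cohorts of 800
patients with 20 restarts over k = 2–10 and 20 seeds per setting;
parameter recovery uses the full 200 restarts at k = 7; the prediction
pattern uses 1,000 patients with 300-tree forests over 20 seeds; the
calibration checks use 200 replicates. Full-scale settings (200 restarts
everywhere, 2,000 trees, 10,000 importance permutations) remain the
package defaults.

## Known limitations

Linear class means only (no splines or quadratic courses); no
covariate-dependent mixing weights; the χ² proportion test and the
Fisher-Z comparison ignore the pairing of samples where pairing exists;
OOB-based $R^2$ can differ from a strict held-out estimate; the generator's
Gaussian covariates understate the tail behaviour of real count-valued
clinical items.
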