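---
title: "Methods: neonatal mortality scoring and its evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal mortality scoring and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnsat)
```

## The clinical problem

Outborn neonates — infants delivered at home or in lower-level units and
transferred to a tertiary centre — die at substantially higher rates than
inborn infants, and much of that excess is decided in the first hours:
hypothermia, hypoglycaemia, hypoxia and delayed transfer are all
modifiable. A useful admission score must therefore be quick, need no
invasive measurement, and discriminate mortality well in both term and
preterm infants.

`msnsat` implements two such scores and the full statistical machinery for
evaluating them on a cohort table (one row per infant: demographics,
admission vitals, transfer timing, outcome).

## The scores

**SNS.** Seven admission findings each earn 0 (most abnormal), 1, or 2
(normal) points: respiratory effort, heart rate, mean blood pressure,
rectal temperature, capillary refill time, first blood glucose after
admission, and SpO₂ in room air. The total ranges 0–14; ≤ 8 is the
conventional mortality cut-off. Rectal temperature and *first* glucose are
deliberate: the first glucose reflects the infant's state before any
corrective infusion, and rectal measurement is the more accurate
temperature route at admission.

**MSNS-AT.** Three transfer-level variables are added: gestational age
(< 32 weeks 0 pt, 32–36 1 pt, ≥ 37 2 pt), birth weight (< 1500 g 0 pt,
1500–2499 1 pt, ≥ 2500 2 pt), and time from birth to admission (≥ 12 h
0 pt, 6–12 h 1 pt, < 6 h 3 pt). The admission-time row is deliberately
asymmetric — early arrival carries the largest protective weight and there
is no 2-point bin. Totals range 0–21, with cut-off ≤ 10 and risk strata
≤ 7 (high), 8–15 (intermediate), ≥ 16 (low).

### Bin-edge conventions

Printed point tables leave edges ambiguous, so the package fixes them
explicitly and property-tests that the bins partition each measurement's
physiologic sanity range: printed closed ranges (`40–60`, `85–92`, `3–5`,
`100–160`, `30–39`, `36–36.5`) are closed intervals; printed strict bounds
(`<40`, `>60`, `>5`, `<3`, `>39` …) are strict; and the one edge printed in
two bins — temperature 36.5 °C — goes to the higher-scoring (less abnormal)
side, so 36.5 scores 2. For the added variables: GA 32 → 1 pt, 37 → 2 pt;
BW 1500 → 1 pt, 2500 → 2 pt; admission at exactly 6 h is intermediate
(1 pt) and at exactly 12 h late (0 pt). The 12 h late-admission edge
follows the point table (the accompanying prose's "after 13 h" is treated
as a rounding of the same bin, not a different rule).

Two findings have no printed bin at all. Rectal temperature above 37.5 °C
(hyperthermia) and a respiratory rate below 40/min without apnea or
grunting are both abnormal, but silently scoring them 2 (normal) would be
clinically wrong and scoring 0 would overstate severity; each defaults to
1 point and is exposed in `sns_config()` so users can audit the choice.
Missing components are always an error — the score is defined only on a
complete record, and no imputation is ever attempted.

## The statistics

All estimators are implemented in the package and each is cross-checked in
the test suite against an independent route (base R, the `survival`
package, `pROC`, or brute-force enumeration):

* **Odds ratios** use the cross-product with the Woolf log-method CI,
  `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))`, chosen because it exactly reproduces
  the published intervals from their printed cells. Zero-cell tables are
  reported *undefined* rather than corrected, with an optional
  Haldane–Anscombe mode; no continuity correction otherwise.
* **Chi-square** is plain Pearson without Yates correction.
* **Mann–Whitney U** enumerates the exact null law over all
  `choose(m+n, m)` labelings when the pooled size is ≤ 12 (exact even under
  ties); otherwise a midrank normal approximation with tie-corrected
  variance and a 0.5 continuity correction. The correction matters: without
  it the approximation can miss the exact two-sided p by up to 0.07 at
  m = n = 6, with it the gap stays below 0.016 on continuous data.
* **ROC/AUC** uses the rank (Mann–Whitney) identity, which equals the
  trapezoidal area under the empirical curve and handles ties as half
  pairs. Cut-offs maximize Youden's J, ties resolved toward the smaller
  threshold. The event direction is always explicit, because low scores
  predict death while long admission times also predict death.
* **Kaplan–Meier / log-rank** are the standard product-limit estimator and
  the observed-minus-expected statistic with hypergeometric variance; at
  tied times deaths precede censorings.
* **Cox regression** maximizes the Breslow-ties partial likelihood by
  Newton–Raphson with step-halving from β = 0, on internally standardized
  covariates, converging when the largest update falls below 1e-8 (at most
  100 iterations). Standard errors come from the observed information.
  Monotone likelihood (complete separation) is detected by coefficient
  divergence and flagged `converged = FALSE` with a warning — never
  returned silently. Time runs from admission; the event is in-hospital
  death, survivors are censored at discharge.
* **Hazard-probability AUC**: the model-comparison device scores each
  fitted Cox model by the ROC AUC of its per-subject risk score against
  the death indicator, with a Hanley–McNeil 95% CI. The risk score is the
  linear predictor βᵀx; any monotone transform of it (e.g.
  1 − S(t*)^exp(βᵀx)) yields the identical AUC, so the choice is
  immaterial and documented rather than configurable.

## The pipeline

`run_analysis()` executes the stages in the order a score-validation study
reports them: validation → scoring → subgroup split (all / preterm < 37 wk
/ term) → rank comparisons → contingency associations → ROC and cut-offs →
Kaplan–Meier and log-rank on the 6.5 h admission split and on the risk
strata → Cox models with hazard-probability AUCs → the adjusted
risk-stratum model. Every number in the report is produced by exactly one
`stats`/`survival` operation; reports are versioned, deterministic, and
serialize to JSON plus per-table CSVs.

Model comparison fits both *score-only* models (whose hazard AUC equals the
score's own AUC, by monotone invariance) and *adjusted* models (score plus
gestational age, birth weight, admission time, Apgar < 3 and early-onset
sepsis, mirroring how the published comparison was adjusted). The adjusted
pair is reported for completeness, but the qualitative claim tested in the
acceptance suite — that the MSNS-AT ranks preterm deaths at least as well
as the SNS — is evaluated on the score-only models: when two in-sample
models share almost all covariates, the difference of their training AUCs
is dominated by noise and says little about the scores themselves.

Subgroups with fewer than `min_events` (default 2) deaths skip the
ROC/survival/Cox stages with a logged warning; constant covariates within
a subgroup (e.g. no Apgar < 3 infant) are dropped and logged. Cut-offs,
strata edges and the admission-time split are configurable
(`analysis_config()`), including a switch that removes the admission-time
points entirely to quantify their contribution.

## The synthetic cohort generator

No patient-level data accompany the published summaries, so
`generate_cohort()` draws cohorts with the *structure* the analysis
assumes; its defaults are the study conditions and are not tuned per test:

* preterm fraction 0.538; gestational age per stratum (preterm ≈ N(33, 3²),
  term ≈ N(39, 1.3²), rounded to completed weeks);
* birth weight linear in gestation (220 g/week, intercept −5500 g, residual
  SD 350 g) — about 1.8 kg at 33 weeks and 3.1 kg at 39;
* admission time log-normal per stratum (preterm median 4 h, IQR ≈ 3–7;
  term median 12.5 h, IQR ≈ 5–36): published means far above medians imply
  a heavy right tail, which the log-normal reproduces; capped at 3 weeks;
* a latent standard-normal severity factor, increased by 0.15 per
  gestational week below 37, loading (λ = 1) on every vital through an
  ordered probit whose baseline bin probabilities (0.08 / 0.30 / 0.62 for
  0/1/2 points) give a mean SNS near 10.8;
* mortality logistic in severity (+1.4 per SD), gestational deficit
  (+0.18/week) and admission-time category (+0.6 intermediate, +1.2 late),
  with the intercept found by `uniroot` so the mean death probability over
  the realized covariates equals 4.96% exactly — deterministic, with an
  explicit error if calibration is infeasible;
* death times log-normal (median 48 h from admission); survivor discharge
  times grow with prematurity (median 4 days + 2.5 days per week below 37).

One integer seed governs every draw; the same `(params, seed)` reproduces
the cohort byte-for-byte, and the generative per-record death probability
is retained for oracle tests.

**What passing tests do and do not show.** The generator reproduces
published *marginals* and a plausible dependence structure; it does not —
cannot — reproduce the real cohort's joint distribution, its extreme
admission-time outliers (a published mean of 17 ± 65 h against a median of
4 h implies outliers no summary statistic pins down), unit-level practice
changes over a seven-year window, or measurement error in the vitals.
Tests passing on synthetic cohorts therefore validate the *pipeline's
correctness and the scores' qualitative behaviour* (e.g. that adding
gestational-age, weight and admission-time points improves preterm
discrimination when admission timing truly affects hazard), not the
published effect sizes; printed AUCs and hazard ratios from the original
cohort are treated as unreproducible without its data.

## Numerical and design choices

* Problem sizes in the routine checks — 20 replicates of n = 2000 for the
  score-ordering property, 50 cohorts of n = 1000 for hazard-ratio
  recovery, n = 4030 for generator calibration — were chosen to make
  sampling noise small relative to the assertions while keeping a full run
  on one CPU in well under a minute.
* Newton–Raphson on standardized covariates starts at β = 0 and is fully
  deterministic; separation is flagged at |β| > 20 on the SD scale.
* Exact Mann–Whitney enumeration stops at pooled n = 12
  (`choose(12, 6) = 924` labelings); beyond that the corrected normal
  approximation is already accurate.
* Two-sided p-values and 95% intervals throughout; no multiplicity
  adjustment, matching the analysis style the pipeline mirrors.
* Report rounding: ORs/AUCs to 2 decimals and percentages to 1–2 decimals
  in printed output; machine-readable output keeps full precision.

## Known limitations

* The Cox implementation covers Breslow ties only — no Efron weights,
  time-varying covariates, frailty or competing risks.
* Odds-ratio CIs are Woolf (asymptotic) only; no exact (Fisher) intervals.
* The risk-stratum Cox model can separate in small cohorts (the high-risk
  stratum may contain every death); it is then flagged, not repaired.
* The generator's admission-time tail, though heavy, is still log-normal;
  real transfer logistics produce occasional multi-day outliers that can
  dominate means.
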