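---
title: "Methods: first-trimester combined screening for preeclampsia and SGA"
author: "pescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-trimester combined screening for preeclampsia and SGA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescreen)
```

## The screening problem

Preeclampsia (PE) is new-onset hypertension with proteinuria after 20
weeks' gestation; it is *early* when delivery occurs before 34 weeks and
*late* otherwise. Small-for-gestational-age (SGA) is a birth weight
strictly below the 10th percentile for gestational age at delivery. Both
conditions are placenta-related, and both leave a first-trimester
signature: affected pregnancies tend to show raised mean arterial
pressure (MAP) and lowered serum PLGF and PAPP-A at 11+0 to 13+6 weeks.
Combined screening turns that signature into a per-pregnancy risk so
that high-risk women can be offered surveillance and prophylactic
low-dose aspirin while intervention is still effective.

`pescreen` implements the full calculation the way first-trimester
combined screening programmes do it, in four steps, each an explicit,
refittable model.

## The risk model

### Step 1: prior risk from maternal characteristics

Five factors enter the prior: BMI band, ethnicity, parity, history of
PE, and chronic hypertension. Each factor level carries a positive
likelihood ratio (LR), separately for the early and the late horizon,
with reference levels at LR 1. The prior is computed on the odds scale:

$$\mathrm{odds}_{\mathrm{prior}} = \frac{p_0}{1 - p_0}
  \prod_{j=1}^{5} \mathrm{LR}_j, \qquad
  p_{\mathrm{prior}} = \frac{\mathrm{odds}}{1 + \mathrm{odds}}$$

The shipped factor table (`default_prior_model()`) is a placeholder
calibrated to this package's default synthetic population, not a vendor
parameter set: baseline risks of 0.165% (early) and 0.843% (late) are
chosen so that, averaged over the default characteristic mix, the
population prior approximates incidences of 0.24% and 1.07%. BMI is
banded at `<25 / 25–30 / >=30` kg/m²; a continuous specification would
also be defensible, but banding keeps the factor table readable and
refittable from modest case counts.

### Step 2: MoM normalisation

Raw marker levels depend strongly on gestational age, so each
measurement is expressed as a multiple of the expected median (MoM) for
the same gestational day. Expected medians are log10-linear in GA days:

$$\widehat{m}(g) = 10^{\,a + b\,g}$$

PLGF and PAPP-A MoM values are further adjusted for maternal weight
(log-linear in weight centred at a reference, default 53 kg), ethnicity
and smoking (multiplicative factors); MAP MoM is GA-adjusted only. The
defaults anchor the expected medians at GA 89 days — MAP 81.3 mmHg,
PLGF 39.3 pg/mL, PAPP-A 4381 mU/L — with slopes of 0.0002, 0.0065 and
0.016 log10/day respectively. The MAP median uses a GA regression like
the serum markers; a population-constant MAP median is available by
setting its slope to zero. All coefficients live in the model object and
are refittable with `fit_median_model()` (least squares of log10 level
on GA; weight slope from residuals; ethnicity/smoking as geometric-mean
ratios).

log10 MoM values are truncated to $[-1, 1]$ (one decade either side of
the median). Without truncation a single aberrant measurement — a
mis-entered concentration, an assay failure — would carry an unbounded
likelihood ratio into the posterior.

### Step 3: marker likelihoods

The log10 MoM triple $x = (\mathrm{MAP}, \mathrm{PLGF},
\mathrm{PAPP\!-\!A})$ is modelled as multivariate Gaussian under each
hypothesis (unaffected, early PE, late PE), giving the marker LR

$$\mathrm{LR}(x) =
  \frac{\phi(x;\,\mu_{\mathrm{aff}},\,\Sigma_{\mathrm{aff}})}
       {\phi(x;\,\mu_{\mathrm{unaff}},\,\Sigma_{\mathrm{unaff}})}$$

`fit_gaussian_model()` estimates group means and covariances from a
training cohort; pooled-covariance and forced-diagonal modes are
available because it is not known whether production screening engines
use horizon-specific covariances. All density arithmetic is done in log
space through a Cholesky factorisation; a near-singular covariance
falls back to its diagonal with a warning rather than failing.

### Step 4: posterior risk

The posterior combines prior odds with the marker LR:
$\mathrm{odds}_{\mathrm{post}} = \mathrm{odds}_{\mathrm{prior}} \times
\mathrm{LR}(x)$. Early and late PE are treated as two independent
binary problems — separate priors, separate Gaussian pairs, separate
posteriors — rather than a competing-risks formulation; this mirrors
how screening programmes report four risks per pregnancy. Risks are
displayed as "1 in N" with $N = \mathrm{round}(1/p)$, and a cutoff
"1:N" calls a pregnancy screen-positive when $p \ge 1/N$, boundary
inclusive (the convention of aneuploidy screening, from which this
methodology descends). The conventional program default is 1:20.

## Blood-pressure protocol

MAP per reading is $(2\,\mathrm{DBP} + \mathrm{SBP})/3$. Readings are
taken from both arms until consecutive readings differ by at most
10 mmHg systolic and 6 mmHg diastolic; the arm MAP is the mean
per-reading MAP of the *last two* readings, and the final MAP is the
higher arm's. Recorded series are assumed to end at the stable pair, so
an unstable final pair is computed anyway but flagged (`stable =
FALSE`) instead of erroring — analysis data sets contain only the final
series, and discarding them would silently bias the cohort. "Last two
stable measurements" is read as the last two readings of a stabilised
sequence, not any stable pair anywhere in the series.

## Evaluation conventions

* **ROC/AUC** — the AUC is the rank (Mann–Whitney) statistic with
  half-credit for ties, identical to the trapezoidal area under the
  empirical curve; confidence intervals and paired AUC comparisons use
  DeLong's method (via pROC). A bootstrap comparison could be swapped
  in, but DeLong is the standard for paired screening-marker curves.
* **Best cutoff** — the threshold maximising the mean of sensitivity
  and specificity; exact ties break toward the lower FPR.
* **Fixed-FPR operating points** — the smallest score threshold whose
  empirical FPR does not exceed the target, with no interpolation: on a
  finite cohort this is exactly reproducible, which matters more here
  than hitting the nominal FPR exactly. DR and PPV are reported at that
  threshold; probability thresholds are also displayed as "1:N"
  cutoffs.
* **Confidence intervals on rates** — Clopper–Pearson exact intervals
  via beta quantiles. With 8 affected pregnancies in a realistic
  cohort, normal-approximation intervals would be badly misleading;
  the exact interval is conservative but honest at these counts.
* **Group comparisons** — Mann–Whitney U, exact enumeration when
  $n_a n_b \le 400$ without ties, normal approximation with tie
  correction otherwise.

## The synthetic cohort generator

No patient-level data ship with this package. `generate_cohort()`
produces cohorts with the statistical structure of a real screening
population, so every stage — file I/O, BP protocol, MoM engine, risk
engine, evaluation — runs against data whose ground truth is known.

What the generator emulates:

* **Outcome flow** — fixed-count mode reproduces the modelled study
  flow exactly: 3270 pregnancies, 8 early PE (5 with SGA), 35 late PE
  (10 with SGA), 84 SGA without PE. A probabilistic mode draws counts
  at the same rates.
* **Marker distributions** — per outcome group, log10 MoM triples are
  Gaussian with medians and spreads taken from group `median (IQR)`
  summaries, converted by the quartile-spacing rule
  $\sigma = \log_{10}(Q3/Q1)/1.349$. The unaffected PLGF MoM median of
  1.11 (IQR 0.79–1.47), for example, gives $\mu = \log_{10} 1.11$,
  $\sigma = 0.200$. Note the generator reproduces a population whose
  MoM medians deviate from 1 under the shipped median model — exactly
  what happens when a median model calibrated on one population is
  applied to another; refitting the medians (`use_fitted_medians`)
  recentres them at 1.
* **Concentrations** — drawn adjusted MoMs are pushed back through the
  covariate adjustment and the GA median model, so the analysis
  pipeline recovers the drawn values; this closure is tested.
* **Blood pressure** — integer per-arm reading series are engineered so
  the protocol's "average of the last two readings" recovers the
  intended MAP to within 1/12 mmHg, and the stored MAP *is* the value
  the protocol recovers. Readings stay integers, as an automatic
  monitor would record them.
* **Outcomes** — hypertension onset, proteinuria, delivery GA and birth
  weight are drawn so that `classify_pe()` and `classify_sga()`
  reproduce the generating labels exactly; birth weights are drawn
  conditionally below (SGA) or above (non-SGA) the interpolated 10th
  percentile of the shipped reference table.
* **Characteristics** — weight and BMI log-normal, height and age
  normal, from group medians/IQRs; chronic hypertension, smoking, IVF
  and parity as per-group binomials. Parity (55% nulliparous among
  non-PE, 70% among PE) and PE history (2% of parous non-PE, 15% of
  parous PE) are not published for the modelled population and were set
  once to field-plausible values.

What it does not emulate, and hence what passing tests cannot show:
marker–marker correlations are zero by default (they are not published
for this population; a correlation block is available in the config),
real MoM distributions have heavier tails than the Gaussian, assay
drift and analyzer batch effects are absent, and the early-PE group
parameters derive from only eight pregnancies, so their IQRs are noisy
estimates of the population spread. Performance measured on this
generator is an upper bound: in a perfectly Gaussian world the
Gaussian LR is the optimal statistic, so in-sample AUCs (for instance
in the default end-to-end pipeline) run higher than any real cohort
would deliver. The held-out experiments below are the fairer readout.

### The enriched case-control experiment

Rare outcomes make detection-rate estimates on realistic cohorts
extremely noisy: with 8 affected, one pregnancy moves the DR by 12.5
points. The headline experiment therefore uses an enriched design —
2,000 early-PE and 20,000 unaffected pregnancies per cohort, one cohort
to fit the Gaussian model and an independent one to evaluate it — and
reports the DR at 10% empirical FPR. DR at fixed FPR is invariant to
outcome prevalence (it conditions on affected status on both axes), so
enrichment changes the precision of the estimate, not its target. At
these sizes the binomial standard error on the DR is below one point.

## Numerical and degenerate-input choices

* Gestational age is held in integer days internally (the screening
  window is 77–97 days); delivery GA in decimal weeks, since the 34-week
  split and percentile lookup are week-scale operations.
* SGA uses strict `<` against a linearly interpolated 10th percentile;
  a weight exactly on the percentile is not SGA. The shipped percentile
  table is synthetic (labelled so in its filename), sex-agnostic, and
  swappable for a real national reference.
* Late PE is boundary-inclusive at exactly 34.0 weeks.
* Hypertension onset at or before 20 weeks is outside the PE definition
  and classifies as `none` with a warning, not an error: such rows are
  chronic-hypertension pregnancies, valid cohort members.
* The marker LR is floored at $10^{-300}$ in scoring: far in the
  unaffected tail the affected density underflows double precision, and
  a zero LR would make the posterior exactly 0, which the "1 in N"
  formatting cannot represent.
* `fit_median_model()` refuses degenerate designs (a single GA value)
  and fewer than 50 training records; `fit_gaussian_model()` requires
  two records per hypothesis group.

## Problem sizes in the test suite

The suite exercises the default 3270-pregnancy cohort for flow and
fidelity checks, 22,000-pregnancy enriched pairs for the held-out
detection-rate experiment, 200-instance randomised sweeps against
brute-force oracles for the evaluation primitives, and 5,000-draw
recovery checks for the model fitters. These sizes were chosen to keep
Monte-Carlo error well inside each test's tolerance while the whole
suite stays fast enough to run habitually.

## Known limitations

* All shipped prior LRs, median coefficients and adjustment factors are
  calibration placeholders for the synthetic population; deploying on
  real data requires refitting every component (the package provides
  the fitters).
* Uterine artery pulsatility index is not part of the marker panel.
* The SGA percentile reference is synthetic; real use needs a national
  chart.
* Early/late risks are independent binary models; a pregnancy
  contributes to both, and no competing-risks adjustment is made.
* The early-PE Gaussian rests on an eight-pregnancy group summary in
  the default configuration; its covariance in particular is fragile.
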