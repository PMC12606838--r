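---
title: "Indirect estimation of demand for family planning satisfied from contraceptive prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect estimation of demand for family planning satisfied from contraceptive prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfpsindirect)
```

## The indicators and why indirect estimation is needed

Four family planning indicators share one numerator — the weighted count of
partnered women aged 15–49 currently using contraception (any method, or
modern methods only):

* **CPRany / CPRm** — contraceptive prevalence: numerator over *all*
  partnered women 15–49;
* **DFPSany / DFPSm** — demand for family planning satisfied: the same
  numerator over only the women *in need* of contraception.

Because the DFPS denominator is a weight-subset of the CPR denominator
under an identical numerator, `DFPS ≥ CPR` always, `CPRany ≥ CPRm` and
`DFPSany ≥ DFPSm` by the method-set inclusion, and the four quantities are
mutually constrained: `DFPSm = CPRm · DFPSany / CPRany`. The package
asserts these orderings as invariants throughout.

Identifying women in need requires fertility-intention, pregnancy,
postpartum-amenorrhea and fecundity questions that many national surveys
outside DHS/MICS do not field. CPR requires a single question. The
package's core is a pair of regression equations that map CPR to DFPS when
direct estimation is impossible.

## Woman-level classification rules

A woman is **in need of contraception** if any of three routes applies:

1. she currently uses a method (users are in need by construction — the
   numerator must sit inside the denominator);
2. she is neither pregnant nor postpartum amenorrheic, is fecund, and wants
   no child within two years or wants to delay two or more years;
3. she is pregnant or postpartum amenorrheic and reports the pregnancy as
   mistimed or unwanted.

She is **infecund** (blocking route 2) if any of five conditions holds:
never menstruated; menopausal; no under-five child and last period more
than six months ago; married five or more years without a birth while not
contracepting; self-declared unable to conceive. The five-year exposure
condition is accepted as a precomputed boolean input — its exact
operationalization varies across survey programs and is upstream of this
package.

Design choices where the questionnaire logic is genuinely open:

* **Missing answers never drop a record**: an unanswered intention or
  fecundity item counts as condition-not-met. This mirrors the revised
  indicator definitions' goal of robustness to item nonresponse, and keeps
  denominators stable across surveys with different skip patterns.
* **Postpartum amenorrhea window**: amenorrhea is honoured for 24 months
  after the last birth by default (`amenorrhea_window_months`),
  configurable because the revised definitions shortened the window without
  a single canonical value. Beyond the window a non-menstruating woman is
  assessed under route 2. A woman amenorrheic *within* the window whose
  birth was wanted is not in need even if she reports wanting no more
  children — route 3 governs while the window is active; this is the
  sharpest consequence of the window and is tested explicitly.
* **Current users are in need regardless of their fecundity or intention
  answers** (including sterilized women). Anything else would allow
  DFPS > 1 or CPR > DFPS.
* **"Undecided" two-year intention** defaults to not-in-need for
  non-users, with a switch (`undecided_in_need`).
* **Method taxonomy**: the modern set is the Hubacher–Trussell list
  (condoms, sterilization, IUD, implants, pills, injectables, emergency
  pills, patches, diaphragms, spermicides, rings, sponges). The
  lactational amenorrhea method is absent from that list and therefore
  defaults to traditional; the taxonomy is user-configurable
  (`method_taxonomy`). Unknown method codes are an error, never silently
  treated as non-use.

`estimate_indicator()` computes weighted ratios per stratum; standard
errors are not part of its contract (point estimates are), and a stratum
with zero denominator weight is flagged missing rather than returned as
0/0.

## The prediction model

DFPS is modelled on the logit scale so that back-transformed predictions
always stay in (0, 1):

$$\mathrm{logit}(DFPS_{any}) = 1.05 + 0.93\,\log(CPR_{any}) +
  2.49\,CPR_{any}^2 + 0.70\,cpdiff$$
$$\mathrm{logit}(DFPS_{m}) = 1.12 + 0.97\,\log(CPR_{m}) +
  2.13\,CPR_{m}^2 - 1.43\,cpdiff$$

with `cpdiff = CPRany − CPRm`. The (log, square) pair is a degree-2
fractional polynomial of the prevalence; `cpdiff` captures reliance on
traditional methods, which raises DFPSany (traditional use still meets
demand) and lowers DFPSm (the same use does not meet *modern* demand) —
hence the opposite coefficient signs.

**Scale conventions.** Everything — CPR, cpdiff, DFPS — enters on the
proportion (0–1) scale and `log` is natural. Published summary tables often
report these quantities in percent; the proportion scale is the one under
which the coefficients reproduce the observed pool medians (CPRany 43.7 %,
cpdiff 3.4 p.p. → DFPSany 68.6 % predicted vs 68.0 % observed; CPRm
34.3 % → DFPSm 57.1 % vs 55.3 %), a consistency check frozen into the test
suite. The CSV reader auto-detects percent-scaled columns (any value > 1)
and rescales with a notice.

**Domain guards.** Prevalences below 1 % are outside the fitted range:
`predict_dfps()` refuses them, `predict_batch()` flags the rows and
continues, and `apply_exclusion()` implements the same rule before model
fitting (the log term is unstable near zero). Values above 0.99 are
clamped with a flag to keep the logit finite. When only CPRm is known,
`cpdiff` falls back to 0 *with a warning* — an approximation, never a
silent default.

## Refitting machinery

`fit_fp()` regresses logit(DFPS) on a fractional polynomial of the
outcome-relevant prevalence plus optional extra covariates (`cpdiff`,
`cpr_ratio`, `tfr`). Choices where convention had to be fixed:

* **Power set**: the standard Royston–Altman candidates
  {−2, −1, −0.5, 0, 0.5, 1, 2, 3}, multisets of size ≤ 2; power 0 is the
  log, and a repeated power (p, p) contributes $x^p$ and $x^p\log x$.
* **Cluster-robust variance**: regions of one country are one dependence
  cluster; the sandwich uses the HC1-type small-sample factor
  $\frac{G}{G-1}\frac{N-1}{N-k}$ (via `sandwich::vcovCL`). With every row
  its own cluster this reduces to ordinary heteroskedasticity-robust
  standard errors, which the tests verify against a hand-rolled oracle.
* **Model ranking** in `fp_search()` is by residual sum of squares
  (equivalently Gaussian deviance), ties broken toward fewer parameters and
  then lower powers. Fits are unweighted — each region is one analysis
  unit.
* **Linear-vs-FP comparison** (`compare_linear_fp`) tests the best
  degree-2 fractional polynomial against the straight line with the
  conventional 3-df F statistic, charging two extra parameters plus one df
  for the power-pair selection. Under a truly linear logit relationship
  this keeps the spurious-curvature rate at or below nominal, which a
  simulation test checks; on data spanning the full prevalence range the
  curvature is real and detected.

`cross_validate()` implements 5-fold cross-validation: refit on four
folds, predict the fifth, back-transform, pool all held-out pairs, and
report bias (mean of predicted − observed), MAE, Pearson correlation and
R² — all on the proportion scale. R² is defined as the squared pooled
correlation; folds are simple random partitions (not stratified by
country), sized within one of each other, reproducible by seed without
disturbing the caller's RNG stream. `out_of_sample_eval()` applies a
frozen model (e.g. `published_model()`) to another dataset with no
refitting — the design used to check transfer across inequality
dimensions (national, residence, wealth, education).

## The synthetic-data generator

Real DHS/MICS microdata are access-restricted, so the generator makes
every stage testable offline. It emulates two data kinds:

**Region tables** (`gen_region_rows`): 103 countries carrying 1,099
subnational regions (the structure of the observed multi-country pool).
CPRany is drawn from a Beta(1.45, 1.54) scaled to [0.015, 0.848] and
cpdiff from a Beta(0.68, 6.04) scaled to [0, 0.639]; both shapes were
matched once to the observed mean and 10th/50th/90th percentiles of the
respective indicators (CPRany mean 41.8 %; cpdiff mean 6.7 p.p., heavily
right-skewed). cpdiff is truncated at CPRany − 0.012 so generated CPRm
never falls below the observed minimum of 1.2 % — which also keeps the
default table fully inside the 1 % inclusion region. DFPS is computed from
the published equations plus a country-shared intercept perturbation
(sd 0.05, the mechanism that makes country-clustered standard errors
meaningful) and independent region-level noise (sd 0.05) on the logit
scale; 0.05 puts synthetic cross-validated R² in the high-nineties regime
the models operate in. The noise-free truth table is returned alongside
for oracle checks.

**Microdata** (`gen_microdata`): women are sampled into categories
(modern user, traditional user, non-user in need, not in need — split
among wanted pregnancies, infecund women, and women wanting a child soon)
with probabilities solved from a target indicator quadruple; the share of
women in need is `CPRany/DFPSany`. Because the four targets are
over-determined, inconsistent quadruples raise an error naming the violated
relation. Weights default to a constant so that recovery error is plain
binomial; heterogeneous weights are available via `weight_range` and are
exercised by the weight-invariance tests.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: multi-stage sampling geometry beyond cluster
ids, item-nonresponse patterns, reporting error in intention questions,
country-specific method mixes, and any deviation of the true CPR–DFPS
relationship from the published functional form. Parameter-recovery
results demonstrate the machinery's correctness, not the equations'
validity on new populations.

## Problem sizes and numerical choices

The test suite and the acceptance script work at the study's native scale
— 1,099 regions × 103 countries — because fits there take milliseconds;
parameter-recovery averages use 50 seeds, and the specification search
crosses 44 power sets with the cpdiff subset choice (88 candidates per
search). Smaller configurations (≈150 regions in 25 countries) are used
where many replicates are needed. Degenerate inputs are errors, not
guesses: rank-deficient designs name the collinear columns, singular
cross-validation folds name the fold, empty strata are flagged missing,
and the logit refuses 0 and 1 exactly.

## Known limitations

* The equations are for *partnered* women 15–49; all-women indicators
  would need refitting where unmarried contraceptive behaviour differs.
* Prediction intervals are out of scope (the machinery reports coefficient
  uncertainty, not prediction-interval formulas).
* The DFPSm equation needs CPRany through cpdiff; with CPRm alone the
  cpdiff = 0 fallback is a flagged approximation.
* Dimensions with strong cultural structure (religion, ethnicity) may not
  transfer; the cross-dimension evaluation tools are provided precisely so
  such transfers can be checked rather than assumed.
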