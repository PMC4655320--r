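---
title: "Methods: screening for small-for-gestational-age infants with third-trimester fetal biometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for small-for-gestational-age infants with third-trimester fetal biometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthscreen)
```

## The problem

Small-for-gestational-age (SGA) infants — birthweight below the 10th
percentile for gestational age and sex — carry most of the burden of
perinatal morbidity attributable to fetal growth restriction (FGR), but many
SGA infants are simply constitutionally small. A screening programme
therefore has two distinct jobs: *detect* the small fetus before birth, and
*discriminate* the pathologically small fetus from the healthy small one.

`growthscreen` implements the analysis pipeline for evaluating both jobs in
a paired design, where every pregnancy in a nulliparous cohort is screened
under two policies simultaneously:

* **selective ultrasonography** — third-trimester biometry only on clinical
  indication, the current standard of care; a woman with no clinically
  indicated scan at 26 weeks or later is screen negative by definition;
* **universal ultrasonography** — research biometry at about 28 and 36
  weeks in everyone, with results masked from clinical care.

Screen positive under either policy is an estimated fetal weight (EFW)
below the 10th percentile at the *last* eligible scan before birth, with a
strict inequality (a percentile of exactly 10.0 is negative).

## Fetal-growth numerics

**EFW.** The default EFW model is the three-parameter Hadlock regression on
head circumference (HC), abdominal circumference (AC) and femur length (FL),
in centimetres:

$$\log_{10} \mathrm{EFW} = 1.326 - 0.00326\,\mathrm{AC}\cdot\mathrm{FL}
  + 0.0107\,\mathrm{HC} + 0.0438\,\mathrm{AC} + 0.158\,\mathrm{FL},$$

with the BPD-inclusive four-parameter variant selectable through the same
registry. Biometry is stored in millimetres in all files (clinical
convention) and converted at the equation boundary.

**Percentiles.** All percentile operations share one form: a reference
standard supplies a location and a scale at each gestational age (GA), and
the percentile is $100\,\Phi\!\big((t(x) - t(\mathrm{loc}))/\mathrm{scale}\big)$
on the standard's working scale. The shipped weight-for-GA standard has
median $\exp(0.578 + 0.332\,g - 0.00354\,g^2)$ grams and SD equal to 12.7%
of the median. Standards live in versioned JSON/CSV registry files with
citation fields; transcriptions are flagged for verification against their
sources, and the test suite exercises the machinery against small toy
standards built in code so that no test depends on transcription accuracy.

The birthweight-for-GA-and-sex reference shipped in
`birthweight_uk_synthetic.csv` is a *synthetic* smooth table (sex-specific
scalings of a log-quadratic median with a 12% proportional SD). It has the
shape of a national reference but not the provenance of one; any real table
with columns `ga_weeks, sex, mean_g, sd_g` can be dropped in. Because the
cohort generator and the classifier use the same registered standard, all
calibration properties are invariant to this choice.

**Customised percentiles.** The customisation model is deliberately simple:
a term optimal weight adjusted linearly for maternal height, weight,
ethnicity and smoking, scaled along the weight-for-GA proportionality curve,
with a proportional-SD normal model. The shipped coefficients are
illustrative surrogates — proprietary customisation coefficient sets are not
redistributable — but the interface (a JSON coefficient file) accepts any
set. Setting every adjustment to zero recovers the population percentile
exactly, which is how the machinery is tested.

**GA-adjusted Z-scores.** Scans happen at slightly different GAs, so each
marker measurement is standardised within the cohort: a polynomial mean
curve (degree 2 by default) is fitted by least squares, and an SD curve by
regressing absolute residuals on the same basis and scaling by
$\sqrt{\pi/2}$. The absolute-residual route is smooth and stable at cohort
size, unlike binned SDs. Fitting requires at least 100 observations spanning
at least 2 weeks of GA; the fitted SD curve must be strictly positive on the
fitted range. **AC growth velocity (ACGV)** is the difference in AC Z-score
between the last scan before birth and the 20-week scan; pregnancies missing
either scan are excluded from velocity-stratified analyses and counted in
the classification log.

**Decile markers.** Five previously described FGR markers are dichotomised
at cohort deciles: highest decile of HC/AC ratio, uterine-artery and
umbilical-artery pulsatility index; lowest decile of AC/FL ratio and ACGV.
Cuts are type-7 empirical quantiles over all subjects with a non-missing
value; flags use strict inequalities, so ties at the cut are never flagged
(consistent with the strict screen-positive rule). The uterine Doppler is
classified at the 20-week scan, the other markers at the last research scan
before birth.

## Outcome definitions

Composite neonatal morbidity is any of: 5-minute Apgar < 7; metabolic
acidosis (cord pH < 7.1 **and** base deficit > 10 mmol/L, both strict);
neonatal-unit admission at term (admission < 48 h after birth at ≥ 37 weeks
with discharge ≥ 48 h after admission). The severe adverse composite is
stillbirth or a term livebirth with neonatal death, hypoxic ischaemic
encephalopathy, inotrope use, mechanical ventilation, or severe metabolic
acidosis (pH < 7.0 and base deficit > 12). Missing component fields are
treated as criterion-not-met and counted in a log; a negative admission
duration is a hard validation error.

## Paired diagnostic accuracy

Both policies are evaluated against the same gold standard on the same
subjects, so every comparison respects the pairing:

* **Sensitivity/specificity/FPR/FNR** are compared with McNemar's test on
  the discordant pairs — exact binomial below 25 discordant pairs, otherwise
  the continuity-corrected chi-square. The statistic provably ignores
  concordant counts, which is tested directly.
* **Relative sensitivity** is the ratio of sensitivities among the diseased,
  with a paired log-delta-method CI (the covariance term uses the
  both-positive fraction).
* **Predictive values** are compared with a generalised score statistic:
  each subject contributes one record per test that called them positive
  (negative, for NPV); the score for the test contrast is evaluated under
  the pooled null predictive value with a cluster-robust empirical variance,
  so subjects positive on both tests are handled correctly. A paired
  multinomial bootstrap over the eight joint cells is always computed
  alongside; the empirical size of the score test is verified by simulation
  (conditionally independent equally accurate tests, n = 500, 2000
  replicates).
* **Likelihood ratios** are compared through the identity
  $\log \mathrm{LR}^+ = \log P(T^+\mid D^+) - \log P(T^+\mid D^-)$: the
  between-test contrast is the difference of two paired log-ratios in
  independent disease strata, each with a paired delta-method variance —
  the Wald test of the log-linear model contrast. Same bootstrap
  cross-check, same size simulation.
* **ROC AUC** uses the Mann–Whitney identity with a DeLong CI (via pROC);
  the tests check it against an exhaustive $O(n^2)$ pair-counting oracle.

Proportion CIs default to Wilson score intervals. A Wald option exists
because published screening tables of this design are frequently
accompanied by simple normal-approximation intervals; `screen_summary()`
exposes both so a reported table can be matched exactly, and the acceptance
suite identifies which method a given set of printed intervals came from
rather than assuming one.

## Risk stratification and interaction

Relative risks use the Katz log-method CI; zero cells get a 0.5 continuity
correction *for the CI only*, never for the point estimate, with a flag.
Two-sided Fisher exact p-values sum hypergeometric probabilities no larger
than the observed table's. The interaction between screen status and a
marker is tested as homogeneity of the risk ratio across the marker's
strata (a Wald chi-square on the difference of stratum log-RRs with Katz
variances), with a logistic-regression interaction Wald p always computed
alongside as a cross-check. The two agree closely at morbidity-scale risks
but are *not* identical tests — the tests require 2-fold agreement only
away from the deep tails (p above $10^{-3}$), where Wald statistics on
different link scales legitimately diverge. A permutation oracle (shuffling
stratum membership while keeping each subject's exposure–outcome pair)
bounds the interaction p within ±0.05 on small strata. No multiplicity
adjustment and no covariate adjustment are applied anywhere, matching the
pre-specified analysis style this pipeline reproduces.

## The synthetic cohort generator

No individual-level data are redistributable for this design, so the
package is exercised end-to-end on a seeded generator
(`generate_cohort()`) whose defaults *are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 3977 | analysed pregnancies |
| `sga_prevalence` | 0.09 | marginal P(birthweight < 10th pct) |
| `fgr_latent_prevalence` | 0.043 | latent growth-restricted class |
| `selective_scan_rate` | 0.42 | fraction with an indicated scan ≥ 26 wk |
| `efw_measurement_cv` | 0.10 | total CV of measured EFW |
| `morbidity_base_rate` | 0.069 | marginal composite morbidity |
| `rr_morbidity_given_sga_lowvelocity` | 3.9 | FGR∧SGA vs non-FGR risk ratio |
| `velocity_deficit` (± `_sd`) | −1.2 (0.3) | AC Z deficit of the FGR class by term |

**Latent structure.** Each pregnancy draws a latent growth percentile
(uniform), mapped to a baseline size Z. The FGR class adds a progressive
deficit ramping linearly from 20 weeks to term. Birthweight is the
registered birthweight standard evaluated at the delivery-GA and sex plus
the birth Z, which adds a growth drift between the last scan and delivery
(`late_growth_sd = 0.7` Z). The baseline mean is solved analytically
(`uniroot` on the two-component mixture CDF) so the marginal SGA rate hits
`sga_prevalence` while binomial sampling variation is preserved.

**Measurement model.** Each scan's biometry is produced by closed-form
inversion of the Hadlock equation: the common scale factor $\lambda$ that
makes the Hadlock EFW of the GA-median biometry equal the latent size is
the root of a quadratic in $\lambda$, so no iterative solve is needed.
On top of $\lambda$ sit (i) an EFW-neutral persistent "body shape" factor
(AC up, HC/FL down, weighted by the Hadlock log-elasticities to cancel at
first order) that gives the ratio markers realistic between-fetus variation
and raises the scan-to-scan correlation of AC Z-scores; (ii) a fractional
head-sparing pattern for the FGR class (AC −5% by term, head preserved);
(iii) transient biological variation; and (iv) multiplicative measurement
error split into a common scan-level component and independent per-measure
components, with the common SD solved from the EFW CV budget through the
elasticities. This split matters: per-measure error is a few percent
(matching sonographer reproducibility), while the EFW-level CV is ~10%, and
getting it wrong washes out the growth-velocity signal entirely.

**Screening channels.** An EFW-standard offset (0.3 Z) separates the
in-utero EFW standard from the birthweight standard, reproducing the
excess of screen positives (~14%) over SGA prevalence (~9%) that arises
when the two references differ. Clinically indicated scans are selected by
a logistic model on diabetes, BMI, age extremes, miscarriage history and a
noisy symphyseal-fundal smallness proxy (intercept solved at generation
time to hit `selective_scan_rate`); clinical EFW carries a systematic
+0.6 Z offset and extra noise relative to research-protocol EFW, which
reproduces the much lower positivity and sensitivity of routine selective
scanning. These operating-characteristic knobs were fixed once, at design
time, against the cohort structure the generator is meant to emulate
(prevalence ≈ 9%, universal screen-positive ≈ 14%, universal sensitivity
in the low-to-mid 50s, selective sensitivity ≈ 20%) and are not retuned.

**Outcomes.** Morbidity is a logistic model on the latent FGR class and
true SGA status; the intercept and FGR effect are solved jointly so the
marginal rate and the FGR∧SGA risk ratio hit their targets exactly in
expectation, with an explicit infeasibility error when the requested risk
ratio cannot be reached at the requested base rate. Component fields
(Apgar, cord gases, admission times) are then sampled conditional on the
composite so that the classifier's re-derived composite agrees with the
latent one; preterm morbidity is forced into the acidosis/Apgar components
because the admission criterion requires term birth. The severe composite
is generated analogously at its own marginal rate. `truth_table()` exposes
the latent ledger for parameter-recovery tests; no analysis stage consumes
it.

**What the generator does not emulate.** Doppler physiology (PI values are
GA-dependent normals with an FGR shift), stillbirths (the cohort is all
livebirths; the stillbirth flag exists only for schema compatibility), twin
pregnancies, masking violations, and any dependence of fetal size on
maternal characteristics (so customised percentiles are expected to perform
like population percentiles here — which is also the study-design
conclusion the pipeline is built to examine, but passing tests on synthetic
data cannot *confirm* that conclusion about real cohorts). Severe SGA
prevalence runs above a real cohort's because the latent tail is cleanly
Gaussian. Calibration results on this generator show the pipeline is
correct, not that any clinical claim generalises.

## Numerical and reporting choices

* Strict `<` everywhere a threshold is printed as "less than".
* Type-7 quantiles for decile cuts; ties at the cut unflagged.
* Exact McNemar below 25 discordant pairs, chi-square with continuity
  correction at or above.
* Katz CIs with 0.5-cell correction for CIs only; infinite RRs signalled
  explicitly rather than corrected away.
* Report tables round half-up — integers for percentages, one decimal for
  ratios — at the output layer only; the JSON ledger keeps full precision.
* Per-subject RNG substreams (one `set.seed` per subject derived from the
  global seed) make cohorts byte-reproducible and mean that enlarging a
  cohort never perturbs existing subjects.

## Problem sizes used by the test suite

Unit tests run on cohorts of 120–500 subjects; calibration checks use the
full 3977-subject scale across 50 seeds (medians, since single-cohort
sensitivity carries ~3 percentage points of binomial noise); test-size
simulations use 2000 replicates at n = 500; the permutation oracle uses
10 000 shuffles on strata of ≤ 60 subjects; Z-model parameter recovery uses
n = 5000. These sizes keep every Monte-Carlo band used in testing at least
an order of magnitude wider than its standard error.

## Known limitations

* The shipped growth standards are transcriptions (EFW, weight-for-GA) or
  synthetic stand-ins (birthweight reference); clinical use requires
  dropping verified references into the registry.
* The generalised score test is the simplest exactly identified variant of
  its family; variants with other working weights exist, which is why the
  seeded paired bootstrap is always reported alongside.
* The risk-ratio homogeneity test and the logistic interaction test answer
  slightly different questions in the tails; both are reported.
* Customisation is a surrogate model, adequate for exercising the
  interface, not for clinical centile assignment.
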