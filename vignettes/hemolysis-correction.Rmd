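---
title: "Correcting serum NSE for hemolysis interference: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting serum NSE for hemolysis interference: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsecorr)
```

## The problem

Neuron-specific enolase (NSE) is a serum tumor marker for small cell lung
cancer and neuroblastoma — and it is abundant in red blood cells. Any
specimen hemolysis, including hemolysis far too mild to see by eye, releases
RBC NSE into the serum and falsely elevates the result. The hemolysis index
(HI), a bichromatic absorbance measurement reported on an integer scale
where 1 HI unit corresponds to 10 mg/L cell-free hemoglobin, detects this
reliably: the visual detection limit sits near 300 mg/L hemoglobin (HI 30),
while clinically relevant interference starts at HI values of 6–11.

`nsecorr` implements the full workflow around that observation: HI
quantification and reference intervals, a spike-recovery model of the NSE
increment, patient-individualized correction, agreement validation, and an
automated release/annotate/correct decision cascade.

## The increment model and its personalization

A spike-recovery experiment adds serial saline dilutions of a concentrated
RBC lysate (a halving series of HI concentrations) to serum pools at a
fixed lysate:serum volume ratio. Regressing the measured NSE increment over
each pool's saline baseline on the measured HI of the spiked aliquot gives
a straight line

\[ \hat y = b_1 \, \mathrm{HI} + b_0 , \]

with \(y\) in µg/L. The slope is dominated by the NSE/HI ratio of the
donor red cells, a quantity that varies several-fold between people. The
model is therefore re-expressed against the donor's measured ratio
\(R_d\):

\[ \hat y = \frac{b_1}{R_d} R \,\mathrm{HI} + \frac{b_0}{R_d} R , \]

so that substituting a patient's own ratio \(R\) — measured as NSE/HI in a
1:30 saline dilution of the patient's washed red cells, a ratio in which
the dilution factor cancels — personalizes the correction:
\(\mathrm{NSE}_{corr} = \mathrm{NSE}_{meas} - \hat y\). Corrections that
would fall below the assay's lower measurable limit (0.05 µg/L) are clamped
there and flagged.

`fit_increment_model()` fits the line by ordinary least squares (the model
class is linear; no robust or weighted variants), `personalize()` rescales
it, and `correct_nse()` applies it.

### Which x-variable?

The increment can be regressed on the spiked aliquot's measured HI
(`hi_meas`) or on the baseline-subtracted `delta_hi`. The published
coefficient convention uses the measured HI, so that is the default in
`spiking_increments()` and `read_spiking_csv()`; since pooled baseline sera
have a small HI (median 2), fitting against `hi_meas` simply shifts the
intercept by about \(-2 R_d\), and applying the model with the specimen's
measured HI compensates exactly. Both modes are exposed because the two
conventions are easy to mix up when reusing coefficients from elsewhere.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hi_cutoff` | 5 | HI | upper limit of the one-sided 95% HI reference interval in healthy sera; "hemolyzed" means strictly above it |
| `hi_calibration_k` (`k`) | 100 | HI per AU | proprietary optical calibration; 100 makes 0.001 AU = 1 mg/L Hb so absorbances round-trip through `hb_from_hi()` |
| `hi_range_max` | 1000 | HI | instrument reporting ceiling |
| `nse_cutoff` | 16.3 | µg/L | manufacturer's 95th-percentile reference limit; below it a hemolyzed result cannot mislead management |
| `trend_delta_pct` | 25 | % | smaller changes in tumor-marker trend monitoring carry no clinical importance |
| `bias_limit_pct` | 20 | % | acceptability band for limits of agreement, from the assay's CV ≤ 10% intermediate precision (±1.96·√2·CV ≈ ±20%) |
| assay floor / ceiling | 0.05 / 370 | µg/L | measurable range of the NSE assay |

"Above" is strict everywhere: an HI of exactly 5, an NSE of exactly
16.3 µg/L, or a 25.0% change do not trigger the next rule. This matches the
observed convention that the smallest abnormal HI is 6.

## The reference-interval estimator

`estimate_reference_interval()` uses the standard nonparametric
rank-interpolation estimator for clinical reference ranges: the percentile
of order \(p\) sits at rank \(r = p(n+1)\), linearly interpolated between
order statistics and clamped to \([1, n]\). Ties need no special handling —
interpolation between equal order statistics returns the tied value. For
one-sided intervals (the relevant case for HI, where only high values are
abnormal) the lower bound is anchored at 0. Guideline practice recommends
at least 120 reference individuals; the function requires 20 and warns
below 120.

## What the synthetic generators emulate

No specimen-level data from the motivating study are public, so the package
ships generators that reproduce the study's *design* and *summary
conditions*; all tests run against these.

**Spiking experiment** (`simulate_spiking_experiment()`): 23 serum pools ×
11 aliquots (one saline baseline each) = 253 samples; a 10-level halving
lysate series starting at HI 6000 (HI 5000 for the 3 lowest-NSE pools,
which improves low-level accuracy); lysate added 1 volume to 10 volumes of
serum, read as a spike fraction of 1/11 (the "1:10 ratio" wording is
ambiguous, so the ratio is a design parameter); donor ratio \(R_d = 0.31\);
pool baseline HI 2 (the healthy median). Pool baseline NSE values are not
enumerated in any source, so the generator spaces 23 values log-uniformly
over 8.4–370 µg/L, the spiked-pool NSE range.

The truth model quantizes the hemolysis level to the instrument's integer
HI scale: `HI_true = round(lysate_HI · f + baseline_HI)` and the true NSE
increment is `donor_r · (HI_true − baseline_HI)`. Quantizing the truth
rather than only the observation keeps two properties simultaneously: with
all CVs at zero the observed fields equal the truth fields bit-for-bit, and
the noise-free regression recovers the donor ratio exactly.

**Validation cohort** (`make_validation_cohort()`): 47 pseudo-patients,
each with a baseline and an intentionally hemolyzed measurement of the same
specimen. Patient ratios are uniform on 0.091–0.467, hemolyzed HI
log-uniform on 6–314, baseline NSE log-uniform on 6.94–366.1 — the ranges
of the validated cohort. A small per-specimen positive offset (uniform
[0, 2] µg/L scaled by \(R\)) represents lysis products beyond the linear
term, so a positive fitted intercept arises in kind.

**Healthy controls** (`make_healthy_cohort()`): right-skewed lognormals,
parameterized analytically from the target summaries rather than tuned:
NSE meanlog \(\log 8.5\) (the median) and sdlog
\(\log(11.8/8.5)/z_{0.95}\) (the 95th percentile), HI meanlog \(\log 2\)
and sdlog 0.55, which puts the rounded 95th percentile at 5.

### Measurement noise and which CV applies where

Noise is multiplicative lognormal with unit mean, parameterized by CV —
the natural error model for positive-valued analyzer readings
(`noise_model()`): HI repeatability 2%, HI intermediate precision 5%, NSE
intermediate precision 10% (the assay's claimed ceiling), NSE within-run
repeatability 2%.

Which CV applies is a property of the measurement session, exposed as the
`precision` argument of the generators. The spiking experiment measures all
253 samples within one day, and the validation protocol assays each
specimen's baseline and hemolyzed aliquots back to back; both therefore
default to the within-run repeatability CVs. This matters: under a 10%
cross-day NSE CV the fitted intercept of the spiking line has a standard
error of several µg/L and paired percent differences have an SD near 20%,
neither of which is compatible with the tight intercepts and
single-digit-percent agreement SDs such experiments actually produce.
The `"intermediate"` setting remains available for sensitivity analyses.

### What the generators do not emulate

Real cohorts bring features the generators deliberately omit: correlation
between a patient's disease state, baseline NSE and hemolysis propensity;
freeze–thaw lysis kinetics; platelet NSE contribution; icterus/lipemia
interference on the HI channel; drift between analyzer calibrations. A
passing test suite shows the algorithms are implemented correctly under the
stated study conditions, not that the printed coefficients transfer to
another instrument or population — the correction workflow is designed to
be re-derived locally.

## Agreement analysis

`bland_altman_percent()` works on the percent scale:
\(d_i = 100\,(c_i - b_i)/\bar{x}_i\) with the pair mean as the default
denominator (the classical Bland–Altman ratio plot); a baseline-denominator
mode exists because the phrase "difference of corrected and initial NSE"
admits either reading. The SD is the sample (n−1) SD and the 95% limits of
agreement are fixed at mean ± 1.96·SD — these numbers are limits of
agreement, even where the surrounding literature occasionally labels them a
confidence interval of the mean difference. Acceptability compares both
limits to the ±20% band, boundary inclusive.

On the significance pattern mirrored by the tests: with 47 pairs and the
validated effect sizes, an *unpaired* rank-sum comparison of hemolyzed
versus baseline NSE has roughly 40% power, so a single simulated draw may
land on either side of α = 0.05. The suite therefore asserts the robust
paired version of the same claim — the Wilcoxon signed-rank test on the
self-controlled pairs rejects decisively, hemolyzed medians exceed baseline
medians, and the corrected-versus-baseline unpaired comparison stays
non-significant with a smaller p for the uncorrected contrast.

## The decision cascade

`decide()` evaluates, in order: (1) HI ≤ cutoff → release; (2) NSE ≤
16.3 µg/L → release with HI note; (3) diagnostic purpose (SCLC/NB) or a
trend change above 25% → corrected report if the patient's ratio is
available, otherwise request the ratio; (4) everything else → release with
HI note (trend purpose without a prior result lands here with an explicit
warning in the rationale). Exactly one action fires per specimen and the
rationale records which rule; the thresholds live in `decision_config()`,
so a different reading of the workflow is a configuration change. Hemolyzed
specimens with unremarkable NSE are released annotated rather than held:
correcting every hemolyzed specimen would require a manual ratio
measurement per patient and invites alert fatigue, while the annotation
preserves the information. A corrected value accompanies the original
result and HI on the report; it never replaces them.

## Numerical choices

- HI reporting rounds half away from zero and clamps to [0, 1000]; values
  below 1 are censored at the low end and carried as 0 with a flag.
- A negative absorbance difference within 0.005 AU is treated as zero;
  beyond that the spectrum is rejected as invalid.
- Model coefficients are carried at full double precision; comparisons to
  printed values happen only in tests, at the printed precision.
- `fit_increment_model()` refuses degenerate designs (all x identical,
  fewer than 2 points after the HI > 5 filter).
- Generators accept an explicit integer seed and are bit-reproducible for
  a given seed.

## Problem sizes

The shipped tests and examples run the study-scale problems directly: the
253-sample spiking design, 47-pair validation cohorts, 200-control healthy
cohorts, and 100 seeded replicates for slope-recovery checks — a few
seconds end to end, so nothing is scaled down.

## Known limitations

- The optical calibration `k` is a stand-in convention, not the
  manufacturer's proprietary value; only products of the full round trip
  (absorbance → HI → Hb) are meaningful across instruments.
- The linear increment model is derived for HI up to ~550; gross hemolysis
  beyond the fitted range extrapolates.
- Only hemolysis is modelled among the serum indices; icterus and lipemia
  are out of scope, as are instrument drivers and LIS messaging.
- Visual hemolysis grading is reduced to a binary flag; the four-degree
  grading scheme has no quantitative definition to implement.
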