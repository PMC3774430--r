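---
title: "The Exposure Hazard Index: model, calibration and prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Exposure Hazard Index: model, calibration and prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehiscore)
```

## The model

The Exposure Hazard Index (EHI) is a semi-quantitative risk score in the
control-banding tradition, designed for screening occupational chemical
exposures when quantitative air monitoring is impractical — typically for
prioritizing inspection and abatement across many small and medium
enterprises. Per chemical,

$$\mathrm{EHI} = \mathrm{TI} \times \mathrm{EI} \times \mathrm{PDI},$$

where

* **TI (toxicity index)** rates intrinsic hazard from the chemical's 8-hour
  time-weighted-average occupational exposure limit (OEL-TWA, ppm). Lower
  limits mean higher toxicity.
* **EI (exposure index)**, in $[0, 1]$, rates the daily exposure duration.
* **PDI (protection deficiency index)**, in $[0, 1]$ under the default
  formula, expresses the residual exposure probability left by the
  workplace's protections. It combines the **management index MI** (how many
  of four measures — safety/health personnel, MSDS, SOPs, training — are in
  place) and the **protection index PI** (the combination of engineering
  controls EEe/EEp/EEn with PPE provision PPEe/PPEn).

Chemicals within an enterprise are assumed toxicologically additive: the
enterprise score is the plain sum of its per-chemical EHIs, with no synergy
or antagonism terms. This is a deliberate simplification; co-exposure
interactions are out of scope.

Two rating schemes coexist:

* the **original** scheme uses categorical tables — eight doubling TI levels
  $1, 2, \dots, 128$ over decade bands of the OEL-TWA (lower bound
  exclusive, upper inclusive), three EI duration bands (0.30 / 0.60 / 1.00
  below 2 h, 2–4 h, at or above 4 h), MI $= N/4$, and a six-entry PI table;
* the **corrected** scheme replaces these with continuous functions
  calibrated against a panel of 20 senior industrial hygienists who rated
  the conditions observed in seven enterprises (nine chemicals, OEL-TWAs
  0.005–750 ppm; durations 10–250 min; all control combinations).

Chemicals with only a ceiling limit get an effective TWA of three times the
ceiling — the published substitution, applied literally even though ceilings
conventionally sit *above* TWAs. Carcinogens and chemicals without any OEL
are rated like the most toxic listed chemical (effective OEL 0.001 ppm).

## The corrected calibration

`ehi_calibration()` is the fitting function; it returns a classed object
with `print`, `summary`, `coef` and `predict` methods.

```{r}
cal <- ehi_calibration()
cal
```

**TI.** The panel ratings are inversely proportional to $\log_{10}$ OEL, and
the model asserts that a tenfold drop in the OEL doubles the health effect:
$\mathrm{TI} = K_0 \, 2^{-\log_{10}\mathrm{OEL}}$. Taking $\log_2$ makes the
slope known, so $K_0$ has the closed-form least-squares solution
$\log_2 K_0 = \overline{\log_2 \mathrm{rating} + \log_{10}\mathrm{OEL}}$
(`fit_ti_scale()`). By default the fit uses the published corrected TI
column, which the power law reproduces self-consistently ($K_0 \approx
17.88$); fitting the raw panel means instead gives $K_0 \approx 16.58$,
because the published correction smoothed the panel's rating noise before
the constant was fixed. How the original constant was derived from the raw
means is not recoverable from the published record, so the corrected column
is treated as ground truth; `ti_source = "panel"` remains available for
user-supplied tables. For carcinogen/no-OEL agents the default substitutes
0.001 ppm into the power law (TI $\approx 8 K_0 \approx 143$); set
`carcinogen_ti = "pin"` to pin them at the original maximum of 128.

**EI.** Ordinary least squares of the seven panel means on duration in
minutes (`fit_linear()`), predictions clamped to $[0, 1]$. The clamp matters
at both ends: the fitted intercept is slightly negative (so tiny durations
would otherwise rate below zero) and the line crosses 1 near 420 min, inside
a full 480-min shift. A through-origin variant (`ei_through_origin = TRUE`)
is provided; both fits round to the same published predictions at the
calibration durations.

**MI and PI.** The corrected MI is the published lookup
$\{0.18, 0.39, 0.60, 0.81, 1.00\}$ for $N = 0..4$ — notably non-zero at
$N = 0$ (even unmanaged workplaces retain some basic hygiene awareness). The
lookup is *not* refit from the panel means because the published correction
moved the $N=0$ value away from the panel's 0.00; a regression rebuild over
$N = 1..4$ (`mi_source = "fit"`) exists for users calibrating their own
panels, capped to $[0, 1]$. PI is the corrected six-entry lookup
$\{0.00, 0.18, 0.42, 0.61, 0.74, 1.00\}$, identical to the panel means.

**PDI.** The published account states only that PDI decreases as MI and PI
improve; the exact algebraic form was not printed. The default here is

$$\mathrm{PDI} = 1 - \tfrac{\mathrm{MI} + \mathrm{PI}}{2},$$

which is affine, symmetric in its arguments, bounded in $[0, 1]$, 0 at full
protection and 1 at none. Alternatives `product_complement`
($(1-\mathrm{MI})(1-\mathrm{PI})$) and `sum_complement`
($2-\mathrm{MI}-\mathrm{PI}$, which can exceed 1) are selectable via
`pdi_formula`; all downstream code treats PDI as opaque.

**Validation regression.** `validate_against_expert()` regresses panel
enterprise EHIs on model EHIs and reports slope, intercept and $R^2$ (0 by
convention for a zero-variance response). The published validation of the
corrected model against its panel (slope 1.05, intercept −0.27, $R^2$ 0.94
over seven enterprises) required per-enterprise panel scores that were never
published, so that particular fit cannot be recomputed; the utility is
verified by exact-fit recovery and noisy parameter-recovery tests instead.

## Scoring and prioritization

`score_survey()` scores a long-format survey table (one row per
enterprise-by-chemical; management and control profiles are
enterprise-level, matching the granularity of the national questionnaire).
`summarize_industries()` reduces each industry to a statistic of its
enterprise EHIs — by default the 95th percentile, the figure the national
prioritization used; a mean is available because a "distribution of
EHI$_{cor}$" summary is ambiguous at industry level.

Percentiles everywhere use the inclusive linear-interpolation method: rank
$h = (n-1)p + 1$ interpolated between flanking order statistics
(`stats::quantile()` type 7). This choice is forced by the published
numbers: on the 25 published industry values it reproduces the cutoffs
32.43 / 20.61 / 10.41 to the printed precision, which nearest-rank methods
do not. One passage prints the 70th-percentile cutoff as 20.3; the table
header's 20.61 is taken as correct and the 20.3 treated as a typo.

`assign_priorities()` bands industries at the 90th/70th/50th percentiles of
the industry statistics with inclusive lower bounds (a statistic exactly at
a cutoff takes the higher band): band 1 at or above p90 down to band 4 below
p50. On the published 25 industry values this yields band sizes 3/5/5/12.
`band_index_profiles()` then summarizes chemical-level TI/EI/MI/PI per band
as mean ± SE (SE $= s/\sqrt{n}$, 0 for a single observation), the diagnostic
that shows, e.g., first-priority industries being driven by long exposures
and weak protections.

```{r}
survey <- generate_survey(generator_config(seed = 2026))
pipe <- run_pipeline(survey)
pipe
head(pipe$industry_summary)
```

## The synthetic survey generator

The national databank behind the published application (a 2006–2009 survey
of 702 enterprises across 25 two-digit-SIC manufacturing industries) was
never deposited. `generate_survey()` therefore emulates its *structure*, not
its joint distributions: per-industry enterprise counts exactly as surveyed
(summing to 702), a chemical palette of the nine calibration chemicals plus
a ceiling-only and a no-OEL synthetic agent (so effective-OEL substitution
is exercised), 1–4 chemicals per enterprise, exposure durations drawn from a
discrete mixture over $\{10, 30, 40, 48, 75, 225, 250, 480\}$ min — the
observed 10–250 min range extended to a full shift so both EI clamps are
exercised — 0–4 management measures, and all six control combinations. Where
the published record gives no distributional detail, the mixture weights
were chosen once as a plausible spread over the legal domains and are not
tuned. Industry codes are sequential placeholders ("01".."25"); the real SIC
codes were not published.

Each enterprise draws from its own RNG substream derived from (seed,
enterprise index), so extending the industry list does not perturb existing
enterprises, and a fixed seed fixes every downstream number bit-for-bit.

`generate_survey_tiered()` marks designated industries high-risk — longer
durations, fewer management measures, weaker controls, more toxic chemicals,
with an `effect` dial from 0 (no shift) to 1 — and exists for recovery
testing: the banding should, and in testing does, place high-risk industries
in priority bands 1–2.

What passing tests on this generator do **not** show: anything about the
real databank's chemical-use frequencies, industry differences, or the
correlation structure between durations, controls and chemicals. The
generator validates the pipeline's mechanics and ordering behaviour, not the
published industry ranking, which is reproduced only from the published
industry-level values themselves (`industry_reference()`).

## Numerical choices and scale

* All internal arithmetic is full double precision; only reports and CSV
  outputs round (half-to-even) to two decimals, matching the published
  presentation.
* OELs must be in ppm; mg/m³ inputs are rejected rather than converted (no
  molecular weights are carried).
* Durations are stored in minutes; the original-scheme hour thresholds are
  120 and 240 min.
* Degenerate inputs: empty exposure lists score 0; single-value groups get
  SE 0; zero-variance responses get $R^2 = 0$; empty surveys and empty
  industry sets are errors, not silent zeros.
* Test problem sizes (a few hundred synthetic enterprises, 1,000-case
  property loops) were chosen to exercise the combinatorics while keeping
  the whole suite near a minute on a single core.

## Limitations

The index is inhalation-only (OEL-TWAs target inhalatory exposure); dermal
and ingestion routes are out of scope, as are STEL-based ratings, mixture
synergy/antagonism, acute-versus-chronic separation, and any statistical
inference on band membership. Carcinogens are handled by a single pragmatic
substitution. The score is semi-quantitative: it ranks and bands, and
should not be read as a quantitative exposure estimate.
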