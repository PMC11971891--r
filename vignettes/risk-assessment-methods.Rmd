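---
title: "Methods: mercury biomonitoring exceedance, exposure and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mercury biomonitoring exceedance, exposure and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgbiomonitor)
```

## Scope and data model

The package analyses mercury biomonitoring campaigns in mother–infant
cohorts. A cohort is a flat collection of sample records — one measured
concentration per subject and matrix — across five matrices: breastmilk,
blood, maternal urine and child urine (µg/L) and household wheat
(µg/kg). Records carry optional WGS84 coordinates and two linkage ids
(infant → mother, subject → household) that drive the infant exposure
route and the milk–urine pairing. Units are mandatory and checked
against the matrix; there is no silent conversion anywhere in the
package.

## Exceedance classification

Each matrix has a permissible limit: breastmilk 1.7 µg/L, blood
20 µg/L, urine 10 µg/L (applied identically to mothers and children,
which remain separate matrices because results are reported per group),
food 100 µg/kg. A record *exceeds* iff its value is strictly greater
than the limit. The strict comparison was a genuine choice: the limits
are stated as "permissible below" thresholds, and a value exactly at the
limit is therefore not counted as exceeding. Published counts cannot
disambiguate the boundary (an exactly-at-limit measurement is
essentially a measure-zero event), so the semantics are exposed as a
`strict` flag rather than hard-coded.

Percentages are reported both exact (`100 · n_above / n_total`, to full
double precision) and rounded to the nearest integer with ties away from
zero, the convention that maps the published counts (134/181, 13/70,
109/224, 93/172) onto the published integers (74 %, 19 %, 49 %, 54 %).
Geometric means are computed on strictly positive values only, with the
number of zeros (non-detects) reported alongside rather than fudged with
a detection-limit substitution.

## Deterministic exposure and risk

For a receptor with intake rate `IR`, exposure frequency `EF`
(days/year), duration `ED` (years), body weight `BW` (kg) and averaging
time `AT` (days), a route concentration `C` gives

    ADD = C × IR × EF × ED / (BW × AT)      [mg/kg/day]
    HQ  = ADD / RfD

The two receptors and their defaults:

| parameter | adult mother | infant | unit |
|-----------|--------------|--------|------|
| route `C` | household wheat | mother's breastmilk | µg/kg, µg/L |
| IR | 159.9 | 0.741 | g/day, L/day |
| EF | 350 | 182 | days/year |
| ED | 30 | 0.25 | years |
| BW | 71.7 | 7.4 | kg |
| AT | 22365 | 45.5 | days |
| RfD | 0.0003 | 0.0003 | mg/kg/day |

Unit handling is explicit: concentrations are converted µg → mg
(÷1000) and the adult food intake g/day → kg/day (÷1000); the infant
intake is volumetric against a per-litre concentration, so no milk
density enters. The infant averaging window equals its exposure window
(45.5 = 182 × 0.25 days); the adult AT of 22365 days is used verbatim as
the receptor's convention. Construction rejects parameter sets with
`AT < EF × ED`.

Two design points deserve a note. First, the route mapping: breastmilk,
blood and urine act as *biomarkers* (classification and association
stages), not as the mother's intake concentration — the mother's dietary
route is wheat, and only that mapping reproduces the deterministic
anchor `ADD(44.44 µg/kg) = 4.653 × 10⁻⁵ mg/kg/day`, `HQ = 0.1551`.
Second, the reference dose: RfD = 0.0003 mg/kg/day is the value under
which the anchor HQ comes out right; an RfD of 4 µg/kg/day sometimes
quoted for mercury reproduces no published quotient and is not used.

`risk_table()` pairs each mother with her household's wheat record and
each infant with the linked mother's milk record; subjects whose route
concentration is missing are skipped and counted, never imputed. ADD is
linear in `C`, so the cohort mean HQ equals the HQ of the mean
concentration — an identity the test suite exploits as an oracle.

## Monte Carlo uncertainty propagation

`fit_concentration()` fits a lognormal by maximum likelihood (through
fitdistrplus) to the strictly positive values of a matrix; zeros are
excluded but counted, giving a zero-inflation weight. `run_mc()` draws
`n_draws` concentrations (default 10,000) — zero with the inflation
probability, lognormal otherwise — and maps each draw through the same
ADD/HQ code path as the deterministic stage. Only the concentration is
randomised: every other factor is a point value by design, so the HQ
distribution is exactly the concentration distribution scaled by a
constant.

Consequences used for validation:

* a degenerate fit (`sdlog = 0`) collapses the MC to the deterministic
  value with zero spread;
* the MC mean converges to
  `(1 − w₀) · exp(µ_log + σ_log²/2) · k / RfD` (with `k` the linear ADD
  constant), checked at 10⁶ draws within 1 %;
* `P(HQ > 1)` equals the analytic lognormal tail beyond the
  concentration whose HQ is 1, within binomial error.

The PRNG is fixed (Mersenne-Twister with inversion sampling for
normals) and recorded in every output, so identical seed and
configuration give bit-identical results across runs. Deterministic
per-subject summaries and MC summaries are reported side by side: a
distributional maximum over 10⁴ draws is a tail order statistic and can
legitimately exceed the deterministic maximum computed from the largest
measured concentration, so the two kinds of "maximum HQ" must not be
conflated.

## Synthetic-cohort generator

The generator exists so every downstream stage runs, and is testable,
without the raw survey data. It emulates the campaign's *structure*:

* 224 mothers (all with urine), of whom 181 give milk and 70 give
  blood; 172 infants, each linked to a milk-donating mother (the studied
  infants are the breastfed children of the milk cohort, and this
  linkage keeps the infant route and the milk–urine pairing complete);
  53 of the 224 households with a wheat sample; one uniform GPS point
  per household inside lat 24.3–27.5, lon 83.3–88.3 (the Gangetic-plain
  study region), shared by all records of that household.
* Per-matrix lognormal margins — the standard model for non-negative,
  right-skewed environmental concentrations — *calibrated* by solving a
  2×2 system: `P(X > limit)` equals the published exceedance fraction
  exactly (the log-limit is the corresponding quantile, a linear
  relation between `µ_log` and `σ_log`), and the expected maximum of
  `n` draws equals the published maximum (root-finding on `σ_log`
  through the order-statistic integral). Calibration targets: milk
  134/181 above 1.7 with max 61.91; blood 13/70 above 20 with max
  38.35; maternal urine 109/224 above 10 with max 151.34; child urine
  93/172 above 10 with max 137.56.
* Dependence between a mother's milk and the two urine matrices through
  a Gaussian copula on the log scale. The latent correlations default to
  values derived from the closed-form raw-scale correlation of a
  bivariate lognormal, `r = (e^{ρσxσy} − 1)/√((e^{σx²}−1)(e^{σy²}−1))`,
  inverted at the published raw-scale r² targets (0.024 for child urine,
  0.108 for maternal urine). The closed form replaces a
  simulation-based mapping: it is exact under the generator's own model
  and is itself verified against simulation in the test suite.
* Food entirely below the 100 µg/kg limit, with the sample maximum
  pinned at exactly 44.44 µg/kg; the bulk of the values is lognormal
  (log-mean `log 8`, log-sd 0.8 — chosen once as a realistic
  low-contamination staple-food profile, placing the deterministic
  mother mean HQ in the few-percent range).
* Optional per-matrix non-detect probability (default 0), recording
  zeros — the mechanism by which an infant HQ minimum of exactly 0 can
  arise.

Numerical choices: values above 3× the calibrated maximum are rejected
and redrawn (redrawing the marginal score only, which perturbs the
copula negligibly at the default correlations) so that a single absurd
tail draw cannot dominate MC summaries; the calibration solver brackets
`σ_log` in [10⁻⁶, 15] and reports an explicit calibration error when no
root exists, e.g. a target maximum essentially equal to the limit.

What the generator does **not** emulate: measurement error and
censoring at a detection limit, household clustering of exposure,
covariates (age, diet, parity), spatial autocorrelation (points are
uniform), and any relation between blood and the other matrices (blood
is independent). Passing tests on synthetic cohorts therefore validate
the *procedures* — calibration, classification, risk math, fitting,
propagation — not the published data-dependent statistics.

## Association statistics

`pair_series()` builds milk–urine pairs through the linkage ids and
counts what it cannot pair. Two fits are offered:

* `simple_linear_fit()` — OLS with intercept on the raw scale (the
  interpretable primary analysis; a log–log variant is available for the
  skewed data). r² here is exactly the squared Pearson correlation, the
  adjusted value follows `1 − (1−r²)(n−1)/(n−k−1)`, p-values come from
  the F distribution, and no multiple-testing correction is applied
  (there are two tests, reported as is).
* `fixed_factor_fit()` — the general-linear-model variant that treats
  each distinct milk value as a categorical level. With continuous
  predictors this design is near-saturated: with every level a
  singleton the model reproduces the data exactly and R² = 1 *by
  construction*, with the adjusted value undefined. The fit reports a
  `saturated` flag and supports quantile binning instead of raw levels;
  its inflated R² is a property of the design, not evidence of
  explanatory power — which is precisely why both variants are
  reported.

Published r² values from the original campaign data are not
reproducible without that data; the package validates the procedures on
synthetic cohorts, where the median recovered raw-scale r² over many
seeds matches the generator's configured targets.

## Pipeline, export, reproducibility

`run_pipeline()` chains simulate (or load) → classify → risk → MC →
association → GeoJSON export, writing a manifest with the package
version, seed, RNG, config hash and per-file MD5 digests. Output is a
pure function of (config, seed, input digest) apart from the manifest
timestamp. Geospatial output is an RFC 7946 FeatureCollection (WGS84,
lon–lat order) per matrix — a data layer for any GIS, not a rendered
map; value bins default to the layer's quartiles with the exceedance
flag as a separate property. Records without coordinates are skipped
and counted; a cohort with no coordinates at all skips the export stage
with a warning rather than failing the run.

## Problem sizes used in validation

The shipped test suite works at the study's own scale (cohorts of a few
hundred records) plus: 10⁶ forward draws for calibration and MC-mean
convergence checks, 10⁵ values for the exceedance-convergence and tail
probability checks, 10⁴ values for MLE parameter recovery (±0.02), 200
seeded cohorts for the binomial-band check of the calibrated milk
exceedance, and 100 seeded replicates for the KS self-consistency and
r²-recovery checks. The full suite runs in well under a minute.

## Known limitations

* The route mapping is fixed (wheat for mothers, milk for infants);
  water, rice, fish or dermal routes would need new parameter sets and
  route pairings.
* The carcinogenic pathway (slope factors) is out of scope; no slope
  factor value is defined here.
* Lognormality is an assumption, not a finding: the fitting stage
  reports a KS statistic, and a poor fit should prompt a different
  family before trusting the MC tail.
* The MC propagates concentration uncertainty only; variability in
  intake rates or body weight is deliberately not modelled, matching the
  point-value parameterisation.
* Raw-data-dependent published statistics (MC means/maxima of the
  original cohort, r², adjusted R²) are covered qualitatively (ordering
  of infant vs mother risk, procedure-level oracles), not as numeric
  targets.
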