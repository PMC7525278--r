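---
title: "Methods and design notes for aquarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

`aquarisk` assesses tables of river or groundwater monitoring data — pH,
electrical conductivity (EC, µS/cm), total dissolved solids (TDS, mg/L),
the major ions Cl, SO₄, HCO₃, Na, K, Ca, Mg (mg/L) and the trace metals
Zn, Co, Cu, Ni, Pb (µg/L) — through six standard stages: guideline
screening, irrigation suitability, a weighted-arithmetic Water Quality
Index, hydrochemical facies, deterministic noncarcinogenic health risk,
and source-apportionment statistics. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the underlying conventions are ambiguous.

## Data model and unit handling

A `water_dataset` couples a per-sample table with a parameter reference
table (`who_parameter_table()`) carrying units, guideline values and WQI
weights. Validation is strict: concentrations must be nonnegative, pH must
lie in [0, 14], and missing values must be explicit `NA`s. The single
documented default is carbonate: `co3` is taken as 0 mg/L when absent,
because routine alkalinity titrations at near-neutral pH report
bicarbonate only.

Ionic indices are defined in milliequivalents per litre; `to_meq()`
converts with standard atomic weights (Na 22.99/1, K 39.10/1, Ca 40.08/2,
Mg 24.31/2, Cl 35.45/1, SO₄ 96.06/2, HCO₃ 61.02/1, CO₃ 60.01/2), shipped
as an editable table (`ion_constants()`).

Guideline exceedance uses a strict `>` comparison — a sample exactly at
the guideline is compliant — and the pH guideline is the two-sided range
6.5–8.5, with exceedance meaning falling outside it on either side. All
other guidelines are upper bounds.

Standard errors in `descriptive_stats()` derive from the sample (n−1)
standard deviation as `se = sd/sqrt(n)`; this convention reproduces
published survey tables that print both columns to within one unit in the
last printed digit (e.g. sd 21.01 at n = 30 gives se 3.84 against a
printed 3.83).

## Irrigation suitability

Five classical indices are computed on meq/L inputs:

* SAR = Na / √(Ca + Mg). This is the literal published form and the
  package default (`sar_convention = "paper"`); the USDA convention
  divides Ca + Mg by 2 inside the root and is available as
  `"standard"`. Keeping both behind a switch reproduces the source
  definition while exposing the conventional one.
* Na% = (Na + K) · 100 / (Ca + Mg + Na + K).
* RSC = (HCO₃ + CO₃) − (Ca + Mg), possibly negative.
* MAR = Mg · 100 / (Ca + Mg).
* KR = Na / (Ca + Mg).

Salinity classes C1–C4 cut EC at 250, 750 and 2250 µS/cm; alkalinity
classes S1–S4 cut SAR at 10, 18 and 26. Published class tables quote
overlapping bounds ("250–750", "750–2250"), so interval boundaries here
are deterministically lower-inclusive: 250 µS/cm is C2, SAR 18 is S3.
Suitability verdicts follow the published cut-offs (Na% 30/60, RSC
1.25/2.5, MAR 50, KR 1/3). The KR rule only names values below 1
(suitable) and above 3 (unsuitable); the open interval between is labelled
"marginal" here, as the gap is otherwise undefined. Zero alkaline-earth
denominators yield `NA` markers rather than errors, so degenerate waters
survive batch processing.

## Water Quality Index

The weighted-arithmetic index is

WQI = Σᵢ Wᵢ · (Cᵢ / Sᵢ) · 100,

with Cᵢ the measured concentration, Sᵢ the guideline and Wᵢ = wᵢ/Σwᵢ the
relative weight derived from integer assigned weights wᵢ ∈ {1..5} (Pb
carries 5; the shipped table sums to 44). Because ΣWᵢ = 1, a water sitting
exactly at every guideline scores 100; the index is linear in every
concentration.

Three decisions deserve note:

* **Relative weights are always recomputed from wᵢ.** The printed
  relative-weight column of the source compilation does not normalise
  (it sums to 0.63) and is inconsistent with wᵢ/Σwᵢ; it is retained via
  `wqi_scheme(use_printed_wi = TRUE)` for comparison runs only.
* **pH enters through Sᵢ = 8.5**, the upper bound of its guideline range,
  the common WQI convention for pH; the denominator is configurable
  (e.g. 7.5 for the range midpoint). This is an assumption, flagged as
  such.
* **The 50–100 band is labelled "good".** The published class list jumps
  from "< 50 excellent" to "100–200 poor", leaving 50–100 unnamed, while
  its own prose calls a mean of 77 "poor"; the conventional five-band
  scheme is used here and the conflict documented. Bands are
  lower-inclusive (a score of exactly 100 is "poor").

Applying the index to the published mean concentrations with formula
weights gives ≈ 57.9. The corresponding published per-sample summary
(range 13.58–209, mean 77) is not reproducible from printed summary
statistics alone — it requires the unpublished raw samples — so it is
treated as context, not as a check.

## Hydrochemical facies

`gibbs_ratios()` computes the classical mechanism ratios Na/(Na+Ca) and
Cl/(Cl+HCO₃) against TDS. Ratios are mass-based (mg/L) by default,
matching the usual axis labels; a meq basis is available since the
literature is not unanimous. The three Gibbs zones (precipitation, rock,
evaporation dominance) have no analytic boundaries anywhere — published
diagrams draw the "boomerang" freehand — so `classify_gibbs()` tests
points against an **editable, documented polygon set**
(`default_gibbs_polygons()`, vertices in ratio × log₁₀ TDS space)
approximating the canonical shapes, and returns `"indeterminate"` outside
them. The zone call is heuristic cartography by construction; the ratios
are exact.

`chadha_classify()` places each sample by the meq-percentage differences
x = %(Ca+Mg) − %(Na+K) over total cations and y = %HCO₃ − %(Cl+SO₄) over
total anions; the sign quadrant gives the facies (1 Ca–HCO₃, 2 Ca–Mg–Cl,
3 Na–Cl, 4 Na–HCO₃). Points exactly on an axis are assigned
deterministically to the higher-numbered adjacent field and flagged
`boundary`, so the four fields partition the plane.

## Noncarcinogenic health risk

The deterministic USEPA exposure model for water:

* ADD_ingestion = Cw · IR · EF · ED / (BW · AT)
* ADD_dermal = Cw · SA · Kp · EF · ET · ED / (BW · AT)
* HQ = ADD / RfD, HI = HQ_ingestion + HQ_dermal (exact sum)

with receptor defaults adult {IR 2 L/d, SA 1800 cm², EF 350 d/yr, ET
0.58 h/d, ED 70 yr, BW 65 kg, AT 25550 d} and child {0.64, 6660, 350,
1.0, 6, 20, 2190}, and per-metal reference doses (µg/kg/day) and dermal
permeabilities Kp (cm/h) in `rfd_defaults()`. Quotients strictly above 1
are flagged.

The dermal equation is implemented **without** the conventional cm³→L
volumetric factor by default: hand recomputation shows the published
adult dermal quotients (Cu 0.04187, Ni 0.31754, Pb 0.0341) reproduce only
under that reading. `units = "physical"` applies CF = 0.001 L/cm³ and
yields doses exactly 1000-fold smaller, for dimensionally conventional
assessments. Related exclusions: the published Co row implies a water
concentration inconsistent with the same table's mean, and the published
child dermal quotients are not reproducible under any single convention
tried, so neither is used as a reference check; the gastrointestinal
absorption fractions are carried as metadata only because they conflict
with the printed dermal/ingestion RfD ratios.

`risk_report()` evaluates either the dataset's arithmetic mean
concentration per metal (`statistic = "mean"`, the summary-level
assessment) or every sample (`"per_sample"`).

## Source-apportionment statistics

`pearson_matrix()` returns Pearson coefficients with two-tailed p-values
from the exact t transform on n − 2 degrees of freedom and star flags at
0.05/0.01. `bartlett_sphericity()` implements
χ² = −(n − 1 − (2p+5)/6)·ln det R with p(p−1)/2 degrees of freedom, and
`kmo()` the Kaiser–Meyer–Olkin measure from anti-image (partial)
correlations via the scaled inverse of R.

`pca_varimax()` eigendecomposes the correlation matrix (so eigenvalues
sum to the number of variables and variance percentages to 100), retains
components with eigenvalue > 1 (Kaiser rule), and varimax-rotates the
retained loadings with Kaiser normalisation at tolerance 1e−6 (via
`stats::varimax`). Two conventions make output deterministic: each factor
is sign-flipped so its largest-magnitude loading is positive, and factors
are reordered by decreasing rotated variance. Orthogonal rotation
preserves per-variable communalities (asserted to 1e−8 in tests), and the
rotated solution is invariant to variable order up to sign/permutation.
When the eigenvalue spectrum is nearly flat (range < 0.5), Kaiser
retention is unstable and a warning is issued.

## The synthetic generator

No raw per-sample data accompany the source survey (n = 30), so the
generator emulates its published marginal summaries: each parameter is
drawn from a normal distribution truncated to the published [min, max],
with parent parameters moment-matched to the published mean and sd
(`fit_truncnorm()`). Naive truncation of N(mean, sd) would bias both
moments; matching solves two nested root problems instead: the truncated
mean is strictly increasing in the location µ, and the mean-matched
truncated sd is increasing in the scale σ toward a tilted-uniform
supremum. σ is capped at five interval widths — beyond that the shape is
at its limit and nothing more is attainable — with the location bracket
(±35 standardised units) wide enough that the mean always matches.

An important, verifiable limitation: **several published rows are jointly
unattainable by any truncated normal.** With the mean pinned, the
family's supremum sd is below the published sd for pH (attained 0.217 vs
0.38), EC (272.5 vs 289.25), TDS (148.3 vs 189.03), Na (5.66 vs 6.30),
K (3.75 vs 3.87), Mg (4.66 vs 4.77) and Ni (19.18 vs 21.01); these rows
describe strongly skewed (presumably lognormal-like) field data whose
mean sits close to the observed minimum. For such rows the fitter keeps
the mean exact, returns the closest attainable sd and flags
`converged = FALSE`; the flags travel with every generated dataset
(`attr(ds, "fits")`). Choosing a different marginal family would fit those
moments but would abandon the published min/max support; the truncated
normal with documented shortfalls was preferred as the more transparent
compromise.

Correlation structure is optional: `default_target_correlation()` is an
(approximate, editable) transcription of the published 12-variable
Pearson matrix — the printed symmetric halves disagree in sign for three
pairs, and the lower triangle is used with pH–Mg taken positive per the
accompanying text. The matrix is repaired to the nearest positive
semidefinite correlation (`Matrix::nearPD`) if needed, and its **rank**
structure is imposed by reordering each column against a correlated
Gaussian reference (Iman–Conover style). Reordering is
distribution-preserving — the sorted values of every marginal are
untouched — and realises rank correlations within about ±0.1 of the
target at n = 1000.

What passing tests on synthetic data do and do not show: the generator
reproduces marginal ranges, attainable moments and approximate pairwise
rank structure, but not the unknown joint distribution, spatial layout or
measurement error of the real survey. Stage outputs on synthetic data
(e.g. Chadha field counts, PCA loadings) are therefore structural checks,
not reproductions of the published per-sample results.

## Numerical and testing choices

* All interval classifications are lower-inclusive; ties in guideline
  screening are compliant; HQ/HI flags are strict (> 1).
* Pipeline tables are written at six significant digits, making repeat
  runs byte-identical for regression diffing.
* One seeded generator drives all randomness; seeds are echoed in every
  report.
* Problem sizes used by the test suite: moment recovery is asserted at
  n ∈ {100, 1000, 10000} with a tolerance schedule; partition
  exhaustiveness on 10⁵ random ion vectors; factor recovery at n = 2000
  over three seeds with maximum loading error < 0.15; KMO against a
  brute-force partial-correlation oracle at 1e−10.

## Known limitations

* The Gibbs zone call is heuristic; treat it as a label for plotting, not
  an inference.
* Mean-mode risk uses the arithmetic mean concentration; no Monte-Carlo
  uncertainty propagation, carcinogenic slope factors or inhalation
  pathway.
* Only the weighted-arithmetic WQI is implemented (no CCME/NSF/entropy
  variants); no Wilcox/USSL or Piper diagram rendering.
* The generator cannot exceed the truncated-normal sd supremum described
  above, and transcribed reference tables inherit the ambiguities of
  their extracted source (kept editable for that reason).
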