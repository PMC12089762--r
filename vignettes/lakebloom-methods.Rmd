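---
title: "Models and methods behind lakebloom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lakebloom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakebloom)
```

## The problem

Surface accumulations of bloom-forming phytoplankton (notably cyanobacteria)
are visible in daily satellite reflectance as patches with elevated
near-infrared reflectance and green color. Turning two decades of daily
multi-band composites into defensible statements about bloom *frequency*,
*onset*, *persistence*, their *trends*, and their *drivers* requires a chain
of small decisions — thresholds, windows, weighting, eligibility rules —
each of which this vignette makes explicit. The package operates on
per-lake raster time series plus per-lake meteorological and nutrient
series; everything upstream of that (atmospheric correction, mosaicking,
lake boundary extraction) is out of scope.

## Detection model

A pixel is bloom iff it is a valid in-lake observation and passes three
independent screens.

**nFAI threshold.** The floating algae index is the 859 nm reflectance
excess over the linear baseline interpolated between 645 and 1240 nm. The
index is brightness-normalized as `nFAI = FAI / (R555 + R645 + R859)`;
the denominator is positive for physical water/bloom spectra, so the
normalization preserves sign. The threshold defaults to 0.02
(dimensionless) and is exposed in `detection_params()` because published
work defers the exact operating point to algorithm-specific calibration;
raising it can only shrink the detected set (a tested monotonicity
invariant).

**Chromaticity screen.** The color space is CIE (x, y). No standard fixes
which linear RGB→XYZ transform applies to satellite bands, so we adopt the
sRGB/D65 matrix applied to (R645, R555, R443) as (R, G, B) — a documented,
reproducible choice — and a default green region `x < 0.35, y > 0.35,
y > x` around the green locus. Both the matrix image and the region are
configurable (a polygon in (x, y) is accepted). Pixels with zero tristimulus
sum are unclassifiable and treated as non-green.

**Water-presence exclusion.** Floating-leaved vegetation (lotus, water
chestnut, etc.) shares the bloom signature but grows where historical
open-water presence is low. Pixels with water presence below 0.75 are never
flagged. The 0.75 default is a convention — the screen's purpose is
categorical (vegetated fringe vs open water), and the synthetic fringe is
generated at 0.3 vs 0.95, far from the cutoff.

Ice seasons are handled at the scene level: for lakes with an ice season,
dates inside freeze–melt are invalid by construction and `detect_bloom()`
refuses them as a precondition violation; the pipeline records them as
zero-valid days.

## From daily areas to annual metrics

The daily statistic is the cloud-weighted frequency
`(A_Bloom/A_valid) · (A_valid/A_Lake)²`: the observed bloom fraction
down-weighted by the squared observed-area fraction, so near-cloud-free days
dominate. It is implemented in a factored form so that full coverage
(`A_valid = A_Lake`) reduces *exactly* to `A_Bloom/A_Lake`, and a day with
no valid pixels contributes 0.

Within each bloom year we apply a 15-day centered running mean. Two
conventions matter and are deliberate:

* **Unobserved days are skipped, not zero-filled.** Zero-filling would
  conflate cloud cover with bloom absence and bias the smoothed level
  downward in cloudy periods.
* **Edges truncate.** The window shrinks at the window boundaries rather
  than padding with invented data. A mass-accounting test verifies the
  truncation exactly.

Onset is the first day with positive detected bloom area; persistence is the
*inclusive* span from first to last bloom day, so a single bloom day has
persistence 1 (the natural reading that persistence is positive exactly when
blooms exist); the annual frequency is the median of the smoothed series
over the persistence span. Onset is reported as a 1-based day-of-year
relative to the window anchor, which keeps Northern and Southern lakes
comparable.

**Bloom-year windows.** Northern lakes and frozen lakes use the calendar
year (restricted to the melt–freeze ice-free span when an ice season
exists; the anchor stays Jan 1, so onset remains a calendar day-of-year).
Non-frozen Southern-Hemisphere lakes use July 1 – June 30 labelled by the
starting year, so an austral Dec–Feb season is one contiguous span, never
split at Jan 1 (a tested invariant).

## Trends

Lakes qualify for trend analysis when blooms occurred in at least half of
their observed years (`2 · bloom_years ≥ observed_years`): with a 20-year
record this is the familiar "at least 10 years" rule, and a 7-of-14 lake
sits exactly on the eligible boundary. Change rates are plain OLS slopes of
annual values on year — not Theil–Sen or Mann–Kendall — because the target
quantity is an annual linear change rate; the slope's two-sided t-test
(n − 2 df) at α = 0.05 yields four exhaustive classes (Sig. Inc., Inc.,
Sig. Dec., Dec.). A slope of exactly zero is classified with the
increasing branch; ties are measure-zero for real data and the choice only
stabilizes degenerate fixtures. No multiple-testing correction is applied
across lakes: the class counts are descriptive.

The OLS machinery is hand-rolled in closed form (and cross-checked against
`stats::lm` in the tests) for one reason: perfect fits have zero residual
variance, where `lm`'s p-value degenerates to NaN; we define p = 0 for a
nonzero perfect slope and p = 1 for a flat line.

**Relative growth rate.** "Percent per year" needs a base. We divide the
slope of the global median series by its *long-term mean* (× 100), not by
the first-year value — the mean is robust to first-year noise — and the
rate is invariant to positive rescaling of the series. The same convention
applies per lake in the period comparison (2003–2015 vs 2016–2022 by
default), where per-lake rates are compared with a matched pair t-test,
again in closed form so that identical periods give t = 0, p = 1 instead of
an error on constant differences.

## Driver attribution

Daily bloom frequency responds to weather within hours to days, so daily
correlations are same-day Pearson (a lag option exists for sensitivity
checks; Spearman is available but not default, since the working model is a
linear association). Days without valid observations are excluded — they
carry no bloom information. Nutrient forcing operates inter-annually, so
fertilizer and N-input correlations use annual frequencies over the
overlapping years only.

The ten nitrogen input categories (NH4/NO3 fertilizer on cropland and
pasture; manure applied to cropland/pasture; manure deposited on
pasture/rangeland; NHx and NOy deposition) aggregate into fertilizer
(i–iv), manure (v–viii), atmospheric (ix–x), cropland (i, ii, v) and
pasture (iii, iv, vi, vii) subsets; the total is the exact sum of the ten,
enforced before correlating.

A lake's best factor is the one with the largest *absolute* significant
correlation — wind and precipitation suppress surface blooms, so their
effect is negative but no less real — with ties broken by a fixed ordering
(temperature, precipitation, wind, N fertilizer, P fertilizer). A lake with
no significant factor is "others". Whether signed or absolute r is "the
highest" correlation is a genuine ambiguity; the choice is recorded in the
report metadata.

## The synthetic world

The simulator exists to exercise every downstream code path with known
truth, not to be radiometrically realistic. Its defaults are fixed once:

* **World size.** 20 lakes, 2003–2022, 16×16 equal-area grids at 0.25 km²
  per pixel (MODIS-like 500 m), so a full lake is 64 km² — consistent with
  a "large lake" threshold of 50 km². 25% of lakes are Southern-Hemisphere;
  25% of Northern lakes get an ice season (freeze day 330, melt day 110).
* **Bloom occurrence.** A daily Bernoulli draw from a logistic model,
  `logit p = −7 + 0.3·T + trend·(year − 2003)`, giving p ≈ 0.03 at 10 °C
  and p ≈ 0.67 at 26 °C — blooms concentrate in the warm season without
  being deterministic. A designed season mode (`bloom_model$season`)
  replaces the logistic model with a fixed window for phenology-recovery
  tests.
* **Reflectance.** Three reference spectra (water, bloom, cloud) chosen to
  place water below the nFAI baseline and outside the green region, blooms
  far above/inside, clouds white and invalid; i.i.d. Gaussian band noise
  (sd 0.002) perturbs them. Bloom patches are small nearshore discs placed
  just inside the low-water-presence fringe — the paper-scale observation
  that blooms hug shallow nearshore zones is a free choice here, not an
  inference.
* **Meteorology.** Sinusoidal air temperature (mean 12 °C, amplitude 12 °C,
  noise sd 2 °C, peak day 200 in the north, day 17 in the south), optional
  linear warming; gamma wind; intermittent exponential rain.
* **Censoring.** Clouds are i.i.d. per-pixel Bernoulli per day (default
  0.2) — no spatial correlation, which makes analytic coverage checks easy
  but understates real cloud clustering.
* **Reproducibility.** Each lake owns deterministic streams split from the
  master seed (geometry, met, nutrients, scenes), so any lake can be
  regenerated in isolation and the full pipeline is byte-reproducible.

What a green test therefore establishes: the *implementation* of detection,
weighting, phenology, trends and attribution is correct against exact
oracles and recovers designed truths under this stylized world. What it
does not establish: performance on real MODIS radiometry, mixed pixels,
spatially correlated clouds, lake-ice misclassification, or real nutrient
loading — no synthetic pass substitutes for validation against field data.

## Numerical choices and degenerate inputs

* Scene stacks serialize reflectance with `%.17g`, so write→read round
  trips are value-identical; reports round to 6 significant digits, below
  any signal here but stable across platforms.
* Zero-variance series are "incomputable" (NA) in correlations, never
  silently zero; constant paired differences give t = 0, p = 1.
* `X + Y + Z = 0` chromaticity pixels are unclassifiable → non-green.
* Fewer than 3 annual values → no trend; fewer than 10 matched days → no
  daily correlation; fewer than 5 overlapping years → no nutrient
  correlation.
* The environment provides no NetCDF or GeoTIFF bindings, so the scene
  store is a self-describing text format with the same information content
  (dimensions, band coordinates in nm, byte validity mask); readers
  validate required bands and sort a shuffled day coordinate with a
  warning.

## Known limitations

Detection is surface-only (no subsurface blooms, species or toxicity);
correlation-based attribution is not causal and ignores interactions and
lags beyond the optional daily lag; endorheic-lake exclusion is represented
only by a per-lake include flag; the simulator's spatial structure
(independent cloud pixels, disc-shaped patches, all-water rectangular
lakes) is deliberately minimal.
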