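# lakebloom

Quantifying surface algal blooms in large lakes from daily multi-band
satellite reflectance, for limnologists and remote-sensing analysts who need
bloom frequency, phenology, trends and candidate drivers from long daily
time series — and a fully synthetic test world to validate every stage
against known ground truth.

## What it computes

**Detection.** Each valid lake pixel of a daily scene (Rayleigh-corrected
reflectance at 443, 555, 645, 859 and 1240 nm) is classified as bloom when
all three conditions hold:

1. *Floating algae index.* The near-infrared excess over the red/SWIR linear
   baseline,

   `FAI = R(859) − [R(645) + (R(1240) − R(645)) · (859 − 645)/(1240 − 645)]`,

   normalized by brightness, `nFAI = FAI / (R555 + R645 + R859)`, exceeds a
   threshold (default 0.02).
2. *Green chromaticity.* The pixel's CIE chromaticity (x, y) — from mapping
   (R645, R555, R443) as (R, G, B) through the sRGB/D65 matrix — falls in a
   green region (default x < 0.35, y > 0.35, y > x), screening out clouds,
   shadows and other non-green features.
3. *Open-water history.* Historical water-presence probability ≥ 0.75,
   excluding floating-leaved vegetation fringes.

**Daily frequency.** With `A_Bloom` the detected bloom area, `A_valid` the
cloud-free observed lake area and `A_Lake` the lake area,

```
frequency = (A_Bloom / A_valid) · (A_valid / A_Lake)²
```

so low-cloud observations carry more weight.

**Phenology.** Within each bloom year (calendar year; ice-free melt–freeze
span for frozen lakes; July–June for non-frozen Southern-Hemisphere lakes),
onset is the first bloom day, persistence the inclusive first-to-last bloom
span, and the annual frequency the median of the 15-day running mean of the
daily frequency over that span.

**Trends.** Lakes blooming in at least half of their observed years get an
OLS slope of annual frequency on year, classified as Sig. Inc. / Inc. /
Sig. Dec. / Dec. at p < 0.05. The global median series is summarized as a
relative growth rate (slope / long-term mean × 100, %/yr), and early
(2003–2015) vs late (2016–2022) per-lake rates are compared with a matched
pair t-test.

**Drivers.** Daily frequency is correlated (Pearson) with same-day air
temperature, wind speed and precipitation; annual frequency with N/P
fertilizer usage and ten anthropogenic nitrogen input categories (plus the
fertilizer / manure / atmospheric / cropland / pasture subsets). Each lake
is labelled with the factor of largest significant |r|, or "others".
Fractions of bloom events above 20 °C and at or below 16 °C are reported.

## Worked example

```r
library(lakebloom)
cfg <- simulation_config(n_lakes = 3, years = c(2003, 2012), seed = 7)
g   <- generate_lake_geometry(cfg, 1)
met <- generate_met_series(cfg, 1)
lk  <- simulate_lake_records(g, met, cfg)    # scenes -> detection, streamed
head(annual_metrics(lk$records, g, cfg$years), 4)
#>      lake bloom_year onset persistence annual_frequency n_observations
#> 1 lake001       2003    88         216      0.010913086            366
#> 2 lake001       2004    96         219      0.010350545            365
#> 3 lake001       2005   134         165      0.013760376            365
#> 4 lake001       2006    93         209      0.009832764            365
```

Lake 001 blooms from spring (onset around day 90–130) for 165–219 days, and
its annual cloud-weighted bloom frequency is around 1 %. The full pipeline
aggregates all lakes:

```r
res <- run_pipeline(pipeline_config(sim = cfg))
#> eligible lakes: 3
#> trend classes: Sig. Inc.=0, Inc.=1, Sig. Dec.=0, Dec.=2
#> global relative rate: -0.87 %/yr (p = 0.570)
#> best factors: temperature
#> bloom events with T>20C: 77.8%, T<=16C: 6.9%
```

With the default (trendless) bloom model the global rate is statistically
indistinguishable from zero, every lake's blooms are attributed to air
temperature (which truly generated them), and most bloom events occur on
warm days — exactly what the simulated world prescribes.

## Command line

```sh
Rscript inst/cli/lakebloom.R run      --config config.yaml --out outdir
Rscript inst/cli/lakebloom.R simulate --config config.yaml --out simdir
Rscript inst/cli/lakebloom.R detect   --scenes simdir/lake001_scenes.csv \
    --geometry simdir/lake001_geometry.json --out detections.csv
```

Verbs: `simulate`, `detect`, `metrics`, `trends`, `drivers`, `run`. Exit
codes: 0 success, 2 config error, 3 data-format error, 4 stage failure.
Scene stacks are self-describing text files (JSON header + long CSV) so the
whole toolchain is portable and diff-able.

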