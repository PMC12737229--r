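# cwtburden

Receptor-oriented source attribution of fine particulate matter (PM2.5)
from ensemble back-trajectories, and the short-term health burden
associated with each source region.

## What it does

An air-quality monitoring site measures hourly PM2.5. A trajectory model
(e.g. HYSPLIT run in ensemble mode) supplies, for each arrival time, a set
of backward trajectories describing where the arriving air parcel has
been. `cwtburden` turns these two inputs into:

1. a **concentration-weighted trajectory (CWT) field** on a regular
   longitude–latitude grid — each cell gets the residence-weighted mean of
   the receptor concentrations observed when trajectories crossed it,

   C_ij = ( Σ_l C_l τ_ijl / Σ_l τ_ijl ) · W(n_ij),

   where τ_ijl counts endpoints of trajectory *l* in cell *(i,j)*,
   n_ij = Σ_l τ_ijl, and W is the standard piecewise sparse-cell weight
   (1.00 / 0.70 / 0.42 / 0.05 relative to the mean cell count);
2. **per-sector source shares** (field integrals over named rectangular
   source regions — five defaults tile the domain around the Beijing
   receptor at 39.98° N, 116.40° E) and **per-arrival-time air-mass
   fractions**, with each day labelled by its dominant source;
3. a **daily health-burden series**: relative risk
   RR = exp(β_eff (C − C0)) and attributable fraction AF = (RR − 1)/RR,
   with sensitivity analysis over the concentration–response coefficient
   β (default 0.38, range 0.31–0.45, explicit scale parameter), and
   box-whisker summaries (mean, 10/25/75/90th percentiles) of PM2.5 and
   AF by source region.

It reads and writes HYSPLIT-style endpoint ("tdump") files and plain CSV
series, and ships a regime-switching synthetic scenario generator
(five wind regimes, 27-member ensembles, calibrated winter concentration
and meteorology distributions) so the entire pipeline is testable without
external meteorological archives.

## Worked example

```r
library(cwtburden)

cfg <- scenario_config(n_days = 10, seed = 42)   # synthetic winter scenario
sc  <- simulate_scenario(cfg)                    # trajectories + hourly PM2.5

fit <- cwt(sc$trajectories, sc$concentrations)   # fit the CWT field
fit
#> Concentration-weighted trajectory field
#>   2160 trajectories over 80 arrival times; grid 48 x 36 (0.25 deg)
#>   occupied cells: 920 of 1728; n_ave (occupied) = 53.14; weighting on
#>   field range: 0.514 .. 29.754 ug/m3; 5110 endpoints outside domain

sector_integrals(fit)                            # where did the pollution reside?
#>   sector n_cells n_defined integral  share
#> 1  local      54        51      795 0.1726
#> 2   west     812       459     1809 0.3927
#> 3  north     304       256      763 0.1655
#> 4   east     140        85     1064 0.2309
#> 5  south     418        69      176 0.0382

days <- dominant_source_per_day(
  timewise_fractions(fit, weighting = "count"))  # daily origin labels
head(days, 4)
#>         date source   tie n_records
#> 1 2024-01-01  north FALSE         8
#> 2 2024-01-02  north FALSE         8
#> 3 2024-01-03  local FALSE         8
#> 4 2024-01-04   west FALSE         8
sc$regimes[1:4]                                  # generating truth
#> [1] "north" "north" "local" "west"

b <- health_burden(sc$concentrations, labels = days)
head(as.data.frame(b), 3)
#>         date    C n_hours complete   RR    AF AF_min AF_max source
#> 1 2024-01-01 22.0      24     TRUE 1.65 0.394  0.335  0.447  north
#> 2 2024-01-02 16.4      24     TRUE 1.45 0.311  0.262  0.356  north
#> 3 2024-01-03 10.0      24     TRUE 1.26 0.204  0.170  0.237  local

burden_by_source(b)                              # box-whisker stats by source
#>   variable group n   mean    p10    p25    p75    p90
#> 1       AF north 2  0.352  0.319  0.331  0.373  0.386
#> 2       AF local 2  0.355  0.234  0.279  0.430  0.475
#> ...
```

The daily mean concentration feeds the exponential dose–response, so AF
rises monotonically with PM2.5: the two clean northern-transport days get
AF ≈ 0.31–0.39 while westerly/easterly transport days reach ≈ 0.5. The
labels reproduce the generating regime sequence.

The full pipeline — field, attributions, daily labels, burden, per-source
summaries, run log — is one call over a plain-text configuration:

```r
conf <- system.file("extdata", "demo_scenario.conf", package = "cwtburden")
run_pipeline(conf, "demo_out")   # writes 5 CSVs + run.log, byte-reproducible
```

On the shipped 90-day demo the per-source mean AF ordering is
south > east > local > west > north, with south ≈ 0.74 and north ≈ 0.30.

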