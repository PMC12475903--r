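# hardivine

Grapevine bud cold hardiness modelling from daily weather-station records.

In cool-climate viticulture, midwinter freeze events kill dormant buds when
the air temperature drops below the buds' current cold hardiness, summarised
as **LT50** — the lethal temperature at which 50 % of primary buds die
(°C, negative). Hardiness is not static: buds **acclimate** (LT50 falls) as
winter chill accumulates and **deacclimate** (LT50 rises) in response to
heat, tracing a U-shaped trajectory over each dormant season. `hardivine`
implements the complete desk-scale pipeline for tracing this trajectory from
daily maximum/minimum temperatures alone:

1. **GHCNd I/O** — bit-exact readers/writers for the fixed-width daily
   element (`.dly`, tenths of °C) and station-inventory dialects.
2. **Curation** — the four-step station filter (record type, geographic
   band |lat| ∈ [30°, 55°], temporal cutoff 1960-01-01, ≥ 220 recorded days
   per season) and hemisphere-aware dormant-season segmentation
   (1 Sep → 1 May north, 1 Mar → 1 Nov south).
3. **Feature extraction** — hourly temperatures reconstructed from daily
   extremes via a sine-day/log-night diurnal curve, then a 126-feature
   predictor vector per station-day-cultivar: 4 daily descriptors, 7
   cumulative descriptors (Utah, North Carolina and chill-hours chilling;
   growing degree hours at bases 0/4/7/10 °C), 30 forward and 30 reverse
   exponentially weighted moving-average temperatures, 54 one-hot cultivar
   indicators, and days-in-season.
4. **Hardiness regression** — a seeded gradient-boosted tree ensemble
   (xgboost) mapping features to LT50, with held-out evaluation (RMSE, °C)
   and permutation feature importance.
5. **Cold damage** — the potential (0–100) that a day injured buds, scored
   by a symmetric logistic in the gap between the daily minimum and LT50:

   ```
   D(tmin, LT50) = 100 / (1 + exp(k (tmin − LT50))),   k = ln(9)/2
   ```

   the unique logistic with D = 10 at tmin = LT50 + 2 °C and D = 90 at
   tmin = LT50 − 2 °C.
6. **Climatology** — per-season summaries (minimum temperature, deepest
   LT50, maximum damage), multi-decade window averages, k-nearest-neighbour
   gridding of station values under great-circle distance, and the
   cosine-latitude-weighted feasible-area fraction (share of territory with
   damage below a threshold, default 20 %).
7. **Synthetic fixtures** — seeded generators for GHCNd-encoded weather
   (annual sinusoid + AR(1) noise + missingness) and U-shaped LT50 ground
   truth expressed in the extracted features, so the whole pipeline is
   testable offline.

Everything is tibble-in/tibble-out and pipe-friendly; `ggplot2` helpers
(`plot_season_hardiness()`, `plot_damage_grid()`, `autoplot()`) and
broom-style `tidy()`/`glance()` methods cover the result types.

## Worked example

```r
library(hardivine)
library(dplyr)

# six years of synthetic weather at a 43°N station, GHCNd-style
w   <- sim_station_weather(weather_gen_config(years = 6, start_year = 1987, seed = 42))
cur <- curate(w$meta, w$daily)
cur
#> <hardivine_curation> 1/1 stations kept, 5 dormant seasons

feats <- extract_features(cur, w$meta, cultivars = c("Riesling", "Concord"))
truth <- sim_lt50_truth(feats, lt50_gen_config(noise_sd = 1, seed = 43))
m     <- train_lt50_model(feats, truth$lt50, seed = 7)
m
#> <lt50_model> 126 features, 2182 training rows, held-out RMSE 1.216 C (seed 7)

pred  <- predict_lt50(m, filter(feats, season_label == 1988, cultivar == "Riesling"))
season_summary(pred, cur$seasons$daily[[which(cur$seasons$season_label == 1988)]])
#> # A tibble: 1 × 5
#>   station_id  cultivar min_temperature max_hardiness max_damage
#>   <chr>       <chr>              <dbl>         <dbl>      <dbl>
#> 1 SYN0000001X Riesling           -16.8         -29.7       8.15
```

The held-out RMSE (1.22 °C) is the model's prediction error on the 10 % of
rows reserved before fitting. The season summary says the 1988–89 dormant
season bottomed out at −16.8 °C while predicted Riesling hardiness reached
−29.7 °C, and the riskiest single day carried an 8.2 % damage potential.

A command-line wrapper over the same functions ships in
`inst/cli/hardivine.R`, with subcommands `simulate`, `curate`, `features`,
`train`, `predict`, `damage`, `summarize`, `windows`, `grid` and `feasible`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hardivine.R", package = "hardivine"))')
Rscript $CLI simulate --seed 7 --out sim
Rscript $CLI curate --input sim --stations sim/stations.txt --out cur
```

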