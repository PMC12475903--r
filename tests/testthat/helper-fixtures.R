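# Shared fixtures, generated in code and cached per test run.

`%||%` <- rlang::`%||%`

.fixtures <- new.env(parent = emptyenv())

# simple constant-or-vector daily series on a contiguous calendar
make_daily <- function(start, n, tmax = 10, tmin = 0,
                       station = "TEST0000001") {
  tibble::tibble(
    station_id = station,
    date = as.Date(start) + seq_len(n) - 1L,
    tmax = rep_len(tmax, n),
    tmin = rep_len(tmin, n)
  )
}

# one full northern dormant-season calendar with mild seasonal structure
make_season_daily <- function(label = 1990, station = "TEST0000001",
                              tmean_winter = -5, tmean_shoulder = 15) {
  start <- as.Date(sprintf("%d-09-01", label))
  end <- as.Date(sprintf("%d-05-01", label + 1))
  dates <- seq(start, end - 1, by = "day")
  frac <- as.numeric(dates - start) / length(dates)
  tmean <- tmean_shoulder + (tmean_winter - tmean_shoulder) *
    sin(pi * frac)^2 * 1.6
  tibble::tibble(
    station_id = station, date = dates,
    tmax = tmean + 4, tmin = tmean - 4
  )
}

# cached multi-season synthetic station: weather -> curation -> features ->
# synthetic LT50 truth (two cultivars keeps it quick)
recovery_fixture <- function() {
  if (is.null(.fixtures$recovery)) {
    w <- sim_station_weather(weather_gen_config(
      years = 8, start_year = 1985, seed = 11, missing_prob = 0.01
    ))
    cur <- curate(w$meta, w$daily)
    feats <- extract_features(cur, w$meta,
                              cultivars = c("Riesling", "Concord"))
    truth <- sim_lt50_truth(feats, lt50_gen_config(noise_sd = 1, seed = 5))
    .fixtures$recovery <- list(w = w, cur = cur, feats = feats, truth = truth)
  }
  .fixtures$recovery
}

# flat hourly series at a constant temperature, n_days long
make_hourly_const <- function(temp, n_days = 1, start = "1990-01-01",
                              station = "TEST0000001") {
  dates <- as.Date(start) + seq_len(n_days) - 1L
  tibble::tibble(
    station_id = station,
    date = rep(dates, each = 24L),
    hour = rep(0:23, times = n_days),
    temp = temp
  )
}
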