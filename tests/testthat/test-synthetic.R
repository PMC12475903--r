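test_that("weather generation is byte-identical under a fixed seed", {
  cfg <- weather_gen_config(years = 2, seed = 123)
  l1 <- encode_dly(sim_station_weather(cfg)$daily)
  l2 <- encode_dly(sim_station_weather(cfg)$daily)
  expect_identical(l1, l2)
  l3 <- encode_dly(sim_station_weather(weather_gen_config(years = 2,
                                                          seed = 124))$daily)
  expect_false(identical(l1, l3))
})

test_that("missingness and the annual mean match their configured statistics", {
  cfg <- weather_gen_config(years = 10, missing_prob = 0.05, seed = 77)
  d <- sim_station_weather(cfg)$daily
  n <- nrow(d)
  miss <- sum(is.na(d$tmax))
  # 99% binomial interval around the configured probability
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(miss, bounds[1])
  expect_lte(miss, bounds[2])

  tmean <- (d$tmax + d$tmin) / 2
  # CLT bound: AR(1) inflates the se of the mean by sqrt((1+phi)/(1-phi))
  se_iid <- cfg$noise_sd / sqrt(sum(!is.na(tmean)))
  se <- se_iid * sqrt((1 + cfg$ar1) / (1 - cfg$ar1))
  expect_lt(abs(mean(tmean, na.rm = TRUE) - cfg$annual_mean), 3 * se + 0.1)
})

test_that("the seasonal phase is hemisphere-correct", {
  n_cfg <- weather_gen_config(latitude = 45, years = 4, noise_sd = 0.5,
                              missing_prob = 0, seed = 5)
  s_cfg <- weather_gen_config(latitude = -35, years = 4, noise_sd = 0.5,
                              missing_prob = 0, seed = 5)
  dn <- sim_station_weather(n_cfg)$daily
  ds <- sim_station_weather(s_cfg)$daily
  month <- function(d) as.integer(format(d$date, "%m"))
  jan_n <- mean(dn$tmax[month(dn) == 1])
  jul_n <- mean(dn$tmax[month(dn) == 7])
  expect_lt(jan_n, jul_n)
  jan_s <- mean(ds$tmax[month(ds) == 1])
  jul_s <- mean(ds$tmax[month(ds) == 7])
  expect_gt(jan_s, jul_s)
})

test_that("network generation plants a recoverable spatial field", {
  const <- sim_station_network(15, field = function(lat, lon) rep(42, length(lat)),
                               seed = 3)
  expect_true(all(const$value == 42))
  expect_identical(const,
                   sim_station_network(15,
                                       field = function(lat, lon) rep(42, length(lat)),
                                       seed = 3))

  # north-south gradient: a KNN grid reproduces it to within the spacing bound
  grad <- function(lat, lon) 100 - 4 * (lat - 35)
  net <- sim_station_network(60, lat_range = c(35, 50),
                             lon_range = c(-100, -70), field = grad, seed = 9)
  cells <- tidyr::expand_grid(latitude = seq(37, 48, by = 1),
                              longitude = seq(-97, -73, by = 2))
  g <- knn_grid(net, cells, k = 3)
  truth <- grad(cells$latitude, cells$longitude)
  mae <- mean(abs(g$value - truth))
  # 60 stations over 15 degrees of latitude: mean spacing ~1.4 degrees, and
  # the gradient moves 4 units per degree -> errors well under 8 units
  expect_lt(mae, 8)
})

test_that("the LT50 truth formula hits its closed-form corners", {
  reg <- cultivar_registry()
  cfg <- lt50_gen_config(noise_sd = 0, vinifera_offset = 0, hybrid_offset = 0)
  mk_feat <- function(chill, gdh10) {
    tibble::tibble(
      station_id = "S1", season_label = 1990L,
      date = as.Date("1990-09-01") + seq_along(chill) - 1,
      cultivar = "Concord", chill_cu = chill, gdh_base10 = gdh10
    )
  }
  # zero chill, zero heat: ceiling
  t0 <- sim_lt50_truth(mk_feat(0, 0), cfg, reg)
  expect_equal(t0$lt50_true, cfg$lt50_max)
  # saturated chill, zero heat: floor
  t1 <- sim_lt50_truth(mk_feat(cfg$chill_requirement * 2, 0), cfg, reg)
  expect_equal(t1$lt50_true, cfg$lt50_min)
  # a hardier cultivar class shifts the whole curve down
  cfg2 <- lt50_gen_config(noise_sd = 0, hybrid_offset = -2)
  tv <- sim_lt50_truth(mk_feat(0, 0), cfg2, reg)
  expect_equal(tv$lt50_true, cfg2$lt50_max - 2)
})

test_that("the seasonal LT50 trajectory is U-shaped with its trough in midwinter", {
  fx <- recovery_fixture()
  one <- dplyr::filter(fx$truth, cultivar == "Concord",
                       season_label == sort(unique(fx$truth$season_label))[2])
  one <- dplyr::arrange(one, date)
  trough <- which.min(one$lt50_true)
  n <- nrow(one)
  # the deepest hardiness falls in midwinter, not at either season edge
  expect_gt(trough, n * 0.2)
  expect_lt(trough, n * 0.8)
  # autumn acclimates (LT50 falls), spring deacclimates (LT50 rises)
  expect_lt(one$lt50_true[trough], one$lt50_true[10])
  expect_lt(one$lt50_true[trough], one$lt50_true[n - 10])
  # truth bounded by the configured band
  cfg <- lt50_gen_config()
  expect_true(all(fx$truth$lt50_true >= cfg$lt50_min &
                    fx$truth$lt50_true <= cfg$lt50_max + 2))
})

test_that("truth generation is a pure function of features and config", {
  fx <- recovery_fixture()
  f <- fx$feats[1:500, ]
  cfg <- lt50_gen_config(noise_sd = 1, seed = 5)
  t1 <- sim_lt50_truth(f, cfg)
  t2 <- sim_lt50_truth(f, cfg)
  expect_identical(t1, t2)
  expect_error(sim_lt50_truth(dplyr::select(f, -chill_cu), cfg), "chill_cu")
})

test_that("end-to-end recovery: train on synthetic truth, predict near the noise floor", {
  fx <- recovery_fixture()
  idx <- seq_len(2000)
  m <- train_lt50_model(fx$feats[idx, ], fx$truth$lt50[idx], seed = 77)
  expect_gte(m$rmse_holdout, 0.8)
  expect_lte(m$rmse_holdout, 1.5)
  # against the noiseless truth the model should do no worse than the noise
  p <- predict_lt50(m, fx$feats[m$holdout_idx, ])$lt50
  expect_lte(rmse(p, fx$truth$lt50_true[m$holdout_idx]), 1.5)
})
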