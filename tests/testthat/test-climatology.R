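k_sig <- log(9) / 2

test_that("season summaries take extreme hardiness, temperature and damage", {
  dates <- as.Date("1990-09-01") + 0:241
  daily <- tibble::tibble(date = dates, tmin = rep(-10, 242))
  daily$tmin[100] <- -15
  lt50 <- tibble::tibble(station_id = "S1", cultivar = "Riesling",
                         date = dates, lt50 = -20)
  s <- season_summary(lt50, daily)
  expect_equal(s$min_temperature, -15)
  expect_equal(s$max_hardiness, -20)
  # closed form: coldest day sits 5 C above LT50
  expect_equal(s$max_damage, 100 / (1 + exp(5 * k_sig)), tolerance = 1e-9)
  expect_lt(s$max_damage, 0.5)

  # a day with tmin = lt50 pushes max damage to at least 50
  daily$tmin[50] <- -20
  expect_gte(season_summary(lt50, daily)$max_damage, 50)

  # mild season: tmin always >= lt50 + 10 keeps damage negligible
  mild <- tibble::tibble(date = dates, tmin = -5)
  expect_lt(season_summary(lt50, mild)$max_damage, 0.01)

  expect_error(season_summary(lt50, tibble::tibble(date = as.Date("2020-01-01"),
                                                   tmin = 0)),
               "overlap")
})

test_that("window averages map seasons to windows and mean per station", {
  sums <- tibble::tibble(
    station_id = "S1",
    season_label = c(1965:1984),
    min_temperature = -20,
    max_hardiness = -25,
    max_damage = 10
  )
  w <- window_average(sums)
  expect_equal(sort(w$window), c("1960-1979", "1980-1999"))
  expect_equal(w$max_damage, c(10, 10))
  expect_equal(w$n_seasons[w$window == "1960-1979"], 15L)

  # station with seasons only in the 1990s appears in the middle window only
  nineties <- dplyr::mutate(sums, season_label = 1990:2009 - 10L)
  w2 <- window_average(dplyr::filter(nineties, season_label >= 1990))
  expect_equal(unique(w2$window), "1980-1999")

  # planted linear trend in damage orders the window means
  trend <- tibble::tibble(
    station_id = "S1", season_label = 1960:2024,
    max_damage = seq(60, 20, length.out = 65)
  )
  wt <- window_average(trend)
  wt <- wt[order(wt$window), ]
  expect_true(all(diff(wt$max_damage) < 0))

  # order invariance
  set.seed(1)
  wt2 <- window_average(trend[sample(nrow(trend)), ])
  expect_equal(dplyr::arrange(wt2, window), dplyr::arrange(wt, window))

  expect_error(
    window_average(sums, windows = list(a = c(1960, 1990), b = c(1985, 2000))),
    "overlap"
  )
})

test_that("knn gridding honours k = 1 coincidence, tie averaging and k = n pooling", {
  st <- tibble::tibble(
    station_id = c("A", "B"),
    latitude = c(40, 42), longitude = c(-80, -80),
    value = c(10, 30)
  )
  g1 <- knn_grid(st, tibble::tibble(latitude = 40, longitude = -80), k = 1)
  expect_equal(g1$value, 10)

  # midpoint on the same meridian is equidistant: mean of the two
  gmid <- knn_grid(st, tibble::tibble(latitude = 41, longitude = -80), k = 2)
  expect_equal(gmid$value, 20)

  # k = station count pools everything
  set.seed(12)
  net <- sim_station_network(8, field = function(lat, lon) runif(length(lat), 0, 100),
                             seed = 12)
  gall <- knn_grid(net, list(lat_range = c(36, 49), lon_range = c(-99, -71),
                             resolution = 2), k = 8)
  expect_true(all(abs(gall$value - mean(net$value)) < 1e-9))
  # convexity: cell values never exceed the station value range
  g5 <- knn_grid(net, list(lat_range = c(36, 49), lon_range = c(-99, -71),
                           resolution = 1), k = 3)
  expect_true(all(g5$value >= min(net$value) & g5$value <= max(net$value)))

  expect_error(knn_grid(st, g1[1, c("latitude", "longitude")], k = 3),
               "exceeds")
})

test_that("knn gridding matches an exhaustive brute-force oracle", {
  skip_if_not_installed("geosphere")
  net <- sim_station_network(
    20, lat_range = c(35, 50), lon_range = c(-100, -70),
    field = function(lat, lon) pmin(100, pmax(0, 90 - 3 * (lat - 35) +
                                                0.3 * (lon + 85))),
    seed = 21
  )
  cells <- tidyr::expand_grid(latitude = seq(36, 49, length.out = 10),
                              longitude = seq(-99, -71, length.out = 10))
  for (k in c(1, 3, 5)) {
    got <- knn_grid(net, cells, k = k)
    oracle <- vapply(seq_len(nrow(cells)), function(i) {
      d <- geosphere::distHaversine(
        cbind(net$longitude, net$latitude),
        c(cells$longitude[i], cells$latitude[i])
      )
      ord <- order(d, net$station_id)
      mean(net$value[ord[seq_len(k)]])
    }, numeric(1))
    expect_equal(got$value, oracle, tolerance = 1e-9)
  }
})

test_that("feasible area is cosine-weighted, thresholded and monotone", {
  grid <- tidyr::expand_grid(latitude = seq(30, 55, by = 1),
                             longitude = seq(-100, -70, by = 1))
  g10 <- dplyr::mutate(grid, value = 10)
  expect_equal(feasible_area(g10)$feasible_fraction, 1.0)

  g0 <- dplyr::mutate(grid, value = 5)
  expect_equal(feasible_area(g0, threshold = 0)$feasible_fraction, 0)

  # half the cells (all south of 42.5) feasible: cosine weighting makes the
  # southern share exceed the raw cell share
  ghalf <- dplyr::mutate(grid, value = ifelse(latitude <= 42, 10, 50))
  fr <- feasible_area(ghalf)$feasible_fraction
  manual <- sum(cos(grid$latitude[grid$latitude <= 42] * pi / 180)) /
    sum(cos(grid$latitude * pi / 180))
  expect_equal(fr, manual, tolerance = 1e-12)
  expect_gt(fr, sum(grid$latitude <= 42) / nrow(grid))

  # monotone in threshold
  set.seed(5)
  grnd <- dplyr::mutate(grid, value = runif(dplyr::n(), 0, 100))
  fr_t <- vapply(c(5, 20, 50, 80),
                 function(t) feasible_area(grnd, threshold = t)$feasible_fraction,
                 numeric(1))
  expect_true(all(diff(fr_t) >= 0))

  # percent change arithmetic of the published statistic
  two <- dplyr::bind_rows(
    dplyr::mutate(grid, value = ifelse(dplyr::row_number() <= nrow(grid) / 2, 10, 30),
                  window = "1960-1979"),
    dplyr::mutate(grid, value = 10, window = "2000-2024")
  )
  fa <- feasible_area(two)
  base <- fa$feasible_fraction[fa$window == "1960-1979"]
  late <- fa$feasible_fraction[fa$window == "2000-2024"]
  expect_equal(fa$pct_change_vs_baseline[fa$window == "2000-2024"],
               100 * (late - base) / base, tolerance = 1e-12)
  expect_equal(feasible_area(dplyr::mutate(grid, value = 50))$pct_change_vs_baseline,
               NA_real_)
})
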