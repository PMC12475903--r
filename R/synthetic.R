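#' Configuration for the synthetic daily-weather generator
#'
#' The generator emulates a mid-latitude station record: the daily mean
#' temperature follows an annual sinusoid with its minimum at the coldest
#' day of the year (mid-January in the north, mid-July in the south), plus
#' stationary AR(1) noise; daily extremes sit half the diurnal range above
#' and below the mean; days go missing independently with a fixed
#' probability; everything is driven by one seed.
#'
#' @param station_id 11-character station identifier.
#' @param latitude,longitude Station coordinates (degrees); the latitude sign
#'   sets the phase of the annual cycle.
#' @param annual_mean Annual mean temperature, degrees C. Default 9.
#' @param annual_amplitude Half peak-to-trough seasonal swing, degrees C.
#'   Default 14 (continental mid-latitude).
#' @param diurnal_range tmax - tmin, degrees C. Default 8.
#' @param ar1 AR(1) coefficient of the day-to-day anomaly, in \[0, 1).
#'   Default 0.7.
#' @param noise_sd Stationary standard deviation of the anomaly, degrees C.
#'   Default 3.
#' @param missing_prob Independent per-day probability that both extremes are
#'   missing. Default 0.02.
#' @param years Number of calendar years to generate. Default 5.
#' @param start_year First calendar year. Default 1990.
#' @param seed Integer seed.
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(station_id = "SYN0000001X",
                               latitude = 43, longitude = -77,
                               annual_mean = 9, annual_amplitude = 14,
                               diurnal_range = 8,
                               ar1 = 0.7, noise_sd = 3,
                               missing_prob = 0.02,
                               years = 5, start_year = 1990,
                               seed = 1L) {
  stopifnot(ar1 >= 0, ar1 < 1, missing_prob >= 0, missing_prob < 1,
            is.finite(annual_mean), is.finite(annual_amplitude),
            years >= 1)
  structure(
    as.list(environment()),
    class = "weather_gen_config"
  )
}

#' Generate a synthetic station weather record
#'
#' @param config A [weather_gen_config()].
#' @return A list with `meta` (one-row station inventory tibble) and `daily`
#'   (tibble `station_id`, `date`, `tmax`, `tmin`); encode with
#'   [encode_dly()] for a GHCNd fixture file.
#' @export
sim_station_weather <- function(config = weather_gen_config()) {
  stopifnot(inherits(config, "weather_gen_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31",
                               config$start_year + config$years - 1)),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  coldest_doy <- if (config$latitude >= 0) 15L else 196L
  seasonal <- config$annual_mean -
    config$annual_amplitude * cos(2 * pi * (doy - coldest_doy) / 365)

  n <- length(dates)
  innov_sd <- config$noise_sd * sqrt(1 - config$ar1^2)
  anom <- numeric(n)
  anom[1] <- rnorm(1, 0, config$noise_sd)
  z <- rnorm(n, 0, innov_sd)
  for (t in 2:n) anom[t] <- config$ar1 * anom[t - 1] + z[t]

  daily_mean <- seasonal + anom
  tmax <- daily_mean + config$diurnal_range / 2
  tmin <- daily_mean - config$diurnal_range / 2
  gone <- runif(n) < config$missing_prob
  tmax[gone] <- NA_real_
  tmin[gone] <- NA_real_

  list(
    meta = tibble::tibble(
      station_id = config$station_id,
      latitude = config$latitude,
      longitude = config$longitude,
      elevation = NA_real_,
      name = paste("SYNTHETIC", config$station_id)
    ),
    daily = tibble::tibble(
      station_id = config$station_id,
      date = dates,
      tmax = round(tmax, 1),
      tmin = round(tmin, 1)
    )
  )
}

#' Generate a synthetic station network over a planted spatial field
#'
#' Places stations uniformly at random inside a bounding box and evaluates a
#' planted damage field at each, recording the truth so gridding can be
#' checked against it.
#'
#' @param n_stations Number of stations (>= 1).
#' @param lat_range,lon_range Length-2 bounds in degrees.
#' @param field Function of (latitude, longitude) returning the planted
#'   value. Default constant 10.
#' @param seed Integer seed.
#' @return Tibble `station_id`, `latitude`, `longitude`, `value`.
#' @export
sim_station_network <- function(n_stations, lat_range = c(35, 50),
                                lon_range = c(-100, -70),
                                field = function(lat, lon) rep(10, length(lat)),
                                seed = 1L) {
  stopifnot(n_stations >= 1,
            lat_range[1] < lat_range[2], lon_range[1] < lon_range[2])
  set.seed(seed)
  lat <- runif(n_stations, lat_range[1], lat_range[2])
  lon <- runif(n_stations, lon_range[1], lon_range[2])
  tibble::tibble(
    station_id = sprintf("SYNNET%05d", seq_len(n_stations)),
    latitude = lat,
    longitude = lon,
    value = field(lat, lon)
  )
}

#' Configuration for the synthetic LT50 ground truth
#'
#' The truth model reproduces the U-shaped dormant-season hardiness
#' trajectory as a balance of acclimation and deacclimation, expressed in
#' the package's own extracted features (so a regressor trained on those
#' features can in principle recover it): hardiness deepens from a ceiling
#' toward a floor as chill-hours accumulate toward a chill requirement, and
#' is pulled back toward the ceiling by recent heat (an EWMA of daily
#' growing degree hours above 10 C). It is a test harness, not a claim about
#' real grapevine physiology.
#'
#' @param lt50_max Ceiling (least hardy) LT50, degrees C. Default -8.
#' @param lt50_min Floor (most hardy) LT50, degrees C. Default -28.
#' @param chill_requirement Chill hours at which acclimation saturates.
#'   Default 800.
#' @param acclimation_span EWMA span (days) of the recent-heat signal.
#'   Default 7.
#' @param deacclimation_gain Degrees C of hardiness lost per smoothed daily
#'   degree-hour above 10 C. Default 0.1.
#' @param noise_sd Gaussian noise added to the observed series, degrees C.
#'   Default 1.
#' @param vinifera_offset,hybrid_offset Additive LT50 offset per species
#'   class, degrees C (*V. vinifera* buds are typically less hardy).
#'   Defaults +2 and 0.
#' @param seed Integer seed for the noise.
#' @return A list of class `lt50_gen_config`.
#' @export
lt50_gen_config <- function(lt50_max = -8, lt50_min = -28,
                            chill_requirement = 800,
                            acclimation_span = 7,
                            deacclimation_gain = 0.1,
                            noise_sd = 1,
                            vinifera_offset = 2, hybrid_offset = 0,
                            seed = 1L) {
  stopifnot(lt50_min < lt50_max, lt50_max <= 0, chill_requirement > 0)
  structure(as.list(environment()), class = "lt50_gen_config")
}

#' Synthetic LT50 ground truth from an extracted feature table
#'
#' Evaluates the truth model of [lt50_gen_config()] on feature rows:
#' `lt50_true = clamp(lt50_max + (lt50_min - lt50_max) * A + g * H + offset)`
#' with `A = min(1, chill_cu / chill_requirement)` the normalised chill-hours
#' acclimation state, `H` the EWMA-smoothed daily degree-hours above 10 C,
#' `g` the deacclimation gain, and the clamp at `[lt50_min, lt50_max]`. The
#' observed series adds seeded Gaussian noise and is clamped to the same
#' band.
#'
#' @param features Feature table from [assemble_features()] /
#'   [extract_features()] (needs `chill_cu`, `gdh_base10`, `cultivar`, and
#'   the key columns).
#' @param config An [lt50_gen_config()].
#' @param registry A [cultivar_registry()] supplying species classes for the
#'   offsets.
#' @return `features`' key columns plus `lt50_true` (noiseless) and `lt50`
#'   (noisy observation), both degrees C.
#' @export
sim_lt50_truth <- function(features, config = lt50_gen_config(),
                           registry = cultivar_registry()) {
  stopifnot(inherits(config, "lt50_gen_config"))
  need <- c("chill_cu", "gdh_base10", "cultivar", "date")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    abort(sprintf("feature table lacks required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  offsets <- setNames(
    ifelse(registry$species == "vinifera",
           config$vinifera_offset, config$hybrid_offset),
    registry$cultivar
  )
  keys <- intersect(c("station_id", "season_label", "date", "cultivar"),
                    names(features))
  grp <- intersect(c("station_id", "season_label", "cultivar"),
                   names(features))

  out <- features |>
    dplyr::select(dplyr::all_of(unique(c(keys, need)))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "date")))) |>
    dplyr::mutate(
      gdh10_daily = c(.data$gdh_base10[1],
                      diff(.data$gdh_base10)),
      heat_recent = ewma(.data$gdh10_daily, config$acclimation_span),
      acclim = pmin(1, .data$chill_cu / config$chill_requirement),
      lt50_true = pmin(config$lt50_max, pmax(
        config$lt50_min,
        config$lt50_max +
          (config$lt50_min - config$lt50_max) * .data$acclim +
          config$deacclimation_gain * .data$heat_recent +
          offsets[.data$cultivar]
      )),
      .by = dplyr::all_of(grp)
    )
  set.seed(config$seed)
  # observed series: truth plus noise, clamped only to the physiological band
  out$lt50 <- pmin(0, pmax(-40, out$lt50_true + rnorm(nrow(out), 0, config$noise_sd)))
  dplyr::select(out, dplyr::all_of(keys), "lt50_true", "lt50")
}
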