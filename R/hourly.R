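#' Solar day length from latitude and day of year
#'
#' Standard solar-declination geometry: declination
#' `-23.44 * cos(2 * pi * (doy + 10) / 365)` degrees, hour angle at
#' sunrise/sunset from `cos(H0) = -tan(lat) * tan(decl)`. Local solar time:
#' sunrise and sunset sit symmetrically around noon.
#'
#' @param doy Day of year (1-366).
#' @param latitude Degrees, `abs(latitude) < 66.6` (no polar day/night).
#' @return A list of numeric vectors `sunrise`, `sunset`, `daylength` (hours).
#' @export
solar_times <- function(doy, latitude) {
  if (abs(latitude) >= 66.6) {
    abort("latitude at or beyond 66.6 degrees: polar day/night unsupported")
  }
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  cos_h0 <- -tan(latitude * pi / 180) * tan(decl)
  cos_h0 <- pmin(1, pmax(-1, cos_h0))
  daylength <- 2 * acos(cos_h0) * 180 / pi / 15
  list(
    sunrise = 12 - daylength / 2,
    sunset = 12 + daylength / 2,
    daylength = daylength
  )
}

# Linear interpolation of short daily gaps; endpoints extended with the
# nearest observed value. Runs longer than gap_max days stay missing.
fill_daily_gaps <- function(daily, gap_max = 3L) {
  filled <- daily
  for (col in c("tmax", "tmin")) {
    x <- daily[[col]]
    if (all(is.na(x))) {
      abort(sprintf("column %s entirely missing; cannot gap-fill", col))
    }
    filled[[col]] <- zoo::na.approx(x, na.rm = FALSE, rule = 2,
                                    maxgap = gap_max)
  }
  still <- is.na(filled$tmax) | is.na(filled$tmin)
  if (any(still)) {
    abort(sprintf(
      "gap longer than %d days cannot be filled: %s to %s",
      gap_max, min(daily$date[still]), max(daily$date[still])
    ))
  }
  filled
}

#' Reconstruct hourly temperatures from daily extremes
#'
#' Builds an idealised diurnal curve for every day of a dormant-season daily
#' series: temperature rises from the day's minimum at sunrise along a sine
#' to an afternoon peak equal to the day's maximum, then declines
#' logarithmically overnight toward the next day's minimum at the next
#' sunrise. Sunrise and sunset come from [solar_times()]. Short daily gaps
#' (up to `gap_max` consecutive days) are linearly interpolated before the
#' curve is built; longer gaps are an error. The hour nearest the sine peak
#' is pinned to the day's maximum exactly, so the hourly maximum of every day
#' reproduces that day's `tmax`.
#'
#' @param daily Complete-calendar daily tibble (`station_id`, `date`, `tmax`,
#'   `tmin`) for one season.
#' @param latitude Station latitude in degrees, `abs(latitude) < 66.6`.
#' @param gap_max Longest daily gap (consecutive missing days) to
#'   interpolate. Default 3.
#' @return Tibble `station_id`, `date`, `hour` (0-23), `temp` (degrees C).
#' @export
hourly_from_daily <- function(daily, latitude, gap_max = 3L) {
  daily <- fill_daily_gaps(dplyr::arrange(daily, .data$date), gap_max)
  n <- nrow(daily)
  doy <- as.integer(format(daily$date, "%j"))
  sol <- solar_times(doy, latitude)
  sunrise <- sol$sunrise
  sunset <- sol$sunset
  dl <- sol$daylength

  tmax <- daily$tmax
  tmin <- daily$tmin
  tmin_next <- c(tmin[-1], tmin[n])
  # temperature when the sun sets, from the daytime sine
  t_sunset <- tmin + (tmax - tmin) * sin(pi * dl / (dl + 4))

  temp <- matrix(NA_real_, nrow = n, ncol = 24)
  hours <- 0:23
  for (d in seq_len(n)) {
    day_part <- hours >= sunrise[d] & hours <= sunset[d]
    temp[d, day_part] <- tmin[d] +
      (tmax[d] - tmin[d]) * sin(pi * (hours[day_part] - sunrise[d]) / (dl[d] + 4))

    # evening: decline from this day's sunset toward the next day's sunrise min
    night_len <- 24 - sunset[d] + (if (d < n) sunrise[d + 1] else sunrise[d])
    eve <- hours > sunset[d]
    temp[d, eve] <- t_sunset[d] -
      (t_sunset[d] - tmin_next[d]) *
        log1p(hours[eve] - sunset[d]) / log1p(night_len)

    # pre-dawn: tail of the previous day's night curve
    pre <- hours < sunrise[d]
    if (d > 1) {
      night_len_prev <- 24 - sunset[d - 1] + sunrise[d]
      temp[d, pre] <- t_sunset[d - 1] -
        (t_sunset[d - 1] - tmin[d]) *
          log1p(hours[pre] + 24 - sunset[d - 1]) / log1p(night_len_prev)
    } else {
      temp[d, pre] <- tmin[d]
    }

    # the day's extremes bound its hours: a warm front (next-day minimum above
    # today's maximum) must not push night hours past today's tmax
    temp[d, ] <- pmin(temp[d, ], tmax[d])
    # pin the hour nearest the sine peak to tmax so the daily max is exact
    peak <- sunrise[d] + (dl[d] + 4) / 2
    peak_hour <- which.min(abs(hours - min(peak, sunset[d])))
    temp[d, peak_hour] <- tmax[d]
  }

  tibble::tibble(
    station_id = daily$station_id[1L],
    date = rep(daily$date, each = 24L),
    hour = rep(hours, times = n),
    temp = as.vector(t(temp))
  )
}
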