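#' Curation settings for a station network
#'
#' Bundles the thresholds of the four-step station filter: record-type
#' (stations need both daily extremes and at least `min_station_years` of
#' record), geographic (absolute latitude inside `latitude_band`, applied
#' symmetrically to both hemispheres), temporal (data before `temporal_cutoff`
#' discarded), and data quality (dormant seasons with fewer than
#' `min_season_days` days carrying both extremes discarded).
#'
#' @param latitude_band Length-2 numeric, inclusive absolute-latitude band in
#'   degrees. Default `c(30, 55)`, the viticultural zone of both hemispheres.
#' @param min_station_years Minimum record span in years between the first and
#'   last day with both extremes. Default 2.
#' @param temporal_cutoff Date before which records are dropped. Default
#'   1960-01-01.
#' @param min_season_days Minimum days with both extremes for a dormant season
#'   to be kept. Default 220.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(latitude_band = c(30, 55),
                            min_station_years = 2,
                            temporal_cutoff = as.Date("1960-01-01"),
                            min_season_days = 220L) {
  stopifnot(
    length(latitude_band) == 2L,
    latitude_band[1] > 0, latitude_band[1] < latitude_band[2],
    latitude_band[2] <= 90,
    min_station_years > 0,
    min_season_days <= 243L
  )
  structure(
    list(
      latitude_band = as.numeric(latitude_band),
      min_station_years = min_station_years,
      temporal_cutoff = as.Date(temporal_cutoff),
      min_season_days = as.integer(min_season_days)
    ),
    class = "curation_config"
  )
}

#' Record-type filter: does a station have a usable dual-element record?
#'
#' A station is kept only if it has days with both `tmax` and `tmin` present
#' and the calendar span between the first and last such day is at least
#' `min_station_years` (years counted as 365.25 days).
#'
#' @param daily Daily series tibble (`station_id`, `date`, `tmax`, `tmin`).
#' @param min_station_years Minimum span in years.
#' @return A list with `keep` (logical) and `reason` (`NA` if kept).
#' @export
filter_record_type <- function(daily, min_station_years = 2) {
  dual <- !is.na(daily$tmax) & !is.na(daily$tmin)
  if (nrow(daily) == 0L || !any(dual)) {
    return(list(keep = FALSE, reason = "no records"))
  }
  span_days <- as.numeric(max(daily$date[dual]) - min(daily$date[dual]))
  if (span_days < min_station_years * 365.25) {
    return(list(keep = FALSE,
                reason = sprintf("record span %.1f years < %s years",
                                 span_days / 365.25, min_station_years)))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Geographic filter: inclusive absolute-latitude band
#'
#' @param latitude Station latitude in decimal degrees.
#' @param band Length-2 band in degrees, applied to `abs(latitude)`.
#' @return A list with `keep` and `reason`.
#' @export
filter_geographic <- function(latitude, band = c(30, 55)) {
  keep <- abs(latitude) >= band[1] & abs(latitude) <= band[2]
  list(
    keep = keep,
    reason = if (keep) NA_character_ else
      sprintf("latitude %.2f outside %.0f-%.0f degree band",
              latitude, band[1], band[2])
  )
}

#' Temporal filter: drop records before a cutoff date
#'
#' @param daily Daily series tibble.
#' @param cutoff Date; rows strictly before it are removed.
#' @return The truncated tibble (possibly zero rows).
#' @export
filter_temporal <- function(daily, cutoff = as.Date("1960-01-01")) {
  dplyr::filter(daily, .data$date >= as.Date(cutoff))
}

#' Segment a daily series into hemisphere-aware dormant seasons
#'
#' Northern-hemisphere seasons run 1 September to 1 May (exclusive end);
#' southern seasons run 1 March to 1 November (exclusive end). The season
#' label is the calendar year of the season's start date. `days_recorded`
#' counts days carrying both extremes; leap days count.
#'
#' @param daily Daily series tibble for one station.
#' @param latitude Station latitude (sign determines hemisphere).
#' @return A nested tibble: one row per season with `station_id`,
#'   `hemisphere`, `season_label`, `start_date`, `end_date` (exclusive),
#'   `days_recorded`, and `daily` (list column of the in-window slice,
#'   completed to the full season calendar).
#' @export
segment_seasons <- function(daily, latitude) {
  if (latitude == 0) {
    abort("hemisphere undefined at latitude 0")
  }
  north <- latitude > 0
  hemisphere <- if (north) "N" else "S"
  if (nrow(daily) == 0L) {
    return(empty_seasons())
  }
  years <- sort(unique(as.integer(format(daily$date, "%Y"))))
  # a season starting in year y can contain records from y (and y+1 in the N)
  labels <- sort(unique(c(years, years - 1L)))
  out <- purrr::map(labels, function(y) {
    start <- as.Date(sprintf("%d-%s", y, if (north) "09-01" else "03-01"))
    end <- if (north) as.Date(sprintf("%d-05-01", y + 1L)) else
      as.Date(sprintf("%d-11-01", y))
    slice <- dplyr::filter(daily, .data$date >= start, .data$date < end)
    if (nrow(slice) == 0L) return(NULL)
    grid <- tibble::tibble(date = seq(start, end - 1, by = "day"))
    slice <- dplyr::left_join(grid, slice, by = "date") |>
      dplyr::mutate(station_id = daily$station_id[1L]) |>
      dplyr::relocate("station_id")
    tibble::tibble(
      station_id = daily$station_id[1L],
      hemisphere = hemisphere,
      season_label = y,
      start_date = start,
      end_date = end,
      days_recorded = sum(!is.na(slice$tmax) & !is.na(slice$tmin)),
      daily = list(slice)
    )
  })
  res <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(res) == 0L) empty_seasons() else res
}

empty_seasons <- function() {
  tibble::tibble(
    station_id = character(), hemisphere = character(),
    season_label = integer(), start_date = as.Date(character()),
    end_date = as.Date(character()), days_recorded = integer(),
    daily = list()
  )
}

#' Data-quality filter: minimum days of dual-element record per season
#'
#' @param seasons Season tibble from [segment_seasons()].
#' @param min_season_days Keep seasons with `days_recorded >=` this count.
#' @return The kept rows.
#' @export
filter_quality <- function(seasons, min_season_days = 220L) {
  dplyr::filter(seasons, .data$days_recorded >= min_season_days)
}

#' Curate a station network into dormant seasons
#'
#' Applies the four filters in order — record type, geographic, temporal,
#' data quality — and segments the survivors into dormant seasons. A station
#' that fails an early filter is never passed to later ones, so the report
#' records only its first failure.
#'
#' @param stations Station inventory tibble
#'   (`station_id`, `latitude`, `longitude`, ...).
#' @param daily Daily series tibble for all stations (long format).
#' @param config A [curation_config()].
#' @return A list of class `hardivine_curation` with:
#'   * `seasons`: nested season tibble (kept seasons only);
#'   * `report`: one row per station with `station_id`, `kept`,
#'     `filter_failed` (`NA` if kept), `seasons_kept`, `record_years`,
#'     `missing_seasons` (in-era seasons dropped by the quality filter).
#' @export
curate <- function(stations, daily, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  if (anyDuplicated(stations$station_id)) {
    abort("duplicate station ids in inventory")
  }
  by_station <- split(daily, daily$station_id)

  rows <- purrr::map(seq_len(nrow(stations)), function(i) {
    st <- stations[i, ]
    d <- by_station[[st$station_id]] %||%
      tibble::tibble(station_id = character(), date = as.Date(character()),
                     tmax = numeric(), tmin = numeric())
    report <- tibble::tibble(
      station_id = st$station_id, kept = FALSE,
      filter_failed = NA_character_, seasons_kept = 0L,
      record_years = NA_real_, missing_seasons = NA_integer_
    )

    rt <- filter_record_type(d, config$min_station_years)
    if (!rt$keep) {
      report$filter_failed <- paste0("record_type: ", rt$reason)
      return(list(seasons = empty_seasons(), report = report))
    }
    geo <- filter_geographic(st$latitude, config$latitude_band)
    if (!geo$keep) {
      report$filter_failed <- paste0("geographic: ", geo$reason)
      return(list(seasons = empty_seasons(), report = report))
    }
    d <- filter_temporal(d, config$temporal_cutoff)
    dual <- !is.na(d$tmax) & !is.na(d$tmin)
    if (!any(dual)) {
      report$filter_failed <- "temporal: no records on or after cutoff"
      return(list(seasons = empty_seasons(), report = report))
    }
    seasons <- segment_seasons(d, st$latitude)
    kept <- filter_quality(seasons, config$min_season_days)
    report$kept <- nrow(kept) > 0L
    report$filter_failed <- if (report$kept) NA_character_ else
      "quality: no season with enough recorded days"
    report$seasons_kept <- nrow(kept)
    report$record_years <-
      round(as.numeric(max(d$date[dual]) - min(d$date[dual])) / 365.25, 2)
    report$missing_seasons <- nrow(seasons) - nrow(kept)
    list(seasons = kept, report = report)
  })

  structure(
    list(
      seasons = dplyr::bind_rows(purrr::map(rows, "seasons")),
      report = dplyr::bind_rows(purrr::map(rows, "report")),
      config = config
    ),
    class = "hardivine_curation"
  )
}

#' @export
print.hardivine_curation <- function(x, ...) {
  cat(sprintf(
    "<hardivine_curation> %d/%d stations kept, %d dormant seasons\n",
    sum(x$report$kept), nrow(x$report), nrow(x$seasons)
  ))
  invisible(x)
}
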