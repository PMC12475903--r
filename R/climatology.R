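#' Per-season hardiness and damage summary
#'
#' For one station-season-cultivar: the seasonal minimum temperature, the
#' maximum cold hardiness (read as deepest hardiness, i.e. the most negative
#' LT50 of the season), and the maximum daily cold-damage potential, where
#' each day's damage compares that day's minimum temperature with the same
#' day's LT50 via [damage_potential()].
#'
#' @param lt50 Tibble `date`, `lt50` (plus optional keys `station_id`,
#'   `cultivar`) of per-day LT50 for the season.
#' @param season_daily Daily tibble `date`, `tmin` (gap-filled or raw) for
#'   the same season.
#' @return One-row tibble: keys (if present), `min_temperature`,
#'   `max_hardiness`, `max_damage`.
#' @export
season_summary <- function(lt50, season_daily) {
  joined <- dplyr::inner_join(
    dplyr::select(lt50, dplyr::any_of(c("station_id", "cultivar")),
                  "date", "lt50"),
    dplyr::select(season_daily, "date", "tmin"),
    by = "date"
  ) |>
    dplyr::filter(!is.na(.data$tmin), !is.na(.data$lt50))
  if (nrow(joined) == 0L) abort("no overlapping dates between lt50 and daily")
  keys <- intersect(c("station_id", "cultivar"), names(joined))
  joined |>
    dplyr::summarise(
      min_temperature = min(.data$tmin),
      max_hardiness = min(.data$lt50),
      max_damage = max(damage_potential(.data$tmin, .data$lt50)),
      .by = dplyr::all_of(keys)
    )
}

#' Average season summaries over multi-decade windows
#'
#' Maps each season (by its starting-year label) into one of the configured
#' year windows and averages every summary column per station (and cultivar,
#' if present) per window. Stations with no season in a window are absent
#' from that window. Windows must not overlap.
#'
#' @param summaries Tibble of per-season summaries carrying `season_label`
#'   plus the columns to average (`min_temperature`, `max_hardiness`,
#'   `max_damage`) and keys (`station_id`, optionally `cultivar`).
#' @param windows Named list of length-2 integer year ranges (inclusive).
#'   Default the three case-study windows `1960-1979`, `1980-1999`,
#'   `2000-2024`.
#' @return Tibble keyed by station (and cultivar), `window`, `n_seasons`,
#'   and the window means of each summary column.
#' @export
window_average <- function(summaries,
                           windows = list(
                             "1960-1979" = c(1960, 1979),
                             "1980-1999" = c(1980, 1999),
                             "2000-2024" = c(2000, 2024)
                           )) {
  rng <- do.call(rbind, windows)
  ord <- order(rng[, 1])
  if (any(rng[ord, 1][-1] <= rng[ord, 2][-length(windows)])) {
    abort("windows overlap")
  }
  lab <- rep(NA_character_, nrow(summaries))
  for (w in names(windows)) {
    inw <- summaries$season_label >= windows[[w]][1] &
      summaries$season_label <= windows[[w]][2]
    lab[inw] <- w
  }
  keys <- intersect(c("station_id", "cultivar"), names(summaries))
  summaries |>
    dplyr::mutate(window = lab) |>
    dplyr::filter(!is.na(.data$window)) |>
    dplyr::summarise(
      n_seasons = dplyr::n(),
      dplyr::across(
        dplyr::any_of(c("min_temperature", "max_hardiness", "max_damage")),
        mean
      ),
      .by = dplyr::all_of(c(keys, "window"))
    )
}

# great-circle distance in km between (lat1, lon1) and vectors (lat2, lon2)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Grid station values by k-nearest neighbours
#'
#' Estimates a regular latitude/longitude grid from scattered station values:
#' each cell takes the unweighted mean of the `k` nearest stations under
#' great-circle (haversine) distance, ties broken by station id order. Cell
#' values are therefore convex combinations of station values. Grouping
#' columns (e.g. `window`) in `stations` produce one layer per group.
#'
#' @param stations Tibble `station_id`, `latitude`, `longitude`, `value`,
#'   plus optional grouping columns named in `layers`.
#' @param grid Either a tibble of cells (`latitude`, `longitude`) or a list
#'   with `lat_range`, `lon_range`, `resolution` (degrees, default 0.5) from
#'   which a regular grid is built.
#' @param k Number of neighbours. Default 5.
#' @param layers Optional character vector of grouping columns; the grid is
#'   estimated once per group.
#' @return Tibble `latitude`, `longitude`, layer columns, `value`.
#' @export
knn_grid <- function(stations, grid, k = 5L, layers = NULL) {
  if (is.list(grid) && !is.data.frame(grid)) {
    res <- grid$resolution %||% 0.5
    grid <- tidyr::expand_grid(
      latitude = seq(grid$lat_range[1], grid$lat_range[2], by = res),
      longitude = seq(grid$lon_range[1], grid$lon_range[2], by = res)
    )
  }
  one_layer <- function(st) {
    if (k > nrow(st)) {
      abort(sprintf("k = %d exceeds station count %d", k, nrow(st)))
    }
    st <- dplyr::arrange(st, .data$station_id)
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      d <- haversine_km(grid$latitude[i], grid$longitude[i],
                        st$latitude, st$longitude)
      mean(st$value[order(d)[seq_len(k)]])
    }, numeric(1))
    dplyr::mutate(grid, value = vals)
  }
  if (is.null(layers)) {
    one_layer(stations)
  } else {
    stations |>
      dplyr::group_by(dplyr::across(dplyr::all_of(layers))) |>
      dplyr::group_modify(~ one_layer(.x)) |>
      dplyr::ungroup()
  }
}

#' Feasible-area fraction and change against a baseline window
#'
#' The feasible fraction of a gridded damage layer is the area-weighted share
#' of cells whose damage potential falls below `threshold`, cells weighted by
#' the cosine of their latitude (a 0.5-degree cell near the pole covers less
#' land than one at the equator). With several layers, the change of each
#' window against the baseline is `100 * (F_w - F_base) / F_base` percent;
#' if the baseline fraction is zero the change is undefined (`NA`).
#'
#' @param grid Tibble `latitude`, `longitude`, `value`, optionally a
#'   `window` column separating layers.
#' @param threshold Damage threshold in percent. Default 20 (regions with
#'   less than 20% seasonal damage counted as suitable for cultivation).
#' @param baseline Window label of the baseline layer (default the first in
#'   sort order).
#' @return Tibble `window`, `feasible_fraction`, `pct_change_vs_baseline`.
#' @export
feasible_area <- function(grid, threshold = 20, baseline = NULL) {
  if (!"window" %in% names(grid)) grid$window <- "all"
  frac <- grid |>
    dplyr::summarise(
      feasible_fraction =
        sum(cos(.data$latitude * pi / 180) * (.data$value < threshold)) /
          sum(cos(.data$latitude * pi / 180)),
      .by = "window"
    ) |>
    dplyr::arrange(.data$window)
  baseline <- baseline %||% frac$window[1]
  if (!baseline %in% frac$window) {
    abort(sprintf("baseline window %s not present", baseline))
  }
  f0 <- frac$feasible_fraction[frac$window == baseline]
  frac$pct_change_vs_baseline <- if (f0 == 0) NA_real_ else
    100 * (frac$feasible_fraction - f0) / f0
  frac
}
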