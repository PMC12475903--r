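#' Feature-extraction settings
#'
#' Controls the predictor scheme: the EWMA spans (30 of them), the growing
#' degree hour base temperatures, the daily-gap interpolation limit, and
#' optional replacement weight tables for the chilling models.
#'
#' @param spans Integer vector of 30 EWMA spans in days. Default 1:30.
#' @param gdh_bases Base temperatures (degrees C) for growing degree hours.
#'   Default `c(0, 4, 7, 10)`.
#' @param gap_max Longest daily gap interpolated before hourly
#'   reconstruction. Default 3.
#' @param utah_table,nc_table Optional replacement weight tables
#'   (data frames with `lower`, `upper`, `weight`; intervals `(lower, upper]`).
#' @param cu_range Temperature interval `(lower, upper]` counted as one chill
#'   hour by the chill-hours model. Default `c(0, 7.2)`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(spans = 1:30,
                           gdh_bases = c(0, 4, 7, 10),
                           gap_max = 3L,
                           utah_table = NULL,
                           nc_table = NULL,
                           cu_range = c(0, 7.2)) {
  stopifnot(length(spans) == 30L, all(spans >= 1))
  structure(
    list(
      spans = as.integer(spans),
      gdh_bases = gdh_bases,
      gap_max = as.integer(gap_max),
      utah_table = utah_table %||% utah_weight_table(),
      nc_table = nc_table %||% nc_weight_table(),
      cu_range = cu_range
    ),
    class = "feature_config"
  )
}

# Utah model hourly chill weights (Richardson); intervals are (lower, upper]
utah_weight_table <- function() {
  data.frame(
    lower = c(-Inf, 1.4, 2.4, 9.1, 12.4, 15.9, 18),
    upper = c(1.4, 2.4, 9.1, 12.4, 15.9, 18, Inf),
    weight = c(0, 0.5, 1, 0.5, 0, -0.5, -1)
  )
}

# North Carolina model hourly chill weights (Shaltout & Unrath);
# optimum 1.0 near 7.2 C, weights turn negative at warm temperatures
nc_weight_table <- function() {
  data.frame(
    lower = c(-Inf, -1.1, 1.6, 7.2, 13, 16.5, 19, 20.7, 22.1),
    upper = c(-1.1, 1.6, 7.2, 13, 16.5, 19, 20.7, 22.1, Inf),
    weight = c(0, 0.5, 1, 0.5, 0, -0.5, -1, -1.5, -2)
  )
}

step_weight <- function(temp, table) {
  w <- numeric(length(temp))
  for (i in seq_len(nrow(table))) {
    w[temp > table$lower[i] & temp <= table$upper[i]] <- table$weight[i]
  }
  w
}

# sum an hourly weight over each day, then accumulate from season start
hourly_accumulate <- function(hourly, weight) {
  tibble::tibble(date = hourly$date, w = weight) |>
    dplyr::summarise(w = sum(.data$w), .by = "date") |>
    dplyr::arrange(.data$date) |>
    dplyr::mutate(units = cumsum(.data$w)) |>
    dplyr::select("date", "units")
}

#' Chilling and heat accumulation from an hourly series
#'
#' All four accumulators return season-to-date totals evaluated at the end of
#' each day. `utah_chill()` and `nc_chill()` apply stepwise hourly weight
#' tables (the Utah weights are negative above 18 C, the North Carolina
#' weights above 16.5 C, so both can decrease); `cu_chill()` counts chill
#' hours with temperature in `(0, 7.2]` C; `gdh()` accumulates
#' `max(0, temp - base)` degree-hours.
#'
#' @param hourly Hourly tibble from [hourly_from_daily()].
#' @param table Optional replacement weight table (see [feature_config()]).
#' @param range Chill-hours interval `(lower, upper]` for `cu_chill()`.
#' @param base Base temperature for `gdh()`, one of the configured bases
#'   unless `allow_any_base = TRUE`.
#' @param config A [feature_config()].
#' @param allow_any_base Permit a base outside `config$gdh_bases`.
#' @return Tibble with `date` and cumulative `units` (or `degree_hours`).
#' @export
utah_chill <- function(hourly, table = utah_weight_table()) {
  hourly_accumulate(hourly, step_weight(hourly$temp, table))
}

#' @rdname utah_chill
#' @export
nc_chill <- function(hourly, table = nc_weight_table()) {
  hourly_accumulate(hourly, step_weight(hourly$temp, table))
}

#' @rdname utah_chill
#' @export
cu_chill <- function(hourly, range = c(0, 7.2)) {
  hourly_accumulate(
    hourly, as.numeric(hourly$temp > range[1] & hourly$temp <= range[2])
  )
}

#' @rdname utah_chill
#' @export
gdh <- function(hourly, base, config = feature_config(),
                allow_any_base = FALSE) {
  if (!allow_any_base && !base %in% config$gdh_bases) {
    abort(sprintf("base %s not in configured set {%s}; set allow_any_base",
                  base, paste(config$gdh_bases, collapse = ", ")))
  }
  out <- hourly_accumulate(hourly, pmax(0, hourly$temp - base))
  dplyr::rename(out, degree_hours = "units")
}

#' Forward and reverse exponentially weighted moving averages
#'
#' `ewma()` is the standard recursive EWMA with smoothing
#' `alpha = 2 / (span + 1)`, initialised at the first value:
#' `e_t = alpha * x_t + (1 - alpha) * e_{t-1}`. `reverse_ewma()` applies the
#' same recursion to the season-to-date sequence traversed from the current
#' day back to the season start, so the earliest days carry the greatest
#' weight; at day `t` it equals
#' `alpha * sum_{i<t} (1-alpha)^(i-1) * x_i + (1-alpha)^(t-1) * x_t`.
#'
#' @param x Numeric series (daily mean temperatures).
#' @param span Span in days, >= 1. `span = 1` (`alpha = 1`) returns the
#'   current value (forward) or the season-start value (reverse).
#' @return Numeric vector, same length as `x`: the (reverse) EWMA evaluated
#'   at every day.
#' @export
ewma <- function(x, span) {
  if (span < 1) abort("span must be >= 1")
  alpha <- 2 / (span + 1)
  n <- length(x)
  out <- numeric(n)
  out[1] <- x[1]
  if (n > 1) {
    for (t in 2:n) out[t] <- alpha * x[t] + (1 - alpha) * out[t - 1]
  }
  out
}

#' @rdname ewma
#' @export
reverse_ewma <- function(x, span) {
  if (span < 1) abort("span must be >= 1")
  alpha <- 2 / (span + 1)
  n <- length(x)
  if (n == 0) return(numeric(0))
  decay <- (1 - alpha)^(seq_len(n) - 1)
  s <- cumsum(decay * x)
  out <- numeric(n)
  out[1] <- x[1]
  if (n > 1) {
    t <- 2:n
    out[t] <- alpha * s[t - 1] + decay[t] * x[t]
  }
  out
}

#' Default cultivar registry (54 cultivars)
#'
#' Loads the registry of 54 grapevine cultivars — 21 *Vitis vinifera* and 33
#' *V. hybrid* — used for the one-hot cultivar indicators. The bundled
#' default (`cultivars_synthetic.csv`) is a synthetic stand-in: real cultivar
#' names with plausible species classes, assembled for this package rather
#' than reproduced from any measured cold-hardiness panel.
#'
#' @param file Optional path to a replacement registry CSV with columns
#'   `cultivar` and `species` (values `vinifera` or `hybrid`).
#' @return Tibble `cultivar`, `species`, `indicator` (the one-hot feature
#'   name for the cultivar).
#' @export
cultivar_registry <- function(file = NULL) {
  file <- file %||%
    system.file("extdata", "cultivars_synthetic.csv", package = "hardivine")
  reg <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("cultivar", "species") %in% names(reg)))
  if (anyDuplicated(reg$cultivar)) abort("duplicate cultivar names in registry")
  reg$indicator <- paste0(
    "cv_", tolower(gsub("[^A-Za-z0-9]+", "_", reg$cultivar))
  )
  tibble::as_tibble(reg)
}

#' Names of the full feature vector, in emission order
#'
#' @param registry A [cultivar_registry()].
#' @param config A [feature_config()].
#' @return Character vector of 126 feature names: 4 daily descriptors, 7
#'   cumulative descriptors, 30 EWMA, 30 reverse EWMA, 54 cultivar
#'   indicators, and `days_in_season`.
#' @export
feature_names <- function(registry = cultivar_registry(),
                          config = feature_config()) {
  c(
    "t_max", "t_min", "t_mean", "t_range",
    "chill_utah", "chill_nc", "chill_cu",
    paste0("gdh_base", config$gdh_bases),
    sprintf("ewma_%02d", config$spans),
    sprintf("rewma_%02d", config$spans),
    registry$indicator,
    "days_in_season"
  )
}

#' Assemble the 126-feature predictor table for one dormant season
#'
#' Emits one row per day and cultivar: four daily descriptors (tmax, tmin,
#' daily mean `(tmax + tmin)/2`, diurnal range), seven season-to-date
#' cumulative descriptors (Utah, North Carolina and chill-hours chilling,
#' growing degree hours at bases 0/4/7/10 C), 30 forward and 30 reverse EWMA
#' temperatures of the daily mean, 54 one-hot cultivar indicators, and
#' `days_in_season` (days elapsed since the season start date; the start day
#' is 0). Exactly 126 feature columns, preceded by the keys `station_id`,
#' `date`, `cultivar`.
#'
#' @param season_daily Complete-calendar daily tibble for one dormant season.
#' @param latitude Station latitude in degrees.
#' @param cultivars Character vector of cultivars to emit rows for; each must
#'   be in the registry.
#' @param registry A [cultivar_registry()].
#' @param config A [feature_config()].
#' @return Tibble with 3 key columns + 126 feature columns.
#' @export
assemble_features <- function(season_daily, latitude, cultivars,
                              registry = cultivar_registry(),
                              config = feature_config()) {
  unknown <- setdiff(cultivars, registry$cultivar)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown cultivar(s) %s; registry has: %s",
      paste(unknown, collapse = ", "),
      paste(registry$cultivar, collapse = ", ")
    ))
  }
  daily <- fill_daily_gaps(dplyr::arrange(season_daily, .data$date),
                           config$gap_max)
  hourly <- hourly_from_daily(daily, latitude, gap_max = config$gap_max)

  cum <- utah_chill(hourly, config$utah_table) |>
    dplyr::rename(chill_utah = "units") |>
    dplyr::mutate(chill_nc = nc_chill(hourly, config$nc_table)$units,
                  chill_cu = cu_chill(hourly, config$cu_range)$units)
  for (b in config$gdh_bases) {
    cum[[paste0("gdh_base", b)]] <- gdh(hourly, b, config)$degree_hours
  }

  tmean <- (daily$tmax + daily$tmin) / 2
  base <- tibble::tibble(
    station_id = daily$station_id[1L],
    date = daily$date,
    t_max = daily$tmax,
    t_min = daily$tmin,
    t_mean = tmean,
    t_range = daily$tmax - daily$tmin
  )
  for (i in seq_along(config$spans)) {
    base[[sprintf("ewma_%02d", config$spans[i])]] <- ewma(tmean, config$spans[i])
    base[[sprintf("rewma_%02d", config$spans[i])]] <-
      reverse_ewma(tmean, config$spans[i])
  }
  base <- dplyr::left_join(base, cum, by = "date")
  base$days_in_season <- as.numeric(base$date - min(base$date))

  out <- purrr::map(cultivars, function(cv) {
    rows <- base
    rows$cultivar <- cv
    for (ind in registry$indicator) rows[[ind]] <- 0
    rows[[registry$indicator[registry$cultivar == cv]]] <- 1
    rows
  }) |>
    dplyr::bind_rows()

  nm <- feature_names(registry, config)
  stopifnot(length(nm) == 126L, all(nm %in% names(out)))
  dplyr::select(out, "station_id", "date", "cultivar", dplyr::all_of(nm))
}

#' Extract features for every curated season of a station network
#'
#' Maps [assemble_features()] over the kept seasons of a
#' [curate()] result, pulling each station's latitude from the inventory.
#' Seasons whose gaps exceed the interpolation limit are skipped with a
#' warning naming the station and season.
#'
#' @param curation A `hardivine_curation` from [curate()].
#' @param stations Station inventory tibble (for latitudes).
#' @param cultivars Cultivars to emit (default: all in the registry).
#' @param registry A [cultivar_registry()].
#' @param config A [feature_config()].
#' @return One tibble of feature rows across all seasons, with a
#'   `season_label` key column.
#' @export
extract_features <- function(curation, stations,
                             cultivars = NULL,
                             registry = cultivar_registry(),
                             config = feature_config()) {
  stopifnot(inherits(curation, "hardivine_curation"))
  cultivars <- cultivars %||% registry$cultivar
  lat <- setNames(stations$latitude, stations$station_id)
  seasons <- curation$seasons
  out <- purrr::map(seq_len(nrow(seasons)), function(i) {
    row <- seasons[i, ]
    feats <- tryCatch(
      assemble_features(row$daily[[1]], lat[[row$station_id]],
                        cultivars, registry, config),
      error = function(e) {
        warn(sprintf("season %d at %s skipped: %s",
                     row$season_label, row$station_id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(feats)) return(NULL)
    feats$season_label <- row$season_label
    feats
  })
  dplyr::bind_rows(purrr::compact(out)) |>
    dplyr::relocate("station_id", "season_label", "date", "cultivar")
}
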