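#' Read a GHCNd daily element (.dly) file into a daily temperature series
#'
#' Parses the fixed-width GHCNd daily dialect: each line carries one
#' station-month-element, 269 characters wide — station id (columns 1-11),
#' year (12-15), month (16-17), element code (18-21), then 31 groups of
#' value (5 chars, tenths of degree C), MFLAG, QFLAG and SFLAG. Only TMAX and
#' TMIN lines contribute; all other elements are ignored. The sentinel -9999
#' and any value carrying a non-blank quality flag decode to missing, as does
#' any value outside the physical plausibility band of -90 to 70 degrees C.
#' Days on which the decoded maximum falls below the decoded minimum are
#' physically inconsistent: both values are set missing and a warning counts
#' the affected days.
#'
#' @param file Path to a `.dly` file, or a character vector of raw lines.
#' @return A tibble with columns `station_id`, `date`, `tmax`, `tmin`
#'   (degrees C, `NA` where missing), one row per calendar day from the first
#'   to the last day covered by any temperature record, dates strictly
#'   increasing.
#' @examples
#' lines <- encode_dly(tibble::tibble(
#'   station_id = "TEST0000001",
#'   date = as.Date("1960-01-01") + 0:9,
#'   tmax = 5 + 0:9, tmin = -2 + 0:9
#' ))
#' read_dly(lines)
#' @export
read_dly <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("empty .dly input: no lines to parse")
  }
  bad_len <- which(nchar(lines) != 269L)
  if (length(bad_len) > 0L) {
    abort(sprintf(
      "malformed .dly line(s) %s: expected 269 characters, got %s",
      paste(head(bad_len, 5L), collapse = ", "),
      paste(nchar(lines)[head(bad_len, 5L)], collapse = ", ")
    ))
  }

  station <- substr(lines, 1L, 11L)
  if (length(unique(station)) > 1L) {
    abort(sprintf(
      "mixed station ids in one .dly stream: %s",
      paste(unique(station), collapse = ", ")
    ))
  }
  element <- substr(lines, 18L, 21L)
  keep <- element %in% c("TMAX", "TMIN")
  if (!any(keep)) {
    abort("no TMAX or TMIN lines found in .dly input")
  }
  lines_t <- lines[keep]
  year <- suppressWarnings(as.integer(substr(lines_t, 12L, 15L)))
  month <- suppressWarnings(as.integer(substr(lines_t, 16L, 17L)))
  if (anyNA(year) || anyNA(month)) {
    abort(sprintf("non-numeric year/month field at line %d",
                  which(keep)[which(is.na(year) | is.na(month))[1L]]))
  }

  # decode the 31 day-groups of every temperature line at once
  day <- rep(1:31, each = length(lines_t))
  start <- 22L + 8L * (day - 1L)
  line_rep <- rep(lines_t, times = 31L)
  val_str <- substr(line_rep, start, start + 4L)
  qflag <- substr(line_rep, start + 6L, start + 6L)
  val <- suppressWarnings(as.integer(val_str))
  bad_val <- is.na(val) & trimws(val_str) != ""
  if (any(bad_val)) {
    bad_line <- which(keep)[((which(bad_val)[1L] - 1L) %% length(lines_t)) + 1L]
    abort(sprintf("non-numeric value field %s at line %d",
                  dQuote(val_str[which(bad_val)[1L]]), bad_line))
  }
  temp <- val * 0.1
  temp[is.na(val) | val == -9999L | qflag != " "] <- NA_real_
  n_implausible <- sum(!is.na(temp) & (temp < -90 | temp > 70))
  if (n_implausible > 0L) {
    warn(sprintf("%d value(s) outside [-90, 70] degrees C set to missing",
                 n_implausible))
    temp[!is.na(temp) & (temp < -90 | temp > 70)] <- NA_real_
  }

  rec <- tibble::tibble(
    element = rep(element[keep], times = 31L),
    year = rep(year, times = 31L),
    month = rep(month, times = 31L),
    day = day,
    temp = temp
  )
  # drop days beyond the month's length (29-31 depending on month/year)
  dim_month <- function(y, m) {
    as.integer(format(
      as.Date(sprintf("%d-%02d-01", y + (m == 12L), (m %% 12L) + 1L)) - 1,
      "%d"
    ))
  }
  rec <- dplyr::filter(rec, .data$day <= dim_month(.data$year, .data$month))
  rec$date <- as.Date(sprintf("%d-%02d-%02d", rec$year, rec$month, rec$day))

  wide <- rec |>
    dplyr::select("element", "date", "temp") |>
    tidyr::pivot_wider(names_from = "element", values_from = "temp") |>
    dplyr::arrange(.data$date)
  if (!"TMAX" %in% names(wide)) wide$TMAX <- NA_real_
  if (!"TMIN" %in% names(wide)) wide$TMIN <- NA_real_

  # trim to the observed extent, then complete the calendar so gaps are explicit
  has_any <- !is.na(wide$TMAX) | !is.na(wide$TMIN)
  if (!any(has_any)) {
    abort("no non-missing TMAX/TMIN values decoded")
  }
  wide <- wide[seq(which(has_any)[1L], max(which(has_any))), ]
  full <- tibble::tibble(date = seq(min(wide$date), max(wide$date), by = "day"))
  out <- dplyr::left_join(full, wide, by = "date") |>
    dplyr::transmute(
      station_id = station[1L],
      date = .data$date,
      tmax = .data$TMAX,
      tmin = .data$TMIN
    )

  inconsistent <- !is.na(out$tmax) & !is.na(out$tmin) & out$tmax < out$tmin
  if (any(inconsistent)) {
    warn(sprintf(
      "%d day(s) with tmax < tmin set to missing (physically inconsistent)",
      sum(inconsistent)
    ))
    out$tmax[inconsistent] <- NA_real_
    out$tmin[inconsistent] <- NA_real_
  }
  out
}

#' Encode a daily temperature series as GHCNd .dly lines
#'
#' Inverse of [read_dly()]: emits one 269-character line per station-month per
#' element, temperatures rounded to tenths of a degree C, missing days as
#' -9999, blank flags. Round-trips with [read_dly()] to 0.1 degrees C.
#'
#' @param daily Tibble with `station_id`, `date`, `tmax`, `tmin`.
#' @return Character vector of fixed-width lines.
#' @export
encode_dly <- function(daily) {
  stopifnot(all(c("station_id", "date", "tmax", "tmin") %in% names(daily)))
  sid <- unique(daily$station_id)
  if (length(sid) != 1L) abort("encode_dly() takes a single station")
  sid <- formatC(sid, width = 11, flag = "-")

  fmt_month <- function(year, month, elem, values_by_day) {
    groups <- vapply(1:31, function(d) {
      v <- values_by_day[d]
      enc <- if (is.na(v)) -9999L else as.integer(round(v * 10))
      paste0(formatC(enc, width = 5), "   ")
    }, character(1))
    paste0(sid, sprintf("%04d", year), sprintf("%02d", month), elem,
           paste(groups, collapse = ""))
  }

  daily <- dplyr::arrange(daily, .data$date)
  ym <- format(daily$date, "%Y-%m")
  out <- character(0)
  for (key in unique(ym)) {
    block <- daily[ym == key, ]
    year <- as.integer(substr(key, 1, 4))
    month <- as.integer(substr(key, 6, 7))
    for (elem in c("TMAX", "TMIN")) {
      vals <- rep(NA_real_, 31)
      vals[as.integer(format(block$date, "%d"))] <-
        block[[if (elem == "TMAX") "tmax" else "tmin"]]
      out <- c(out, fmt_month(year, month, elem, vals))
    }
  }
  out
}

#' Read a GHCNd station inventory (ghcnd-stations.txt dialect)
#'
#' Fixed-width columns: station id 1-11, latitude 13-20, longitude 22-30,
#' elevation 32-37 (metres, -999.9 for missing), name 42-71.
#'
#' @param file Path to the inventory file, or a character vector of lines.
#' @return Tibble with `station_id`, `latitude`, `longitude`, `elevation`,
#'   `name`.
#' @export
read_ghcnd_stations <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty station inventory")

  out <- tibble::tibble(
    station_id = trimws(substr(lines, 1L, 11L)),
    latitude = suppressWarnings(as.numeric(substr(lines, 13L, 20L))),
    longitude = suppressWarnings(as.numeric(substr(lines, 22L, 30L))),
    elevation = suppressWarnings(as.numeric(substr(lines, 32L, 37L))),
    name = trimws(substr(lines, 42L, 71L))
  )
  out$elevation[!is.na(out$elevation) & out$elevation == -999.9] <- NA_real_
  if (anyNA(out$latitude) || anyNA(out$longitude)) {
    abort(sprintf("unparseable coordinates for station(s): %s",
                  paste(out$station_id[is.na(out$latitude) | is.na(out$longitude)],
                        collapse = ", ")))
  }
  bad <- abs(out$latitude) > 90 | abs(out$longitude) > 180
  if (any(bad)) {
    abort(sprintf("out-of-range coordinates for station(s): %s",
                  paste(out$station_id[bad], collapse = ", ")))
  }
  dup <- duplicated(out$station_id)
  if (any(dup)) {
    abort(sprintf("duplicate station id(s): %s",
                  paste(unique(out$station_id[dup]), collapse = ", ")))
  }
  out
}

#' Encode a station inventory as ghcnd-stations fixed-width lines
#'
#' Inverse of [read_ghcnd_stations()]; missing elevation encodes as -999.9.
#'
#' @param stations Tibble with `station_id`, `latitude`, `longitude`,
#'   `elevation`, `name`.
#' @return Character vector of fixed-width lines.
#' @export
encode_stations <- function(stations) {
  elev <- ifelse(is.na(stations$elevation), -999.9, stations$elevation)
  sprintf(
    "%-11s %8.4f %9.4f %6.1f %2s %-30s",
    stations$station_id, stations$latitude, stations$longitude,
    elev, "", substr(stations$name %||% "", 1, 30)
  )
}

#' Write and read tabular results as CSV
#'
#' All tabular outputs are comma-delimited UTF-8 with a header row; missing
#' values are written as empty fields. `read_table_csv()` round-trips what
#' `write_table()` wrote.
#'
#' @param records A data frame with named columns.
#' @param file Destination (for writing) or source (for reading) path.
#' @return `write_table()` returns `records` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table <- function(records, file) {
  stopifnot(is.data.frame(records))
  readr::write_csv(records, file, na = "")
  invisible(records)
}

#' @rdname write_table
#' @export
read_table_csv <- function(file) {
  readr::read_csv(file, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}
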