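#' Plot a season's hardiness trajectory against daily minimum temperature
#'
#' Draws the predicted (or synthetic-truth) LT50 trajectory and the daily
#' minimum temperature for one station-season; the gap between the two lines
#' is what the damage sigmoid scores.
#'
#' @param lt50 Tibble `date`, `lt50` (optionally `cultivar` for colour).
#' @param season_daily Daily tibble `date`, `tmin`.
#' @return A ggplot object.
#' @export
plot_season_hardiness <- function(lt50, season_daily) {
  p <- ggplot2::ggplot(lt50, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(
      data = season_daily,
      ggplot2::aes(y = .data$tmin),
      colour = "steelblue", alpha = 0.6
    )
  if ("cultivar" %in% names(lt50) && length(unique(lt50$cultivar)) > 1) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$lt50, colour = .data$cultivar)
    )
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$lt50),
                                colour = "firebrick")
  }
  p +
    ggplot2::labs(x = NULL, y = "temperature (°C)",
                  title = "Daily minimum temperature vs LT50") +
    ggplot2::theme_minimal()
}

#' Plot a gridded damage layer as a tile map
#'
#' @param grid Tibble from [knn_grid()] (`latitude`, `longitude`, `value`,
#'   optionally `window` for facets).
#' @return A ggplot object.
#' @export
plot_damage_grid <- function(grid) {
  p <- ggplot2::ggplot(
    grid,
    ggplot2::aes(x = .data$longitude, y = .data$latitude, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "damage\n(%)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if ("window" %in% names(grid)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$window))
  }
  p
}

#' Autoplot a fitted LT50 model: top permutation/gain importances
#'
#' @param object An `lt50_model`.
#' @param top_n Number of features to show. Default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lt50_model
#' @export
autoplot.lt50_model <- function(object, top_n = 15, ...) {
  imp <- head(tidy(object), top_n)
  ggplot2::ggplot(
    imp,
    ggplot2::aes(x = .data$gain,
                 y = stats::reorder(.data$feature, .data$gain))
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "gain", y = NULL,
                  title = "LT50 model feature importance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
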