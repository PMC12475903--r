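#' Train the LT50 regressor
#'
#' Fits a seeded gradient-boosted tree ensemble (xgboost, squared-error
#' objective, single thread for determinism) mapping the 126-column feature
#' table to observed LT50 in degrees C. A held-out fraction (default 10%) is
#' reserved before fitting and scored afterwards; the held-out RMSE and row
#' indices are recorded in the returned bundle so downstream importance
#' analysis can reuse rows the model never saw.
#'
#' @param features Data frame whose feature columns (everything except
#'   `station_id`, `season_label`, `date`, `cultivar`) feed the model.
#' @param lt50 Numeric vector of observed LT50 (degrees C), one per row.
#' @param holdout_frac Fraction of rows reserved for testing. Default 0.1.
#' @param nrounds,max_depth,eta,subsample Gradient-boosting hyperparameters.
#' @param seed Integer seed controlling the held-out split and the fit.
#' @return An object of class `lt50_model`: list with `model` (xgboost
#'   booster), `feature_names`, `seed`, `params`, `rmse_holdout`,
#'   `holdout_idx`, `n_train`.
#' @export
train_lt50_model <- function(features, lt50,
                             holdout_frac = 0.1,
                             nrounds = 600L, max_depth = 6L, eta = 0.1,
                             subsample = 1.0,
                             seed = 1L) {
  X <- feature_matrix(features)
  if (nrow(X) != length(lt50)) {
    abort(sprintf("feature/label length mismatch: %d rows vs %d labels",
                  nrow(X), length(lt50)))
  }
  if (any(!is.finite(lt50))) abort("non-finite LT50 labels")
  if (nrow(X) < 50L) abort("need at least 50 rows to train")
  if (anyNA(X)) abort("missing feature values")

  n <- nrow(X)
  set.seed(seed)
  holdout_idx <- sort(sample.int(n, size = max(1L, round(holdout_frac * n))))
  train_idx <- setdiff(seq_len(n), holdout_idx)

  params <- list(
    objective = "reg:squarederror", max_depth = max_depth,
    learning_rate = eta, subsample = subsample, nthread = 1,
    seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(
    X[train_idx, , drop = FALSE], label = lt50[train_idx], nthread = 1
  )
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  pred_hold <- predict(booster, X[holdout_idx, , drop = FALSE])
  structure(
    list(
      model = booster,
      feature_names = colnames(X),
      seed = seed,
      params = c(params, nrounds = nrounds, holdout_frac = holdout_frac),
      rmse_holdout = rmse(pred_hold, lt50[holdout_idx]),
      holdout_idx = holdout_idx,
      n_train = length(train_idx)
    ),
    class = "lt50_model"
  )
}

# strip key columns and return the numeric feature matrix in bundle order
feature_matrix <- function(features, expected = NULL) {
  keys <- intersect(c("station_id", "season_label", "date", "cultivar"),
                    names(features))
  X <- as.matrix(dplyr::select(features, -dplyr::all_of(keys)))
  if (!is.null(expected)) {
    missing <- setdiff(expected, colnames(X))
    extra <- setdiff(colnames(X), expected)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf(
        "feature columns do not match the model: missing {%s}, extra {%s}",
        paste(missing, collapse = ", "), paste(extra, collapse = ", ")
      ))
    }
    X <- X[, expected, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}

#' Predict LT50 from a feature table
#'
#' Applies a fitted [train_lt50_model()] bundle row-wise; raw model outputs
#' are clamped to the physiologically plausible LT50 band (default
#' \[-40, 0\] degrees C).
#'
#' @param bundle An `lt50_model`.
#' @param features Feature table with exactly the bundle's feature columns
#'   (key columns `station_id`, `season_label`, `date`, `cultivar` are
#'   carried through if present).
#' @param clamp Length-2 clamp band in degrees C.
#' @return Tibble of the key columns plus `lt50` (degrees C).
#' @export
predict_lt50 <- function(bundle, features, clamp = c(-40, 0)) {
  stopifnot(inherits(bundle, "lt50_model"))
  X <- feature_matrix(features, expected = bundle$feature_names)
  raw <- predict(bundle$model, X)
  keys <- intersect(c("station_id", "season_label", "date", "cultivar"),
                    names(features))
  out <- tibble::as_tibble(features[, keys, drop = FALSE])
  out$lt50 <- pmin(clamp[2], pmax(clamp[1], raw))
  out
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors (degrees C).
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("predicted and observed must have equal length")
  }
  if (length(predicted) == 0L) abort("empty input to rmse")
  sqrt(mean((predicted - observed)^2))
}

#' Cold-damage potential from daily minimum temperature and LT50
#'
#' Scores the chance (0-100) that a day's minimum temperature injured
#' dormant buds with a symmetric logistic in the gap `tmin - lt50`:
#' `100 / (1 + exp(k * (tmin - lt50)))` with `k = log(9) / 2`, the unique
#' logistic slope putting the potential at 10 when the minimum sits 2
#' degrees C above the predicted LT50 and at 90 when it sits 2 degrees C
#' below, and at 50 when they coincide.
#'
#' @param tmin Daily minimum temperature, degrees C (vectorised).
#' @param lt50 Predicted LT50, degrees C (vectorised).
#' @return Damage potential in \[0, 100\].
#' @export
damage_potential <- function(tmin, lt50) {
  k <- log(9) / 2
  100 / (1 + exp(k * (tmin - lt50)))
}

#' Permutation feature importance on held-out rows
#'
#' Importance of a feature = mean increase in held-out RMSE when that
#' feature's column is shuffled, over `n_permutations` seeded shuffles.
#' Rows used must not have been seen in training; by default the bundle's
#' recorded held-out rows are the natural input.
#'
#' @param bundle An `lt50_model`.
#' @param features Feature table of evaluation rows.
#' @param lt50 Observed LT50 for those rows.
#' @param n_permutations Shuffles per feature. Default 5.
#' @param seed Integer seed.
#' @param clamp Clamp band passed to prediction.
#' @return Tibble `feature`, `importance` (mean RMSE increase, degrees C),
#'   `se` (standard error over shuffles), sorted descending.
#' @export
feature_importance <- function(bundle, features, lt50,
                               n_permutations = 5L, seed = 1L,
                               clamp = c(-40, 0)) {
  stopifnot(inherits(bundle, "lt50_model"))
  if (n_permutations < 1L) abort("n_permutations must be >= 1")
  X <- feature_matrix(features, expected = bundle$feature_names)
  base_pred <- pmin(clamp[2], pmax(clamp[1], predict(bundle$model, X)))
  base_rmse <- rmse(base_pred, lt50)
  set.seed(seed)
  res <- purrr::map(colnames(X), function(f) {
    deltas <- vapply(seq_len(n_permutations), function(p) {
      Xp <- X
      Xp[, f] <- Xp[sample.int(nrow(Xp)), f]
      pred <- pmin(clamp[2], pmax(clamp[1], predict(bundle$model, Xp)))
      rmse(pred, lt50) - base_rmse
    }, numeric(1))
    tibble::tibble(
      feature = f,
      importance = mean(deltas),
      se = stats::sd(deltas) / sqrt(n_permutations)
    )
  })
  dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Save / load a fitted LT50 model bundle
#'
#' The booster is written with xgboost's own serialiser next to a JSON
#' sidecar carrying the seed, feature names, hyperparameters and held-out
#' RMSE.
#'
#' @param bundle An `lt50_model`.
#' @param path Directory to write into (created if needed).
#' @return `save_lt50_model()` returns `path` invisibly; `load_lt50_model()`
#'   returns the restored `lt50_model`.
#' @export
save_lt50_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "lt50_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$model, file.path(path, "model.ubj"))
  meta <- bundle[c("feature_names", "seed", "params", "rmse_holdout",
                   "holdout_idx", "n_train")]
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lt50_model
#' @export
load_lt50_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  structure(
    c(list(model = xgboost::xgb.load(file.path(path, "model.ubj"))), meta),
    class = "lt50_model"
  )
}

#' @export
print.lt50_model <- function(x, ...) {
  cat(sprintf(
    "<lt50_model> %d features, %d training rows, held-out RMSE %.3f C (seed %d)\n",
    length(x$feature_names), x$n_train, x$rmse_holdout, x$seed
  ))
  invisible(x)
}

#' Tidy and glance methods for fitted LT50 models
#'
#' `tidy()` returns the booster's gain-based feature importances, one row per
#' feature used; `glance()` returns a one-row model summary.
#'
#' @param x An `lt50_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lt50_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$model)
  tibble::tibble(
    feature = imp$Feature,
    gain = imp$Gain,
    cover = imp$Cover,
    frequency = imp$Frequency
  )
}

#' @rdname tidy.lt50_model
#' @export
glance.lt50_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_train = x$n_train,
    n_holdout = length(x$holdout_idx),
    rmse_holdout = x$rmse_holdout,
    nrounds = as.integer(x$params$nrounds),
    max_depth = as.integer(x$params$max_depth),
    learning_rate = as.numeric(x$params$learning_rate),
    seed = as.integer(x$seed)
  )
}

#' @rdname tidy.lt50_model
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy.lt50_model
#' @export
glance <- function(x, ...) UseMethod("glance")
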