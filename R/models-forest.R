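# Random forest and geographical random forest (a global forest blended
# with per-location forests trained on spatial neighborhoods), both backed
# by ranger.

#' Fit a random forest regressor
#'
#' A seeded regression forest with impurity-based feature importances
#' normalized to sum to 1. Out-of-bag R² is reported for diagnostics
#' alongside the in-sample metrics.
#'
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param n_trees Number of trees.
#' @param mtry Variables tried per split (default: ranger's regression
#'   default, p/3 rounded).
#' @param min_node Minimum node size.
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @param seed Integer seed; fixes bootstrap and split draws.
#' @return A `mob_rf` model object with an `importances` tibble.
#' @export
fit_rf <- function(design, outcome, n_trees = 500, mtry = NULL, min_node = 5,
                   max_depth = 0, seed = 1L) {
  if (n_trees < 1) {
    abort("invalid-config: `n_trees` must be >= 1",
          class = "mobesity_invalid_config")
  }
  X <- as.data.frame(design)
  fit <- ranger::ranger(y = outcome, x = X, num.trees = n_trees, mtry = mtry,
                        min.node.size = min_node, max.depth = max_depth,
                        importance = "impurity", seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  fitted <- stats::predict(fit, data = X, num.threads = 1)$predictions
  res <- outcome - fitted
  tss <- sum((outcome - mean(outcome))^2)
  metrics <- list(r2 = 1 - sum(res^2) / tss, rmse = sqrt(mean(res^2)),
                  oob_r2 = fit$r.squared)
  new_model_result("rf", fitted = fitted, residuals = res, metrics = metrics,
                   importances = tibble::tibble(variable = names(imp),
                                                importance = unname(imp)) |>
                     dplyr::arrange(dplyr::desc(.data$importance)),
                   ranger_fit = fit)
}

#' @describeIn fit_rf Normalized feature importances, descending.
#' @param x A `mob_rf` object.
#' @param ... Unused.
#' @export
tidy.mob_rf <- function(x, ...) x$importances

#' @export
predict.mob_rf <- function(object, newdata, ...) {
  stats::predict(object$ranger_fit, data = as.data.frame(newdata),
                 num.threads = 1)$predictions
}

#' @export
autoplot.mob_rf <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$variable,
                                                     .data$importance))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$variable),
                          color = "grey60") +
    ggplot2::geom_point(color = "steelblue", size = 2) +
    ggplot2::labs(x = "normalized importance", y = NULL,
                  title = "Random-forest feature importance") +
    ggplot2::theme_minimal()
}

grf_local_seed <- function(seed, i) derive_seed(seed, 10000L + i)

#' Fit a geographical random forest
#'
#' Trains one global forest plus, for every location, a local forest on its
#' `n_local_neighbors` spatially nearest observations (the location itself
#' included). Fitted values blend the global and local predictions:
#' `blend_weight * global + (1 - blend_weight) * local`. Per-location local
#' importances are retained, enabling maps of spatially varying variable
#' relevance. Out-of-sample points are served by the local forest of their
#' nearest training location (retrained deterministically on demand).
#'
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param coords Planar coordinates of the observations.
#' @param n_local_neighbors Size of each local training neighborhood
#'   (documented floor 20; must not exceed n).
#' @param blend_weight Weight on the global forest in `[0, 1]`; 1 reproduces
#'   the global forest exactly.
#' @param n_trees Trees in the global forest.
#' @param local_trees Trees in each local forest.
#' @param min_node Minimum node size (both levels).
#' @param seed Integer seed; local forests derive per-location seeds.
#' @return A `mob_grf` model object with `local_importances` (one row per
#'   location, one column per variable, rows normalized to sum to 1).
#' @export
fit_grf <- function(design, outcome, coords, n_local_neighbors = 100,
                    blend_weight = 0.5, n_trees = 200, local_trees = 60,
                    min_node = 5, seed = 1L) {
  X <- as.data.frame(design)
  n <- nrow(X)
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  if (n_local_neighbors > n) {
    abort("invalid-config: `n_local_neighbors` exceeds the number of observations",
          class = "mobesity_invalid_config")
  }
  if (n_local_neighbors < 20) {
    abort("invalid-config: `n_local_neighbors` must be >= 20",
          class = "mobesity_invalid_config")
  }
  if (blend_weight < 0 || blend_weight > 1) {
    abort("invalid-config: `blend_weight` must lie in [0, 1]",
          class = "mobesity_invalid_config")
  }
  global <- fit_rf(X, outcome, n_trees = n_trees, min_node = min_node,
                   seed = seed)
  d <- cross_dist(coords, coords)
  local_pred <- numeric(n)
  imp <- matrix(0, n, ncol(X), dimnames = list(NULL, names(X)))
  for (i in seq_len(n)) {
    nn <- order(d[i, ], seq_len(n))[seq_len(n_local_neighbors)]
    lf <- ranger::ranger(y = outcome[nn], x = X[nn, , drop = FALSE],
                         num.trees = local_trees, min.node.size = min_node,
                         importance = "impurity",
                         seed = grf_local_seed(seed, i), num.threads = 1)
    local_pred[i] <- stats::predict(lf, data = X[i, , drop = FALSE],
                                    num.threads = 1)$predictions
    li <- lf$variable.importance
    imp[i, ] <- if (sum(li) > 0) li / sum(li) else 1 / length(li)
  }
  fitted <- blend_weight * global$fitted + (1 - blend_weight) * local_pred
  res <- outcome - fitted
  tss <- sum((outcome - mean(outcome))^2)
  metrics <- list(r2 = 1 - sum(res^2) / tss, rmse = sqrt(mean(res^2)),
                  oob_r2_global = global$metrics$oob_r2)
  new_model_result("grf", fitted = fitted, residuals = res, metrics = metrics,
                   global_fit = global,
                   local_importances = tibble::as_tibble(as.data.frame(imp)),
                   design = X, outcome = outcome, coords = coords,
                   n_local_neighbors = n_local_neighbors,
                   blend_weight = blend_weight, local_trees = local_trees,
                   min_node = min_node, seed = seed)
}

#' @describeIn fit_grf Local importances in long form with coordinates.
#' @param x A `mob_grf` object.
#' @param ... Unused.
#' @export
tidy.mob_grf <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(location = seq_len(nrow(x$local_importances)),
                   x = x$coords[, 1], y = x$coords[, 2]),
    x$local_importances) |>
    tidyr::pivot_longer(-c("location", "x", "y"), names_to = "variable",
                        values_to = "importance")
}

#' @export
predict.mob_grf <- function(object, newdata, newcoords, ...) {
  Xn <- as.data.frame(newdata)[, names(object$design), drop = FALSE]
  nc <- as.matrix(as.data.frame(newcoords)[, 1:2])
  gpred <- predict(object$global_fit, Xn)
  d_train <- cross_dist(object$coords, object$coords)
  d_new <- cross_dist(nc, object$coords)
  nearest <- apply(d_new, 1, which.min)
  lpred <- numeric(nrow(Xn))
  for (i in unique(nearest)) {
    rows <- which(nearest == i)
    nn <- order(d_train[i, ], seq_len(nrow(object$design)))[
      seq_len(object$n_local_neighbors)]
    lf <- ranger::ranger(y = object$outcome[nn],
                         x = object$design[nn, , drop = FALSE],
                         num.trees = object$local_trees,
                         min.node.size = object$min_node,
                         seed = grf_local_seed(object$seed, i),
                         num.threads = 1)
    lpred[rows] <- stats::predict(lf, data = Xn[rows, , drop = FALSE],
                                  num.threads = 1)$predictions
  }
  object$blend_weight * gpred + (1 - object$blend_weight) * lpred
}
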