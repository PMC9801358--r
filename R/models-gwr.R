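# Geographically weighted regression: per-location weighted least squares
# with an adaptive bisquare kernel, corrected-AIC model complexity via the
# hat-matrix trace, and golden-section bandwidth selection.

# Core GWR sweep for one adaptive bandwidth. Returns local coefficients,
# fitted values, and the diagonal of the hat matrix. `loo = TRUE` zeroes the
# self-weight (leave-one-out prediction, used by the CV criterion).
gwr_engine <- function(X, y, d, bandwidth, kernel = "bisquare", loo = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(n)
  s_ii <- numeric(n)
  ridge_used <- FALSE
  for (i in seq_len(n)) {
    di <- d[i, ]
    dmax <- sort(di, partial = bandwidth)[bandwidth]
    if (kernel == "bisquare") {
      w <- ifelse(di < dmax, (1 - (di / dmax)^2)^2, 0)
    } else {  # uniform: every point within the bandwidth weighted equally
      w <- as.numeric(di <= dmax)
    }
    if (loo) w[i] <- 0
    xw <- X * w
    M <- crossprod(X, xw)
    rhs <- crossprod(xw, y)
    b <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(b)) {
      ridge_used <- TRUE
      M <- M + diag(1e-8 * max(diag(M), 1), p)
      b <- solve(M, rhs)
    }
    beta[i, ] <- b
    fitted[i] <- sum(X[i, ] * b)
    s_ii[i] <- if (loo) 0 else w[i] * as.numeric(X[i, , drop = FALSE] %*%
                                                   solve(M, X[i, ]))
  }
  if (ridge_used) {
    warn("singular local design at one or more locations; ridge fallback (1e-8) applied")
  }
  list(beta = beta, fitted = fitted, s_ii = s_ii)
}

gwr_aicc <- function(X, y, d, bandwidth, kernel) {
  eng <- gwr_engine(X, y, d, bandwidth, kernel)
  n <- length(y)
  rss <- sum((y - eng$fitted)^2)
  trS <- sum(eng$s_ii)
  sigma <- sqrt(rss / n)
  if (sigma <= 0 || n - 2 - trS <= 0) return(Inf)
  2 * n * log(sigma) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

gwr_cv_score <- function(X, y, d, bandwidth, kernel) {
  eng <- gwr_engine(X, y, d, bandwidth, kernel, loo = TRUE)
  sum((y - eng$fitted)^2)
}

#' Golden-section search for the adaptive GWR bandwidth
#'
#' Selects the adaptive bandwidth (number of nearest neighbors, the focal
#' point included) minimizing the corrected AIC (default) or the
#' leave-one-out CV score over `[p + 2, n]`. A coarse scan first brackets
#' the minimum; golden-section search then refines inside the bracket. If
#' the scan yields no finite criterion values the search falls back to a
#' dense grid with a warning.
#'
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param coords Two-column matrix (or data frame with `x`, `y`) of planar
#'   coordinates.
#' @param criterion `"aicc"` (default) or `"cv"`.
#' @param kernel `"bisquare"` (default) or `"uniform"`.
#' @return Integer bandwidth, with the evaluated search trace attached as
#'   attribute `"trace"` (a tibble of bandwidth/criterion pairs).
#' @export
gwr_bandwidth <- function(design, outcome, coords, criterion = c("aicc", "cv"),
                          kernel = c("bisquare", "uniform")) {
  criterion <- match.arg(criterion)
  kernel <- match.arg(kernel)
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(design)))
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  n <- nrow(X)
  if (n < 30) {
    abort("invalid-input: bandwidth selection needs at least 30 locations",
          class = "mobesity_invalid_config")
  }
  d <- cross_dist(coords, coords)
  lo <- ncol(X) + 2L
  hi <- n
  crit_fun <- if (criterion == "aicc") gwr_aicc else gwr_cv_score
  cache <- new.env(parent = emptyenv())
  f <- function(bw) {
    key <- as.character(bw)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- crit_fun(X, outcome, d, bw, kernel)
    cache[[key]] <- val
    val
  }

  # Coarse bracketing scan.
  grid <- unique(round(seq(lo, hi, length.out = min(10, hi - lo + 1))))
  vals <- vapply(grid, f, numeric(1))
  if (all(!is.finite(vals))) {
    warn("bandwidth criterion non-finite on the bracketing scan; falling back to a dense grid")
    grid <- unique(round(seq(lo, hi, length.out = min(25, hi - lo + 1))))
    vals <- vapply(grid, f, numeric(1))
  }
  m <- which.min(vals)
  a <- grid[max(m - 1L, 1L)]
  b <- grid[min(m + 1L, length(grid))]

  # Golden-section refinement on the integer bracket.
  gr <- (sqrt(5) - 1) / 2
  while (b - a > 2L) {
    x1 <- as.integer(round(b - gr * (b - a)))
    x2 <- as.integer(round(a + gr * (b - a)))
    if (x1 >= x2) { x1 <- a + (b - a) %/% 3L; x2 <- b - (b - a) %/% 3L }
    if (f(x1) <= f(x2)) b <- x2 else a <- x1
  }
  keys <- sort(as.integer(ls(cache)))
  evaluated <- tibble::tibble(
    bandwidth = keys,
    criterion = vapply(as.character(keys), function(k) cache[[k]], numeric(1)))
  best <- evaluated$bandwidth[which.min(evaluated$criterion)]
  structure(as.integer(best), trace = evaluated, criterion = criterion)
}

#' Fit a geographically weighted regression
#'
#' For every location, fits a weighted least-squares model with adaptive
#' bisquare weights `w = (1 - (d/d_max)^2)^2` for `d < d_max`, where
#' `d_max` is the distance to the `bandwidth`-th nearest location (the focal
#' point counted among them), and zero beyond. Reports local coefficients,
#' the hat-matrix trace as the effective number of parameters, in-sample R²
#' and RMSE, adjusted R² using the effective parameters, and the corrected
#' AIC `2n log(sigma) + n log(2*pi) + n (n + tr(S)) / (n - 2 - tr(S))`.
#'
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param coords Planar coordinates (matrix or data frame with two columns).
#' @param bandwidth `"auto"` (golden-section selection) or an integer
#'   `>= ncol(design) + 2`.
#' @param kernel `"bisquare"` (default) or `"uniform"` (all points within
#'   the bandwidth weighted 1; at `bandwidth = n` this reduces exactly to
#'   the global OLS fit).
#' @param criterion Bandwidth-selection criterion when `bandwidth = "auto"`.
#' @return A `mob_gwr` model object with `local_coefficients` (one row per
#'   location), `bandwidth`, `effective_parameters`, and metrics.
#' @export
fit_gwr <- function(design, outcome, coords, bandwidth = "auto",
                    kernel = c("bisquare", "uniform"),
                    criterion = c("aicc", "cv")) {
  kernel <- match.arg(kernel)
  criterion <- match.arg(criterion)
  Xdf <- as.data.frame(design)
  X <- cbind(`(Intercept)` = 1, as.matrix(Xdf))
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  n <- nrow(X)
  if (any(!is.finite(coords))) {
    abort("invalid-input: non-finite coordinates",
          class = "mobesity_invalid_config")
  }
  if (identical(bandwidth, "auto")) {
    bandwidth <- gwr_bandwidth(Xdf, outcome, coords, criterion = criterion,
                               kernel = kernel)
  }
  bandwidth <- as.integer(bandwidth)
  if (bandwidth < ncol(X) + 1 || bandwidth > n) {
    abort("invalid-config: bandwidth must lie in [p + 2, n]",
          class = "mobesity_invalid_config")
  }
  d <- cross_dist(coords, coords)
  eng <- gwr_engine(X, outcome, d, bandwidth, kernel)
  res <- outcome - eng$fitted
  rss <- sum(res^2)
  tss <- sum((outcome - mean(outcome))^2)
  trS <- sum(eng$s_ii)
  r2 <- 1 - rss / tss
  sigma <- sqrt(rss / n)
  aicc <- if (sigma > 0 && n - 2 - trS > 0) {
    2 * n * log(sigma) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
  } else {
    -Inf
  }
  metrics <- list(r2 = r2,
                  adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - trS - 1),
                  rmse = sqrt(rss / n), aic = aicc,
                  effective_parameters = trS,
                  bandwidth = bandwidth)
  local_coefficients <- tibble::as_tibble(as.data.frame(eng$beta))
  new_model_result("gwr", fitted = eng$fitted, residuals = res,
                   metrics = metrics, local_coefficients = local_coefficients,
                   coords = coords, kernel = kernel, bandwidth = bandwidth,
                   terms = colnames(X))
}

#' @describeIn fit_gwr Local coefficients in long form: one row per
#'   (location, term) with the location's coordinates.
#' @param x A `mob_gwr` object.
#' @param ... Unused.
#' @export
tidy.mob_gwr <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(location = seq_len(nrow(x$local_coefficients)),
                   x = x$coords[, 1], y = x$coords[, 2]),
    x$local_coefficients) |>
    tidyr::pivot_longer(-c("location", "x", "y"), names_to = "term",
                        values_to = "estimate")
}

#' @export
predict.mob_gwr <- function(object, newdata, newcoords, ...) {
  # Out-of-sample prediction borrows the local model of the nearest fitted
  # location.
  Xn <- cbind(1, as.matrix(as.data.frame(newdata)[, object$terms[-1], drop = FALSE]))
  nc <- as.matrix(as.data.frame(newcoords)[, 1:2])
  d <- cross_dist(nc, object$coords)
  nearest <- apply(d, 1, which.min)
  B <- as.matrix(object$local_coefficients)[nearest, , drop = FALSE]
  rowSums(Xn * B)
}

#' @export
autoplot.mob_gwr <- function(object, term = NULL, ...) {
  d <- tidy(object)
  if (is.null(term)) term <- setdiff(unique(d$term), "(Intercept)")[1]
  d <- dplyr::filter(d, .data$term == !!term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("GWR local coefficients: %s", term),
                  color = "estimate") +
    ggplot2::theme_minimal()
}
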