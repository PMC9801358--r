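# Spatial weights, global Moran's I, standardization, VIF diagnosis with
# iterative elimination, and bivariate correlations.

#' k-nearest-neighbor spatial weights
#'
#' Binary k-NN weights on centroid Euclidean distance, row-standardized.
#' Ties in distance are broken by tract order (and therefore by `tract_id`
#' when the table is id-sorted), which keeps the neighbor sets deterministic
#' even with duplicated centroids.
#'
#' @param tracts A tract table with `x`, `y` (and optionally `tract_id`)
#'   columns, or a two-column coordinate matrix.
#' @param k Number of neighbors, `1 <= k < n`.
#' @param symmetrize Make the neighbor relation symmetric by union before
#'   row-standardizing?
#' @return An object of class `spatial_weights`: ids, per-row neighbor index
#'   lists and weights, `row_standardized = TRUE`.
#' @export
knn_weights <- function(tracts, k = 8, symmetrize = FALSE) {
  if (is.matrix(tracts)) {
    coords <- tracts
    ids <- as.character(seq_len(nrow(coords)))
  } else {
    coords <- cbind(tracts$x, tracts$y)
    ids <- if ("tract_id" %in% names(tracts)) tracts$tract_id
           else as.character(seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (any(!is.finite(coords))) {
    abort("invalid-input: non-finite centroid coordinates",
          class = "mobesity_invalid_config")
  }
  if (k >= n || k < 1) {
    abort("invalid-config: need 1 <= k < number of tracts",
          class = "mobesity_invalid_config")
  }
  d <- cross_dist(coords, coords)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # stable: ties broken by id order
    ord <- ord[ord != i]
    nb[[i]] <- sort(ord[seq_len(k)])
  }
  if (symmetrize) {
    for (i in seq_len(n)) {
      for (j in nb[[i]]) {
        if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
      }
    }
  }
  w <- lapply(nb, function(js) rep(1 / length(js), length(js)))
  structure(list(ids = ids, neighbors = nb, weights = w,
                 row_standardized = TRUE, k = as.integer(k)),
            class = "spatial_weights")
}

#' Dense matrix form of spatial weights
#'
#' @param weights A [knn_weights()] object.
#' @return An n x n numeric matrix with zero diagonal.
#' @export
weights_matrix <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, weights$neighbors[[i]]] <- weights$weights[[i]]
  }
  W
}

#' Global Moran's I with permutation inference
#'
#' Computes `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)` and `S0` the total weight. The null expectation is
#' `-1/(n-1)`. Inference is reported two ways: a seeded permutation test
#' (two-sided, doubling the smaller one-sided rank p-value) and the
#' normal approximation under the normality assumption.
#'
#' @param values Numeric vector aligned with the weights' ids.
#' @param weights A [knn_weights()] object.
#' @param n_permutations Number of value permutations for the null.
#' @param seed Seed for the permutation draws.
#' @return An object of class `mob_moran` with elements `statistic`,
#'   `expected`, `sd_norm`, `p_norm`, `p_perm`, `n`, `n_permutations`.
#' @export
morans_i <- function(values, weights, n_permutations = 999, seed = 1L) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != length(weights$ids)) {
    abort("invalid-input: values not aligned with weights ids",
          class = "mobesity_invalid_config")
  }
  if (stats::var(values) == 0) {
    abort("degenerate-input: constant values have no spatial autocorrelation",
          class = "mobesity_degenerate_input")
  }
  W <- weights_matrix(weights)
  S0 <- sum(W)
  z <- values - mean(values)
  denom <- sum(z^2)
  I_of <- function(zz) (n / S0) * as.numeric(crossprod(zz, W %*% zz)) / denom
  I <- I_of(z)
  EI <- -1 / (n - 1)

  # Normal-approximation variance (normality assumption).
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  sd_norm <- sqrt(max(VarI, 0))
  p_norm <- 2 * stats::pnorm(-abs((I - EI) / sd_norm))

  p_perm <- NA_real_
  perm <- numeric(0)
  if (n_permutations > 0) {
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) I_of(z[sample.int(n)]), numeric(1))
    })
    ge <- (1 + sum(perm >= I)) / (n_permutations + 1)
    le <- (1 + sum(perm <= I)) / (n_permutations + 1)
    p_perm <- min(1, 2 * min(ge, le))
  }
  structure(list(statistic = I, expected = EI, sd_norm = sd_norm,
                 p_norm = p_norm, p_perm = p_perm, n = n,
                 n_permutations = n_permutations,
                 permutations = perm),
            class = "mob_moran")
}

#' @export
print.mob_moran <- function(x, ...) {
  cat(sprintf("Global Moran's I: %.4f (expected %.4f under the null)\n",
              x$statistic, x$expected))
  cat(sprintf("  permutation p (two-sided, %d perms): %.4g; normal-approx p: %.4g\n",
              x$n_permutations, x$p_perm, x$p_norm))
  invisible(x)
}

#' @export
glance.mob_moran <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, expected = x$expected,
                 sd_norm = x$sd_norm, p_norm = x$p_norm, p_perm = x$p_perm,
                 n = x$n, n_permutations = x$n_permutations)
}

#' Standardize design columns to zero mean and unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator). The per-column
#' centers and scales are attached as attributes so the transform can be
#' inverted.
#'
#' @param design Data frame or matrix of numeric covariates.
#' @param cols Columns to standardize (default: all numeric columns).
#' @return A tibble of standardized columns with attributes `center` and
#'   `scale`.
#' @export
standardize_columns <- function(design, cols = NULL) {
  df <- tibble::as_tibble(as.data.frame(design))
  if (is.null(cols)) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  ctr <- vapply(cols, function(v) mean(df[[v]]), numeric(1))
  scl <- vapply(cols, function(v) stats::sd(df[[v]]), numeric(1))
  zero <- names(scl)[!is.finite(scl) | scl == 0]
  if (length(zero) > 0) {
    abort(sprintf("degenerate-column: zero standard deviation in: %s",
                  paste(zero, collapse = ", ")),
          class = "mobesity_degenerate_input")
  }
  for (v in cols) df[[v]] <- (df[[v]] - ctr[v]) / scl[v]
  attr(df, "center") <- ctr
  attr(df, "scale") <- scl
  df
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from regressing column `j` on all
#' remaining columns (intercept included). Exactly collinear columns report
#' `Inf`.
#'
#' @param design Data frame or matrix with at least two columns and more
#'   rows than columns.
#' @return A tibble: `variable`, `vif`, sorted by descending VIF.
#' @export
vif <- function(design) {
  X <- as.data.frame(design)
  p <- ncol(X)
  if (nrow(X) <= p) {
    abort("underdetermined-design: need more rows than columns",
          class = "mobesity_invalid_config")
  }
  if (p < 2) {
    return(tibble::tibble(variable = names(X), vif = 1))
  }
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, as.matrix(X[, -j, drop = FALSE])), X[[j]])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[[j]] - mean(X[[j]]))^2)
    if (tss == 0) {
      abort(sprintf("degenerate-column: constant column '%s'", names(X)[j]),
            class = "mobesity_degenerate_input")
    }
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(variable = names(X), vif = out) |>
    dplyr::arrange(dplyr::desc(.data$vif))
}

#' Iterative VIF elimination
#'
#' Repeatedly removes the single variable with the highest VIF (ties broken
#' by the lexicographically first name) until all VIFs fall below `cutoff`.
#' An ordered `forced_removals` list is honored first, allowing judgment
#' calls — e.g. dropping one education share before the automatic rule
#' would — to be replayed deterministically.
#'
#' @param design Data frame of covariates (standardize first for the
#'   conventional reading, though VIF is scale-invariant).
#' @param cutoff VIF threshold below which the cascade stops (default 5,
#'   the typical multicollinearity cut-off).
#' @param forced_removals Optional character vector of variables to remove,
#'   in order, before automatic removals resume.
#' @return An object of class `vif_trace`: per-round VIF tables with the
#'   removed variable, the final retained set, and the final VIF table.
#' @export
vif_cascade <- function(design, cutoff = 5, forced_removals = NULL) {
  X <- tibble::as_tibble(as.data.frame(design))
  rounds <- list()
  forced <- forced_removals
  repeat {
    v <- vif(X)
    over <- max(v$vif)
    if (length(forced) == 0 && over < cutoff) break
    if (ncol(X) <= 1) {
      abort("exhaustion: cascade would empty the design",
            class = "mobesity_invalid_config")
    }
    if (length(forced) > 0) {
      drop_var <- forced[1]
      forced <- forced[-1]
      if (!drop_var %in% names(X)) {
        abort(sprintf("invalid-config: forced removal '%s' not in design", drop_var),
              class = "mobesity_invalid_config")
      }
    } else {
      cand <- v$variable[v$vif == over]
      drop_var <- sort(cand)[1]
    }
    rounds[[length(rounds) + 1]] <- list(vifs = v, removed = drop_var)
    X <- X[, setdiff(names(X), drop_var), drop = FALSE]
  }
  structure(list(rounds = rounds, retained = names(X), final_vifs = vif(X),
                 cutoff = cutoff),
            class = "vif_trace")
}

#' @export
print.vif_trace <- function(x, ...) {
  cat(sprintf("VIF cascade: %d round(s), cutoff %g\n", length(x$rounds), x$cutoff))
  for (i in seq_along(x$rounds)) {
    r <- x$rounds[[i]]
    cat(sprintf("  round %d: max VIF %.3f -> removed '%s'\n",
                i, max(r$vifs$vif), r$removed))
  }
  cat(sprintf("  retained %d variable(s); final max VIF %.3f\n",
              length(x$retained), max(x$final_vifs$vif)))
  invisible(x)
}

#' @describeIn vif_cascade Tidy the trace into one row per (round, variable),
#'   with `removed` flagging the variable eliminated that round. Round 0 is
#'   the final, post-cascade VIF table.
#' @param x A `vif_trace`.
#' @param ... Unused.
#' @export
tidy.vif_trace <- function(x, ...) {
  rounds <- purrr::imap_dfr(x$rounds, function(r, i) {
    dplyr::mutate(r$vifs, round = i, removed = .data$variable == r$removed)
  })
  final <- dplyr::mutate(x$final_vifs, round = length(x$rounds) + 1L,
                         removed = FALSE)
  dplyr::bind_rows(rounds, final) |>
    dplyr::select("round", "variable", "vif", "removed")
}

#' Pearson and Spearman correlation between two vectors
#'
#' Both coefficients with two-sided p-values; Spearman uses average ranks
#' for ties (asymptotic p so tied data are handled without warning).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A one-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`.
#' @export
correlations <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("invalid-input: need two aligned vectors of length >= 3",
          class = "mobesity_invalid_config")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("degenerate-input: constant vector", class = "mobesity_degenerate_input")
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  tibble::tibble(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Correlations between the visit measures and the outcome
#'
#' One row per visit-frequency measure, each correlated with obesity
#' prevalence across tracts.
#'
#' @param data Tract table joined with the visit measures (must contain the
#'   three `*_vf` columns and `obesity_prevalence`).
#' @return A tibble with one row per measure plus the correlation columns of
#'   [correlations()].
#' @export
measure_outcome_correlations <- function(data) {
  keep <- !is.na(data$obesity_prevalence)
  purrr::map_dfr(visit_measure_variables(), function(m) {
    dplyr::bind_cols(tibble::tibble(measure = m),
                     correlations(data[[m]][keep],
                                  data$obesity_prevalence[keep]))
  })
}

#' @export
autoplot.vif_trace <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vif,
                                  y = stats::reorder(.data$variable, .data$vif),
                                  color = .data$removed)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~round, nrow = 1) +
    ggplot2::labs(title = "VIF elimination cascade", x = "VIF (log scale)",
                  y = NULL, color = "removed") +
    ggplot2::theme_minimal()
}
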