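# Global linear model under the shared fit/predict/tidy/glance contract.

# Significance tiers used throughout the reporting.
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

new_model_result <- function(kind, fitted, residuals, metrics, ...) {
  structure(c(list(kind = kind, fitted = fitted, residuals = residuals,
                   metrics = metrics), list(...)),
            class = c(paste0("mob_", kind), "mob_model"))
}

#' @export
glance.mob_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = x$kind),
                   tibble::as_tibble(x$metrics[!vapply(x$metrics, is.null,
                                                       logical(1))]))
}

#' @export
print.mob_model <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d\n", x$kind, length(x$fitted)))
  m <- glance(x)
  print(as.data.frame(m), row.names = FALSE)
  invisible(x)
}

#' Fit the global ordinary-least-squares model
#'
#' Least squares with intercept on a (typically standardized) design,
#' reporting per-coefficient t-based p-values with the conventional
#' significance tiers (* < 0.05, ** < 0.01, *** < 0.001), in-sample R²,
#' adjusted R², RMSE, and the Gaussian-likelihood AIC.
#'
#' @param design Data frame of numeric predictors.
#' @param outcome Numeric outcome vector.
#' @return A `mob_ols` model object with `tidy()` and `glance()` methods.
#' @export
#' @examples
#' d <- tibble::tibble(x1 = rnorm(50))
#' fit <- fit_ols(d, 2 * d$x1 + 1)
#' tidy(fit)
fit_ols <- function(design, outcome) {
  X <- as.data.frame(design)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) {
    abort("invalid-input: need more rows than predictors plus intercept",
          class = "mobesity_invalid_config")
  }
  if (any(!is.finite(as.matrix(X))) || any(!is.finite(outcome))) {
    abort("invalid-input: non-finite entries in design or outcome",
          class = "mobesity_invalid_config")
  }
  df <- cbind(.outcome = outcome, X)
  fit <- stats::lm(.outcome ~ ., data = df)
  if (anyNA(coef(fit))) {
    abort("singular-design: rank-deficient design matrix",
          class = "mobesity_singular_design")
  }
  sm <- summary(fit)
  res <- stats::residuals(fit)
  metrics <- list(r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared,
                  rmse = sqrt(mean(res^2)), aic = stats::AIC(fit))
  ct <- sm$coefficients
  coefs <- tibble::tibble(term = rownames(ct), estimate = ct[, 1],
                          std_error = ct[, 2], statistic = ct[, 3],
                          p_value = ct[, 4], stars = p_stars(ct[, 4]))
  new_model_result("ols", fitted = stats::fitted(fit), residuals = res,
                   metrics = metrics, coefficients = coefs, lm_fit = fit)
}

#' @describeIn fit_ols Coefficient table (term, estimate, standard error,
#'   t statistic, p-value, significance stars).
#' @param x A `mob_ols` object.
#' @param ... Unused.
#' @export
tidy.mob_ols <- function(x, ...) x$coefficients

#' @export
predict.mob_ols <- function(object, newdata, ...) {
  unname(stats::predict(object$lm_fit, newdata = as.data.frame(newdata)))
}

#' @export
autoplot.mob_ols <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$estimate > 0), show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2) +
    ggplot2::labs(x = "standardized coefficient", y = NULL,
                  title = "OLS coefficients") +
    ggplot2::theme_minimal()
}
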