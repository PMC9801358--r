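# The baseline-vs-test experiment: tract exclusion, tenfold cross-validation,
# the five-model comparison report, importance aggregation across folds, and
# stepwise redundancy analysis.

#' Exclude tracts too small or without an outcome
#'
#' Removes tracts with fewer than `min_population` residents or a missing
#' obesity prevalence, and reports how many were excluded (count and
#' percentage) via a message and the `"exclusions"` attribute.
#'
#' @param tracts Tract table with `population` and `obesity_prevalence`.
#' @param min_population Exclusion threshold; a tract with exactly this many
#'   residents is retained ("fewer than" is strict).
#' @return The filtered tibble with attribute `exclusions` (a list with
#'   `n_excluded`, `pct_excluded`, `n_retained`).
#' @export
filter_tracts <- function(tracts, min_population = 50) {
  if (!all(c("population", "obesity_prevalence") %in% names(tracts))) {
    abort("invalid-input: tracts need `population` and `obesity_prevalence` columns",
          class = "mobesity_invalid_config")
  }
  keep <- tracts$population >= min_population &
    !is.na(tracts$obesity_prevalence)
  out <- tracts[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("empty-analysis: every tract was excluded",
          class = "mobesity_empty_analysis")
  }
  n_exc <- sum(!keep)
  pct <- 100 * n_exc / nrow(tracts)
  message(sprintf("%d census tract(s) (%.1f%%) excluded (population < %d or missing prevalence); %d retained",
                  n_exc, pct, min_population, nrow(out)))
  lat <- attr(tracts, "latent")
  if (!is.null(lat)) attr(out, "latent") <- lat[keep, , drop = FALSE]
  attr(out, "exclusions") <- list(n_excluded = n_exc, pct_excluded = pct,
                                  n_retained = nrow(out))
  out
}

#' k-fold cross-validation of one model
#'
#' Seeded fold assignment; out-of-fold predictions are pooled and R² / RMSE
#' are computed on the pooled predictions (stable even for small samples).
#'
#' @param kind Model kind (see [fit_model()]).
#' @param design Data frame of predictors.
#' @param outcome Numeric outcome.
#' @param coords Coordinates (for the spatial models).
#' @param k Number of folds (default tenfold).
#' @param seed Seed for the fold assignment and per-fold fits.
#' @param spec Hyperparameters forwarded to the fitter.
#' @return One-row tibble `r2`, `rmse`, with the fold assignment attached as
#'   attribute `"folds"` and per-fold fits' importances (random forests only)
#'   as attribute `"fold_importances"`.
#' @export
cross_validate <- function(kind, design, outcome, coords = NULL, k = 10,
                           seed = 1L, spec = list()) {
  n <- length(outcome)
  if (k > n || k < 2) {
    abort("invalid-config: need 2 <= k <= n folds",
          class = "mobesity_invalid_config")
  }
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  preds <- rep(NA_real_, n)
  fold_imps <- list()
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_model(kind, design[tr, , drop = FALSE], outcome[tr],
                     coords = if (!is.null(coords)) {
                       as.data.frame(coords)[tr, , drop = FALSE]
                     },
                     spec = spec, seed = derive_seed(seed, f))
    preds[!tr] <- predict_model(fit, design[!tr, , drop = FALSE],
                                if (!is.null(coords)) {
                                  as.data.frame(coords)[!tr, , drop = FALSE]
                                })
    if (inherits(fit, "mob_rf")) fold_imps[[f]] <- fit$importances
  }
  r2 <- 1 - sum((outcome - preds)^2) / sum((outcome - mean(outcome))^2)
  out <- tibble::tibble(r2 = r2, rmse = sqrt(mean((outcome - preds)^2)))
  attr(out, "folds") <- folds
  if (length(fold_imps) > 0) attr(out, "fold_importances") <- fold_imps
  out
}

#' Mean feature importance across cross-validation folds
#'
#' Arithmetic mean of per-fold normalized importances, sorted descending and
#' ranked; the per-fold normalization (sum 1) is preserved by the mean.
#'
#' @param fold_results List of importance tibbles (`variable`, `importance`)
#'   or named numeric vectors, one per fold, over identical variable sets.
#' @return Tibble `variable`, `mean_importance`, `rank`.
#' @export
aggregate_importance <- function(fold_results) {
  if (length(fold_results) < 1) {
    abort("invalid-input: need at least one fold result",
          class = "mobesity_invalid_config")
  }
  as_vec <- function(f) {
    if (is.data.frame(f)) setNames(f$importance, f$variable) else f
  }
  vecs <- lapply(fold_results, as_vec)
  vars <- sort(names(vecs[[1]]))
  for (v in vecs) {
    if (!identical(sort(names(v)), vars)) {
      abort("schema: inconsistent variable sets across folds",
            class = "mobesity_invalid_config")
    }
  }
  m <- rowMeans(vapply(vecs, function(v) v[vars], numeric(length(vars))))
  tibble::tibble(variable = vars, mean_importance = unname(m)) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Baseline-versus-test model comparison
#'
#' Runs the five estimators on two nested analysis sets — the baseline
#' (post-cascade socioeconomic/demographic variables) and the test set
#' (baseline plus the three visit-frequency measures) — and reports, per
#' model and set, the convention-appropriate metrics: in-sample R²,
#' adjusted R², RMSE, and AIC for the statistical models (OLS, GWR);
#' tenfold-cross-validated R² and RMSE for the machine-learning models
#' (RF, DNN, GRF). A model failure (e.g. the network's sample-size floor on
#' a small city) is recorded as an annotated row, not an abort.
#'
#' @param tracts Filtered tract table (see [filter_tracts()]); filtering is
#'   applied here if unfiltered rows remain.
#' @param measures Visit-measure table from [derive_visit_measures()].
#' @param baseline_vars Character vector of baseline covariates; by default
#'   the post-[vif_cascade()] demographic set is computed on the spot.
#' @param models Model kinds to run.
#' @param k CV folds for the machine-learning models.
#' @param seed Master seed.
#' @param specs Named list of per-model hyperparameter lists.
#' @param vif_cutoff Cutoff for the automatic cascade when `baseline_vars`
#'   is not supplied.
#' @param min_population Tract exclusion threshold.
#' @return A `mob_comparison` object: a tibble with one row per
#'   (model, analysis set) and columns `r2`, `rmse`, `adjusted_r2`, `aic`,
#'   `source`, `note`; attributes carry the baseline variable set, the
#'   cascade trace (when computed), and any RF fold importances.
#' @export
compare_models <- function(tracts, measures,
                           baseline_vars = NULL,
                           models = c("ols", "gwr", "rf", "dnn", "grf"),
                           k = 10, seed = 1L, specs = list(),
                           vif_cutoff = 5, min_population = 50) {
  if (anyNA(tracts$obesity_prevalence) ||
      any(tracts$population < min_population)) {
    tracts <- filter_tracts(tracts, min_population)
  }
  data <- dplyr::inner_join(tracts, measures, by = "tract_id")
  cascade <- NULL
  if (is.null(baseline_vars)) {
    demo <- standardize_columns(data[, demographic_variables()])
    cascade <- vif_cascade(demo, cutoff = vif_cutoff)
    baseline_vars <- cascade$retained
  }
  test_vars <- c(baseline_vars, visit_measure_variables())
  design_all <- standardize_columns(data[, test_vars])
  outcome <- data$obesity_prevalence
  coords <- data[, c("x", "y")]

  rows <- list()
  fold_imps <- list()
  for (kind in models) {
    for (set in c("baseline", "test")) {
      vars <- if (set == "baseline") baseline_vars else test_vars
      design <- design_all[, vars, drop = FALSE]
      spec <- specs[[kind]] %||% list()
      row <- tryCatch({
        if (kind %in% c("ols", "gwr")) {
          fit <- fit_model(kind, design, outcome, coords = coords,
                           spec = spec, seed = seed)
          g <- fit$metrics
          tibble::tibble(model = kind, set = set, r2 = g$r2, rmse = g$rmse,
                         adjusted_r2 = g$adjusted_r2, aic = g$aic,
                         source = "in_sample", note = NA_character_)
        } else {
          cv <- cross_validate(kind, design, outcome, coords = coords,
                               k = k, seed = derive_seed(seed, 100L), spec = spec)
          if (kind == "rf") {
            fold_imps[[set]] <- attr(cv, "fold_importances")
          }
          tibble::tibble(model = kind, set = set, r2 = cv$r2, rmse = cv$rmse,
                         adjusted_r2 = NA_real_, aic = NA_real_,
                         source = "cv", note = NA_character_)
        }
      }, error = function(e) {
        tibble::tibble(model = kind, set = set, r2 = NA_real_,
                       rmse = NA_real_, adjusted_r2 = NA_real_,
                       aic = NA_real_, source = NA_character_,
                       note = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("mob_comparison", class(out)),
            baseline_vars = baseline_vars, cascade = cascade, seed = seed,
            k = k, n = length(outcome), rf_fold_importances = fold_imps)
}

#' @describeIn compare_models Long-form metrics with improvement flags:
#'   `improved` is `TRUE` when the test analysis beats the baseline on that
#'   metric (higher R², lower RMSE/AIC) at 3-decimal resolution and `NA` on
#'   a tie, mirroring the conservative tie-reporting convention.
#' @param x A `mob_comparison`.
#' @param ... Unused.
#' @export
tidy.mob_comparison <- function(x, ...) {
  long <- tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("r2", "rmse", "adjusted_r2", "aic"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value) | !is.na(.data$note))
  wide <- long |>
    tidyr::pivot_wider(id_cols = c("model", "metric"), names_from = "set",
                       values_from = "value")
  flags <- wide |>
    dplyr::mutate(
      higher_better = .data$metric %in% c("r2", "adjusted_r2"),
      b3 = round(.data$baseline, 3), t3 = round(.data$test, 3),
      improved = dplyr::case_when(
        is.na(.data$b3) | is.na(.data$t3) ~ NA,
        .data$b3 == .data$t3 ~ NA,
        .data$higher_better ~ .data$t3 > .data$b3,
        TRUE ~ .data$t3 < .data$b3),
      tie = !is.na(.data$b3) & !is.na(.data$t3) & .data$b3 == .data$t3) |>
    dplyr::select("model", "metric", "improved", "tie")
  dplyr::left_join(long, flags, by = c("model", "metric"))
}

#' @export
print.mob_comparison <- function(x, ...) {
  cat(sprintf("Baseline vs test comparison (n = %d, %d-fold CV for ML models)\n",
              attr(x, "n"), attr(x, "k")))
  print(as.data.frame(tibble::as_tibble(x)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
autoplot.mob_comparison <- function(object, metric = "r2", ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data[[metric]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data[[metric]],
                                  fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(title = sprintf("Baseline vs test: %s", metric),
                  x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Stepwise regression starting from the derived measures
#'
#' Starts with the visit-frequency measures and gradually adds the
#' socioeconomic/demographic candidates: each forward step adds the
#' candidate with the smallest entry p-value below `p_enter`; after every
#' addition a backward pass drops any current variable — including the
#' starting measures — whose p-value exceeds `p_remove`, recording which
#' entering variable triggered the drop. This reproduces redundancy
#' patterns where a derived measure becomes insignificant once a correlated
#' demographic enters.
#'
#' @param design Data frame containing all start and candidate columns
#'   (standardize first for comparable coefficients).
#' @param outcome Numeric outcome.
#' @param start_vars Character vector of starting variables (the three
#'   measures).
#' @param candidate_vars Character vector of candidate variables, disjoint
#'   from `start_vars`.
#' @param p_enter Entry threshold (p-value of the candidate's coefficient).
#' @param p_remove Removal threshold on current-variable p-values.
#' @param max_steps Hard cap on total add/drop actions.
#' @return A `mob_stepwise` object: the step trace (step, action, variable,
#'   p_value, r2, triggered_by) with attributes `final_vars` and
#'   `final_fit`.
#' @export
stepwise_regression <- function(design, outcome, start_vars, candidate_vars,
                                p_enter = 0.05, p_remove = 0.05,
                                max_steps = 100) {
  X <- as.data.frame(design)
  if (!all(start_vars %in% names(X)) || !all(candidate_vars %in% names(X))) {
    abort("invalid-input: start/candidate variables missing from design",
          class = "mobesity_invalid_config")
  }
  if (length(intersect(start_vars, candidate_vars)) > 0) {
    abort("invalid-input: candidates must be disjoint from start variables",
          class = "mobesity_invalid_config")
  }
  fit_on <- function(vars) {
    stats::lm(.outcome ~ ., data = cbind(.outcome = outcome,
                                         X[, vars, drop = FALSE]))
  }
  pvals_of <- function(fit) {
    ct <- summary(fit)$coefficients
    p <- ct[, 4]
    p[names(p) != "(Intercept)"]
  }
  r2_of <- function(fit) summary(fit)$r.squared

  current <- start_vars
  remaining <- candidate_vars
  trace <- list()
  step <- 0L
  fit <- fit_on(current)
  trace[[length(trace) + 1]] <- tibble::tibble(
    step = step, action = "start", variable = paste(current, collapse = "+"),
    p_value = NA_real_, r2 = r2_of(fit), triggered_by = NA_character_)

  repeat {
    if (step >= max_steps || length(remaining) == 0) break
    entry <- purrr::map_dfr(remaining, function(v) {
      f <- fit_on(c(current, v))
      ct <- summary(f)$coefficients
      p <- if (v %in% rownames(ct)) ct[v, 4] else NA_real_
      tibble::tibble(variable = v, p_value = p, r2 = r2_of(f))
    })
    entry <- dplyr::filter(entry, is.finite(.data$p_value))
    if (nrow(entry) == 0 || min(entry$p_value) >= p_enter) break
    best <- entry[which.min(entry$p_value), ]
    step <- step + 1L
    current <- c(current, best$variable)
    remaining <- setdiff(remaining, best$variable)
    fit <- fit_on(current)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, action = "add", variable = best$variable,
      p_value = best$p_value, r2 = r2_of(fit), triggered_by = NA_character_)
    last_added <- best$variable

    # Backward pass: drop anything (start measures included) that the new
    # entrant has rendered insignificant.
    repeat {
      p <- pvals_of(fit)
      p <- p[names(p) != last_added]
      if (length(p) == 0 || max(p) <= p_remove) break
      worst <- names(p)[which.max(p)]
      step <- step + 1L
      current <- setdiff(current, worst)
      fit <- fit_on(current)
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = step, action = "drop", variable = worst,
        p_value = max(p), r2 = r2_of(fit), triggered_by = last_added)
    }
  }
  out <- dplyr::bind_rows(trace)
  structure(out, class = c("mob_stepwise", class(out)),
            final_vars = current, final_fit = fit)
}

#' @describeIn stepwise_regression The step trace as a tibble.
#' @param x A `mob_stepwise`.
#' @param ... Unused.
#' @export
tidy.mob_stepwise <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mob_stepwise <- function(x, ...) {
  sm <- summary(attr(x, "final_fit"))
  tibble::tibble(n_steps = max(x$step), n_final = length(attr(x, "final_vars")),
                 r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared)
}

#' @export
autoplot.mob_stepwise <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$r2)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(color = .data$action), size = 2) +
    ggplot2::labs(title = "Stepwise regression trace", x = "step",
                  y = expression(R^2), color = NULL) +
    ggplot2::theme_minimal()
}
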