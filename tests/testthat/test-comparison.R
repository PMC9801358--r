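test_that("tract filtering applies both exclusion rules with a strict threshold", {
  tr <- tibble::tibble(tract_id = c("a", "b", "c", "d"),
                       population = c(40L, 60L, 50L, 5000L),
                       obesity_prevalence = c(20, NA, 25, 30))
  suppressMessages({
    kept <- filter_tracts(tr)
  })
  # population exactly 50 is retained ("fewer than 50" is strict)
  expect_equal(kept$tract_id, c("c", "d"))
  exc <- attr(kept, "exclusions")
  expect_equal(exc$n_excluded, 2L)
  expect_equal(exc$pct_excluded, 50)
  # one row failing each rule leaves an empty analysis
  both <- tibble::tibble(tract_id = c("a", "b"), population = c(40L, 60L),
                         obesity_prevalence = c(20, NA))
  expect_error(suppressMessages(filter_tracts(both)),
               class = "mobesity_empty_analysis")
  # no exclusions: identity with zero counts
  clean <- tibble::tibble(tract_id = "z", population = 100L,
                          obesity_prevalence = 25)
  suppressMessages(kept2 <- filter_tracts(clean))
  expect_equal(attr(kept2, "exclusions")$n_excluded, 0L)
  expect_equal(nrow(kept2), 1L)
})

test_that("cross-validation partitions indices exactly once and is seeded", {
  n <- 103
  d <- withr::with_seed(1, tibble::tibble(a = rnorm(n)))
  yv <- d$a + withr::with_seed(2, rnorm(n))
  cv <- cross_validate("ols", d, yv, k = 10, seed = 5)
  folds <- attr(cv, "folds")
  expect_length(folds, n)
  expect_setequal(unique(folds), 1:10)
  expect_identical(cv$r2, cross_validate("ols", d, yv, k = 10, seed = 5)$r2)
  expect_error(cross_validate("ols", d, yv, k = n + 1),
               class = "mobesity_invalid_config")
})

test_that("pooled CV R2 matches the theoretical signal share", {
  # Var(X beta) = 3 sigma^2  =>  R2 = 0.75
  n <- 5000
  withr::with_seed(3, {
    X <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    yv <- X$x1 + X$x2 + X$x3 + rnorm(n)
  })
  cv <- cross_validate("ols", X, yv, k = 10, seed = 4)
  expect_equal(cv$r2, 0.75, tolerance = 0.05)
})

test_that("importance aggregation averages folds and preserves normalization", {
  one <- tibble::tibble(variable = c("a", "b"), importance = c(0.7, 0.3))
  agg <- aggregate_importance(list(one, one, one))
  expect_equal(agg$mean_importance, c(0.7, 0.3))
  expect_equal(agg$rank, 1:2)
  two <- tibble::tibble(variable = c("a", "b"), importance = c(0.5, 0.5))
  agg2 <- aggregate_importance(list(one, two))
  expect_equal(sum(agg2$mean_importance), 1, tolerance = 1e-9)
  bad <- tibble::tibble(variable = c("a", "z"), importance = c(0.5, 0.5))
  expect_error(aggregate_importance(list(one, bad)),
               class = "mobesity_invalid_config")
})

test_that("CV random forests surface the informative feature across folds", {
  n <- 400
  withr::with_seed(5, {
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(X) <- c("signal", paste0("noise", 1:3))
    yv <- 1.5 * X$signal + rnorm(n)
  })
  cv <- cross_validate("rf", X, yv, k = 10, seed = 6,
                       spec = list(n_trees = 100))
  agg <- aggregate_importance(attr(cv, "fold_importances"))
  expect_equal(agg$variable[1], "signal")
  expect_equal(sum(agg$mean_importance), 1, tolerance = 1e-9)
})

test_that("adding coupled visit measures lifts OLS R2; the report keeps conventions", {
  cfg <- sim_config(n_tracts = 400, seed = 42, behavior_share = 0.2,
                    small_tract_rate = 0, missing_rate = 0)
  st <- sim_study(cfg)
  suppressMessages({
    comp <- compare_models(st$tracts, st$measures, models = c("ols", "rf"),
                           k = 5, seed = 1, specs = list(rf = list(n_trees = 100)))
  })
  df <- tibble::as_tibble(comp)
  r2 <- function(m, s) df$r2[df$model == m & df$set == s]
  expect_gt(r2("ols", "test"), r2("ols", "baseline"))
  # Table-3 conventions: statistical models in-sample with AIC/adjusted R2,
  # ML models from CV without them
  expect_true(all(df$source[df$model == "ols"] == "in_sample"))
  expect_true(all(df$source[df$model == "rf"] == "cv"))
  expect_true(all(is.na(df$aic[df$model == "rf"])))
  expect_true(all(!is.na(df$aic[df$model == "ols"])))
  expect_equal(nrow(df), 4)
  # flags derive from stored metrics
  fl <- tidy(comp)
  expect_true(all(c("improved", "tie") %in% names(fl)))
})

test_that("a DNN failure on a tiny city is annotated, not fatal", {
  cfg <- sim_config(n_tracts = 77, seed = 8, small_tract_rate = 0,
                    missing_rate = 0)
  st <- sim_study(cfg)
  suppressMessages({
    comp <- compare_models(st$tracts, st$measures, models = c("ols", "dnn"),
                           k = 5, seed = 1)
  })
  df <- tibble::as_tibble(comp)
  dnn_rows <- df[df$model == "dnn", ]
  expect_true(all(is.na(dnn_rows$r2)))
  expect_true(all(grepl("sample-size", dnn_rows$note)))
  expect_true(all(!is.na(df$r2[df$model == "ols"])))
})

test_that("stepwise selection keeps true predictors and discards noise", {
  n <- 2000
  withr::with_seed(9, {
    X <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(X) <- c("m1", "m2", "m3", "A", paste0("noise", 1:5))
    yv <- 0.8 * X$m1 + 0.7 * X$A + rnorm(n)
  })
  sw <- stepwise_regression(X, yv, start_vars = c("m1", "m2", "m3"),
                            candidate_vars = names(X)[4:9])
  final <- attr(sw, "final_vars")
  expect_true(all(c("m1", "A") %in% final))
  expect_false(any(grepl("^noise", final)))
  # empty candidate list: the start model is the final model
  sw0 <- stepwise_regression(X, yv, start_vars = c("m1", "m2", "m3"),
                             candidate_vars = character(0))
  expect_equal(attr(sw0, "final_vars"), c("m1", "m2", "m3"))
  expect_equal(max(sw0$step), 0)
})

test_that("a redundant measure is dropped once its correlated demographic enters", {
  n <- 1500
  withr::with_seed(10, {
    B <- rnorm(n)
    m3 <- 0.9 * B + sqrt(1 - 0.81) * rnorm(n)   # noisy proxy of B
    X <- data.frame(m1 = rnorm(n), m3 = m3, B = B, other = rnorm(n))
    yv <- 0.8 * X$m1 + 1.0 * B + rnorm(n)
  })
  sw <- stepwise_regression(X, yv, start_vars = c("m1", "m3"),
                            candidate_vars = c("B", "other"))
  tr <- tibble::as_tibble(sw)
  drop_row <- tr[tr$action == "drop" & tr$variable == "m3", ]
  expect_equal(nrow(drop_row), 1)
  expect_equal(drop_row$triggered_by, "B")
  expect_false("m3" %in% attr(sw, "final_vars"))
  expect_true(all(c("m1", "B") %in% attr(sw, "final_vars")))
})

test_that("replaying the stepwise trace reproduces the final model", {
  n <- 800
  withr::with_seed(11, {
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    names(X) <- c("m1", "a", "b", "c", "d")
    yv <- X$m1 + 0.6 * X$a - 0.4 * X$b + rnorm(n)
  })
  sw <- stepwise_regression(X, yv, start_vars = "m1",
                            candidate_vars = c("a", "b", "c", "d"))
  tr <- tibble::as_tibble(sw)
  vars <- "m1"
  for (i in seq_len(nrow(tr))) {
    if (tr$action[i] == "add") vars <- c(vars, tr$variable[i])
    if (tr$action[i] == "drop") vars <- setdiff(vars, tr$variable[i])
  }
  expect_setequal(vars, attr(sw, "final_vars"))
  refit <- lm(yv ~ ., data = X[, attr(sw, "final_vars"), drop = FALSE])
  expect_equal(unname(coef(refit)), unname(coef(attr(sw, "final_fit"))),
               tolerance = 1e-12)
})
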