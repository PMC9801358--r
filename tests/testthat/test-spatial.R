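test_that("k-NN weights recover the obvious geometry and row-standardize", {
  co <- cbind(c(0, 1, 2), c(0, 0, 0))
  w <- knn_weights(co, k = 1)
  expect_equal(w$neighbors, list(2L, 1L, 2L))
  w4 <- knn_weights(matrix(runif(100), 50, 2), k = 4)
  expect_true(all(vapply(w4$weights, sum, numeric(1)) - 1 < 1e-9))
  expect_true(all(vapply(seq_along(w4$neighbors),
                         function(i) !(i %in% w4$neighbors[[i]]), logical(1))))
  expect_error(knn_weights(co, k = 3), class = "mobesity_invalid_config")
})

test_that("k-NN neighbor sets match a brute-force distance sort", {
  co <- withr::with_seed(8, matrix(runif(100), 50, 2))
  w <- knn_weights(co, k = 4)
  for (i in 1:50) {
    d <- sqrt(colSums((t(co) - co[i, ])^2))
    d[i] <- Inf
    expect_equal(w$neighbors[[i]], sort(order(d)[1:4]))
  }
})

test_that("Moran's I equals the double-sum formula and the ape oracle", {
  skip_if_not_installed("ape")
  co <- withr::with_seed(42, matrix(runif(100), 50, 2))
  w <- knn_weights(co, k = 4)
  x <- withr::with_seed(43, rnorm(50))
  m <- morans_i(x, w, n_permutations = 0)
  # explicit double sum
  W <- weights_matrix(w)
  z <- x - mean(x)
  num <- 0
  for (i in 1:50) for (j in 1:50) num <- num + W[i, j] * z[i] * z[j]
  I_ref <- (50 / sum(W)) * num / sum(z^2)
  expect_equal(m$statistic, I_ref, tolerance = 1e-10)
  expect_equal(m$expected, -1 / 49)
  a <- ape::Moran.I(x, W)
  expect_equal(m$statistic, a$observed, tolerance = 1e-10)
})

test_that("checkerboard field on rook weights gives exactly -1", {
  w <- rook_weights(6, 6)
  vals <- as.vector(outer(1:6, 1:6, function(r, c) (-1)^(r + c)))
  m <- morans_i(vals, w, n_permutations = 0)
  expect_equal(m$statistic, -1, tolerance = 1e-12)
})

test_that("an iid field sits inside its own permutation band", {
  co <- withr::with_seed(3, matrix(runif(200), 100, 2))
  w <- knn_weights(co, k = 5)
  x <- withr::with_seed(4, rnorm(100))
  m <- morans_i(x, w, n_permutations = 499, seed = 12)
  band <- quantile(m$permutations, c(0.025, 0.975))
  expect_gte(m$statistic, band[[1]])
  expect_lte(m$statistic, band[[2]])
  expect_gt(m$p_perm, 0.05)
  # permutation p reproducible under the same seed
  m2 <- morans_i(x, w, n_permutations = 499, seed = 12)
  expect_identical(m$p_perm, m2$p_perm)
  expect_error(morans_i(rep(1, 100), w), class = "mobesity_degenerate_input")
})

test_that("Moran's I is invariant to affine transforms of the values", {
  co <- withr::with_seed(5, matrix(runif(80), 40, 2))
  w <- knn_weights(co, k = 4)
  x <- withr::with_seed(6, rnorm(40))
  i1 <- morans_i(x, w, n_permutations = 0)$statistic
  i2 <- morans_i(3 * x - 17, w, n_permutations = 0)$statistic
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("standardization follows the sample-sd convention and inverts", {
  s <- standardize_columns(data.frame(a = c(1, 2, 3)))
  expect_equal(s$a, c(-1, 0, 1))
  d <- withr::with_seed(2, data.frame(u = rnorm(50, 5, 2), v = runif(50)))
  z <- standardize_columns(d)
  expect_true(all(abs(colMeans(as.matrix(z))) < 1e-12))
  expect_true(all(abs(apply(as.matrix(z), 2, sd) - 1) < 1e-12))
  back <- sweep(sweep(as.matrix(z), 2, attr(z, "scale"), "*"), 2,
                attr(z, "center"), "+")
  expect_true(max(abs(back - as.matrix(d))) <= 1e-10)
  expect_error(standardize_columns(data.frame(a = rep(2, 5))), "a",
               class = "mobesity_degenerate_input")
})

test_that("VIF is 1 for orthogonal columns, Inf for duplicates, and matches closed form", {
  # exactly orthogonal (to the intercept too) via QR
  Q <- qr.Q(qr(cbind(1, withr::with_seed(9, matrix(rnorm(200 * 4), 200, 4)))))
  X <- as.data.frame(Q[, 2:5]); names(X) <- paste0("q", 1:4)
  v <- vif(X)
  expect_true(all(abs(v$vif - 1) < 1e-8))
  # duplicated column: both infinite
  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  vd <- vif(dup)
  expect_true(all(is.infinite(vd$vif)))
  # exact pairwise correlation 0.9 => VIF = 1/(1 - 0.81)
  u <- Q[, 2]; w <- Q[, 3]
  X2 <- data.frame(x1 = u, x2 = 0.9 * u + sqrt(1 - 0.81) * w)
  v2 <- vif(X2)
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
})

test_that("VIF agrees with the auxiliary-regression oracle and is scale-invariant", {
  skip_if_not_installed("car")
  X <- withr::with_seed(10, {
    M <- as.data.frame(matrix(rnorm(500 * 6), 500, 6))
    names(M) <- paste0("v", 1:6)
    M$v2 <- 0.7 * M$v1 + 0.5 * M$v2
    M
  })
  mine <- vif(X)
  oracle <- car::vif(lm(y ~ ., data = cbind(y = rnorm(500), X)))
  expect_equal(setNames(mine$vif, mine$variable)[names(oracle)],
               oracle, tolerance = 1e-8)
  rescaled <- vif(dplyr::mutate(X, v1 = v1 * 1000, v4 = v4 / 77))
  expect_equal(dplyr::arrange(mine, variable)$vif,
               dplyr::arrange(rescaled, variable)$vif, tolerance = 1e-8)
})

test_that("VIF cascade removes compositional shares and terminates below cutoff", {
  n <- 300
  comp <- withr::with_seed(12, {
    l <- matrix(rnorm(n * 3, 0, 0.4), n, 3)
    e <- exp(l)
    100 * e / rowSums(e)
  })
  X <- data.frame(s1 = comp[, 1], s2 = comp[, 2], s3 = comp[, 3],
                  z1 = rnorm(n), z2 = rnorm(n))
  tr <- vif_cascade(X, cutoff = 5)
  expect_gte(length(tr$rounds), 1)
  expect_true(any(c("s1", "s2", "s3") %in%
                    vapply(tr$rounds, function(r) r$removed, character(1))))
  expect_lt(max(tr$final_vifs$vif), 5)
  # rounds strictly decrease the variable count
  sizes <- vapply(tr$rounds, function(r) nrow(r$vifs), integer(1))
  expect_true(all(diff(sizes) < 0) || length(sizes) == 1)
  # re-running vif on the retained set confirms the fixed point
  expect_lt(max(vif(X[, tr$retained])$vif), 5)

  clean <- withr::with_seed(13, as.data.frame(matrix(rnorm(200 * 3), 200, 3)))
  tr0 <- vif_cascade(clean)
  expect_length(tr0$rounds, 0)
  expect_equal(tr0$retained, names(clean))

  forced <- vif_cascade(X, forced_removals = c("z1", "s2"))
  expect_equal(vapply(forced$rounds[1:2], function(r) r$removed, character(1)),
               c("z1", "s2"))
})

test_that("correlations capture affine, monotone, and rank-oracle behavior", {
  x <- withr::with_seed(14, rnorm(100))
  aff <- correlations(x, 2 * x + 1)
  expect_equal(aff$pearson_r, 1, tolerance = 1e-12)
  expect_equal(aff$spearman_rho, 1, tolerance = 1e-12)
  mono <- correlations(x, exp(3 * x))
  expect_equal(mono$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(mono$pearson_r, 1)
  # spearman equals pearson of average ranks (with ties)
  y <- withr::with_seed(15, sample(1:10, 100, replace = TRUE))
  z <- withr::with_seed(16, rnorm(100))
  got <- correlations(as.numeric(y), z)
  expect_equal(got$spearman_rho,
               cor(rank(y, ties.method = "average"),
                   rank(z, ties.method = "average")),
               tolerance = 1e-12)
  expect_error(correlations(rep(1, 10), rnorm(10)),
               class = "mobesity_degenerate_input")
})
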