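test_that("tract generator honours counts, unique ids, and compositional education", {
  cfg <- sim_config(n_tracts = 77, seed = 1)
  tr <- sim_tracts(cfg)
  expect_equal(nrow(tr), 77)
  expect_equal(anyDuplicated(tr$tract_id), 0)
  edu <- rowSums(tr[, c("pct_no_highschool", "pct_highschool_no_univ",
                        "pct_university")])
  expect_true(all(abs(edu - 100) < 0.01))
  race <- as.matrix(tr[, c("pct_white", "pct_black", "pct_am_indian",
                           "pct_asian", "pct_pacific", "pct_hispanic")])
  expect_true(all(race >= 0 & race <= 100))
  expect_true(all(tr$device_count >= 1))
  # determinism: identical config => bit-identical table and latent factors
  tr2 <- sim_tracts(cfg)
  expect_identical(tr, tr2)
  expect_error(sim_config(n_tracts = 0), class = "mobesity_invalid_config")
})

test_that("poverty-related demographics are strongly correlated", {
  tr <- sim_tracts(sim_config(n_tracts = 2000, seed = 1))
  expect_gte(cor(tr$pct_below_poverty, tr$pct_food_stamp), 0.4)
  expect_gte(cor(tr$pct_below_poverty, tr$pct_unemployed), 0.4)
  expect_lte(cor(tr$pct_below_poverty, tr$median_income), -0.4)
})

test_that("POI generator respects counts, support, and seeding", {
  cfg <- sim_config(n_tracts = 10, grid_extent = 10,
                    n_pois_per_category = c(fast_food = 50, fitness = 30,
                                            nature_park = 20), seed = 2)
  po <- sim_pois(cfg)
  expect_equal(nrow(po), 100)
  expect_equal(unname(table(po$category)[c("fast_food", "fitness", "nature_park")]),
               c(50L, 30L, 20L), ignore_attr = TRUE)
  expect_true(all(po$x >= 0 & po$x <= 10 & po$y >= 0 & po$y <= 10))
  expect_identical(po, sim_pois(cfg))
  expect_error(sim_config(n_pois_per_category = c(fast_food = 0, fitness = 0,
                                                  nature_park = 0)),
               class = "mobesity_invalid_config")
  expect_error(sim_config(gravity_decay = -1), class = "mobesity_invalid_config")
})

test_that("gravity kernel draws more visitors to near POIs than far ones", {
  # One tract, one near and one far POI of the same category; the Monte-Carlo
  # mean over replicate draws must favor the near POI.
  totals <- c(near = 0, far = 0)
  for (s in 1:300) {
    cfg <- sim_config(n_tracts = 1, grid_extent = 20, seed = s,
                      n_pois_per_category = c(fast_food = 2, fitness = 0,
                                              nature_park = 0),
                      small_tract_rate = 0, missing_rate = 0)
    tr <- sim_tracts(cfg)
    po <- tibble::tibble(poi_id = c("near", "far"), category = "fast_food",
                         x = c(tr$x + 1, tr$x + 15), y = tr$y)
    v <- sim_visits(tr, po, cfg)
    for (r in seq_len(nrow(v))) {
      totals[v$poi_id[r]] <- totals[v$poi_id[r]] + v$true_count[r]
    }
  }
  expect_gt(totals["near"], totals["far"])
})

test_that("visit generation is seeded and category-closed", {
  cfg <- clean_config(n = 40, seed = 5,
                      n_pois_per_category = c(fast_food = 10, fitness = 5,
                                              nature_park = 0))
  tr <- sim_tracts(cfg)
  po <- sim_pois(cfg)
  v1 <- sim_visits(tr, po, cfg)
  v2 <- sim_visits(tr, po, cfg)
  expect_identical(v1, v2)
  expect_false("nature_park" %in% v1$category)
  expect_true(all(v1$true_count >= 1))
})

test_that("privacy censoring drops singletons, rounds 2-4 up to 4, keeps the rest", {
  rec <- tibble::tibble(tract_id = "t1", poi_id = sprintf("p%d", 1:5),
                        category = "fast_food", true_count = c(1L, 2L, 3L, 4L, 9L))
  cen <- censor_visits(rec)
  expect_equal(nrow(cen), 4)                       # singleton removed
  expect_false("p1" %in% cen$poi_id)
  expect_equal(cen$recorded_count, c(4L, 4L, 4L, 9L))
  expect_equal(cen$true_count, c(2L, 3L, 4L, 9L))
  # conservation: dropped records are exactly the count-1 records; surviving
  # counts are >= 4 or equal to truth
  cfg <- clean_config(n = 60, seed = 9)
  v <- sim_visits(sim_tracts(cfg), sim_pois(cfg), cfg)
  cen2 <- censor_visits(v)
  expect_equal(nrow(v) - nrow(cen2), sum(v$true_count == 1))
  expect_true(all(cen2$recorded_count >= 4 |
                    cen2$recorded_count == cen2$true_count))
  expect_error(censor_visits(tibble::tibble(true_count = 0L)),
               class = "mobesity_invalid_record")
})

test_that("outcome degenerates to an exact linear model when all noise is off", {
  cfg <- sim_config(n_tracts = 150, seed = 3, sar_rho = 0, noise_sd = 0,
                    spatial_coef_amplitude = 0, behavior_share = 0,
                    small_tract_rate = 0, missing_rate = 0)
  tr <- sim_obesity(sim_tracts(cfg), cfg)
  des <- standardize_columns(tr[, names(cfg$true_coefficients)])
  fit <- suppressWarnings(fit_ols(des, tr$obesity_prevalence))
  expect_gt(fit$metrics$r2, 1 - 1e-10)
  expect_true(all(tr$obesity_prevalence >= 0 & tr$obesity_prevalence <= 100))
})

test_that("outcome respects range, missingness, and stores ground truth", {
  cfg <- sim_config(n_tracts = 400, seed = 4, missing_rate = 0.05)
  tr <- sim_obesity(sim_tracts(cfg), cfg)
  prev <- tr$obesity_prevalence
  expect_true(all(prev >= 0 & prev <= 100, na.rm = TRUE))
  expect_gt(sum(is.na(prev)), 0)
  gt <- attr(tr, "ground_truth")
  expect_equal(gt$true_coefficients, cfg$true_coefficients)
  expect_error(sim_config(sar_rho = 1), class = "mobesity_invalid_config")
})

test_that("SAR outcome is positively autocorrelated versus its own permutation", {
  # With sar_rho > 0 and no spatially varying coefficients, Moran's I of the
  # outcome should exceed that of an iid shuffle in at least 95 of 100 seeds.
  wins <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_tracts = 64, seed = s, sar_rho = 0.6,
                      spatial_coef_amplitude = 0, small_tract_rate = 0,
                      missing_rate = 0)
    tr <- sim_obesity(sim_tracts(cfg), cfg)
    w <- knn_weights(tr, k = 6)
    i_obs <- morans_i(tr$obesity_prevalence, w, n_permutations = 0)$statistic
    shuffled <- withr::with_seed(s, sample(tr$obesity_prevalence))
    i_perm <- morans_i(shuffled, w, n_permutations = 0)$statistic
    if (i_obs > i_perm) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("default SAR strength yields Moran's I in the strongly positive band", {
  cfg <- sim_config(n_tracts = 900, seed = 1, sar_rho = 0.7,
                    small_tract_rate = 0, missing_rate = 0)
  tr <- sim_obesity(sim_tracts(cfg), cfg)
  i <- morans_i(tr$obesity_prevalence, knn_weights(tr, k = 8),
                n_permutations = 0)$statistic
  expect_gte(i, 0.3)
  expect_lte(i, 0.9)
})
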