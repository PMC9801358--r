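# Synthetic study generator: tracts with collinear demographics, POIs,
# gravity-model visit counts with privacy censoring, and a spatially
# autocorrelated obesity outcome with known ground truth.

#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the data-generating process: the tract grid,
#' POI counts per category, the gravity kernel for visit intensity, the
#' privacy-censoring stand-in, and the outcome model (linear coefficients on
#' standardized covariates, optional spatially varying coefficient,
#' simultaneous-autoregressive error, and the share of outcome variance
#' carried by the latent behavior propensity that also drives visits).
#'
#' @param n_tracts Number of census tracts (jittered-grid centroids).
#' @param grid_extent Side length of the square study area, in km-like
#'   planar units.
#' @param n_pois_per_category Named integer vector giving the number of
#'   points of interest for `fast_food`, `fitness`, and `nature_park`.
#' @param gravity_decay Positive distance-decay exponent of the visit
#'   gravity kernel `(1 + d)^-gravity_decay`.
#' @param mean_devices_per_tract Mean resident device-panel size for an
#'   average-population tract.
#' @param true_coefficients Named numeric vector of outcome coefficients on
#'   the standardized covariate scale; names must be generated variables.
#' @param spatial_coef_amplitude Amplitude of the spatially varying component
#'   added to the first coefficient (0 disables spatial heterogeneity in the
#'   coefficients).
#' @param sar_rho Simultaneous-autoregressive parameter of the outcome error,
#'   strictly inside (-1, 1); positive values induce positive spatial
#'   autocorrelation of the kind observed in tract-level obesity prevalence.
#' @param noise_sd Standard deviation of the SAR innovations; an additional
#'   iid component with sd `noise_sd / 2` is added on top.
#' @param behavior_share Share of outcome variance contributed by the latent
#'   visit-behavior propensity (0 decouples visits from the outcome).
#' @param visit_rate Baseline per-device visit intensity before distance
#'   decay.
#' @param nb_dispersion Negative-binomial size parameter of the visit counts
#'   (smaller = more overdispersed).
#' @param knn_k Number of nearest neighbors used for the SAR weights.
#' @param small_tract_rate Fraction of tracts given a population below 50,
#'   exercising the exclusion rule.
#' @param missing_rate Fraction of tracts whose obesity prevalence is
#'   recorded as missing.
#' @param impute_alpha Power-law exponent used when imputing censored counts.
#' @param seed Integer master seed; every stage derives its own stream.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_tracts = 100, seed = 1)
#' tr <- sim_tracts(cfg)
sim_config <- function(n_tracts = 900,
                       grid_extent = 30,
                       n_pois_per_category = c(fast_food = 60, fitness = 40,
                                               nature_park = 25),
                       gravity_decay = 1.5,
                       mean_devices_per_tract = 200,
                       true_coefficients = c(pct_black = 1.2,
                                             median_income = -0.9,
                                             pct_below_poverty = 1.0,
                                             pct_no_highschool = 0.5,
                                             pct_age_18_29 = -0.5,
                                             pop_density = -0.4),
                       spatial_coef_amplitude = 0,
                       sar_rho = 0.7,
                       noise_sd = 1,
                       behavior_share = 0.15,
                       visit_rate = 0.35,
                       nb_dispersion = 1.2,
                       knn_k = 8,
                       small_tract_rate = 0.02,
                       missing_rate = 0.02,
                       impute_alpha = 2,
                       seed = 1L) {
  assert_positive_int(n_tracts, "n_tracts")
  if (!is.numeric(grid_extent) || grid_extent <= 0) {
    abort("invalid-config: `grid_extent` must be positive",
          class = "mobesity_invalid_config")
  }
  if (is.null(names(n_pois_per_category)) ||
      !all(names(n_pois_per_category) %in% poi_categories())) {
    abort("invalid-config: `n_pois_per_category` must be named with POI categories",
          class = "mobesity_invalid_config")
  }
  if (any(n_pois_per_category < 0) || sum(n_pois_per_category) < 1) {
    abort("invalid-config: at least one POI is required",
          class = "mobesity_invalid_config")
  }
  if (!is.numeric(gravity_decay) || gravity_decay <= 0) {
    abort("invalid-config: `gravity_decay` must be positive",
          class = "mobesity_invalid_config")
  }
  if (abs(sar_rho) >= 1) {
    abort("invalid-config: `sar_rho` must lie strictly inside (-1, 1)",
          class = "mobesity_invalid_config")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("invalid-config: `noise_sd` must be nonnegative",
          class = "mobesity_invalid_config")
  }
  if (behavior_share < 0 || behavior_share >= 1) {
    abort("invalid-config: `behavior_share` must lie in [0, 1)",
          class = "mobesity_invalid_config")
  }
  known <- c(demographic_variables(), visit_measure_variables())
  bad <- setdiff(names(true_coefficients), known)
  if (length(bad) > 0) {
    abort(sprintf("invalid-config: unknown variable(s) in `true_coefficients`: %s",
                  paste(bad, collapse = ", ")),
          class = "mobesity_invalid_config")
  }
  assert_positive_int(knn_k, "knn_k")
  structure(
    list(n_tracts = as.integer(n_tracts), grid_extent = grid_extent,
         n_pois_per_category = n_pois_per_category,
         gravity_decay = gravity_decay,
         mean_devices_per_tract = mean_devices_per_tract,
         true_coefficients = true_coefficients,
         spatial_coef_amplitude = spatial_coef_amplitude,
         sar_rho = sar_rho, noise_sd = noise_sd,
         behavior_share = behavior_share, visit_rate = visit_rate,
         nb_dispersion = nb_dispersion, knn_k = as.integer(knn_k),
         small_tract_rate = small_tract_rate, missing_rate = missing_rate,
         impute_alpha = impute_alpha, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate census tracts with collinear demographic structure
#'
#' Places `n_tracts` centroids on a jittered grid and draws the 24
#' demographic covariates from a latent deprivation factor so that the
#' generated table reproduces the collinearity patterns of real ACS-style
#' data: the three education shares are exactly compositional (they sum to
#' 100), and the poverty-related variables (poverty rate, food-assistance
#' rate, unemployment, income) are strongly mutually correlated. A latent
#' visit-behavior propensity per POI category is attached as the
#' `"latent"` attribute; it later drives both visit intensities and,
#' optionally, the outcome.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per tract: `tract_id`, centroid `x`/`y`,
#'   `population`, `device_count`, the 24 demographic columns, and an
#'   `obesity_prevalence` column initialized to `NA` (filled by
#'   [sim_obesity()]).
#' @export
sim_tracts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tracts
  extent <- config$grid_extent
  withr::with_seed(derive_seed(config$seed, 1L), {
    side <- ceiling(sqrt(n))
    cell <- extent / side
    idx <- seq_len(n) - 1L
    gx <- (idx %% side + 0.5) * cell
    gy <- (idx %/% side + 0.5) * cell
    x <- gx + runif(n, -0.35, 0.35) * cell
    y <- gy + runif(n, -0.35, 0.35) * cell

    # Latent deprivation factor: spatially smooth plus idiosyncratic noise.
    f_s <- random_surface(x, y, extent)
    f <- zstd(0.8 * f_s + 0.6 * rnorm(n))
    f2 <- zstd(0.7 * random_surface(x, y, extent) + 0.7 * rnorm(n))

    # Race/ethnicity shares via softmax (white/black/asian/am-indian/pacific
    # plus an implicit remainder category), loaded on deprivation.
    lr <- cbind(white = 1.2 - 0.9 * f + rnorm(n, 0, 0.35),
                black = 0.2 + 1.0 * f + rnorm(n, 0, 0.35),
                asian = -0.6 - 0.3 * f + rnorm(n, 0, 0.45),
                am_indian = -3.4 + rnorm(n, 0, 0.3),
                pacific = -4.6 + rnorm(n, 0, 0.3),
                other = -1.3 + rnorm(n, 0, 0.3))
    er <- exp(lr)
    race <- 100 * er / rowSums(er)

    # Education: an exactly compositional triplet (sums to 100).
    le <- cbind(no_hs = -0.35 + 0.9 * f + rnorm(n, 0, 0.3),
                hs = 0.4 + rnorm(n, 0, 0.2),
                univ = 0.35 - 0.9 * f + rnorm(n, 0, 0.3))
    ee <- exp(le)
    edu <- 100 * ee / rowSums(ee)

    tracts <- tibble::tibble(
      tract_id = sprintf("t%05d", seq_len(n)),
      x = x, y = y,
      population = as.integer(round(exp(rnorm(n, log(4200), 0.35)))),
      pct_white = race[, "white"], pct_black = race[, "black"],
      pct_am_indian = race[, "am_indian"], pct_asian = race[, "asian"],
      pct_pacific = race[, "pacific"],
      pct_hispanic = 100 * stats::plogis(-1.1 + 0.6 * f + rnorm(n, 0, 0.7)),
      pct_male = clamp(rnorm(n, 49.3, 1.6), 30, 70),
      pct_married = clamp(48 - 6 * f + rnorm(n, 0, 5), 5, 90),
      pct_age_18_29 = clamp(rnorm(n, 20, 3), 2, 60),
      pct_age_30_39 = clamp(rnorm(n, 17, 2.5), 2, 50),
      pct_age_40_49 = clamp(rnorm(n, 15, 2.2), 2, 50),
      pct_age_50_59 = clamp(rnorm(n, 14, 2.2), 2, 50),
      pct_age_60_plus = clamp(rnorm(n, 26, 4), 2, 70),
      pct_no_highschool = edu[, "no_hs"],
      pct_highschool_no_univ = edu[, "hs"],
      pct_university = edu[, "univ"],
      median_income = round(exp(log(65000) - 0.35 * f + rnorm(n, 0, 0.18))),
      pct_unemployed = clamp(5.5 + 2.8 * f + rnorm(n, 0, 1.5), 0, 40),
      pct_below_poverty = clamp(16 + 9 * f + rnorm(n, 0, 4), 0, 80),
      pct_food_stamp = clamp(13 + 8.5 * f + rnorm(n, 0, 4), 0, 80),
      median_home_value = round(exp(log(280000) - 0.4 * f + rnorm(n, 0, 0.25))),
      median_year_built = round(clamp(rnorm(n, 1962, 12), 1900, 2020)),
      pct_renter_occupied = clamp(42 + 9 * f + rnorm(n, 0, 10), 0, 100),
      pop_density = round(exp(log(2500) + 0.35 * f2 + rnorm(n, 0, 0.5))),
      obesity_prevalence = NA_real_
    )

    # A few near-empty tracts so the population exclusion rule has work to do.
    small <- runif(n) < config$small_tract_rate
    tracts$population[small] <- as.integer(sample(0:49, sum(small), replace = TRUE))

    tracts$device_count <- pmax(
      1L, rpois(n, config$mean_devices_per_tract * tracts$population / 4200))

    latent <- tibble::tibble(
      tract_id = tracts$tract_id,
      deprivation = f,
      prop_fast_food = 0.8 * f + 0.6 * rnorm(n),
      prop_fitness = -0.8 * f + 0.6 * rnorm(n),
      prop_nature_park = -0.5 * f + 0.8 * rnorm(n)
    )
    attr(tracts, "latent") <- latent
    tracts
  })
}

#' Simulate points of interest
#'
#' Draws the requested number of POIs per category uniformly over the study
#' square.
#'
#' @param config A [sim_config()].
#' @return A tibble: `poi_id`, `category`, `x`, `y`.
#' @export
sim_pois <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$n_pois_per_category
  if (sum(counts) < 1) {
    abort("invalid-config: zero total POIs", class = "mobesity_invalid_config")
  }
  withr::with_seed(derive_seed(config$seed, 2L), {
    purrr::imap_dfr(as.list(counts), function(m, cat) {
      if (m == 0) return(tibble::tibble())
      tibble::tibble(
        poi_id = sprintf("%s_%03d", cat, seq_len(m)),
        category = cat,
        x = runif(m, 0, config$grid_extent),
        y = runif(m, 0, config$grid_extent))
    })
  })
}

#' Simulate true (uncensored) tract-to-POI visitor counts
#'
#' For every tract/POI pair, draws a negative-binomial visitor count whose
#' mean follows a gravity kernel: the tract's device count times
#' `(1 + d)^-gravity_decay` in tract-POI distance, scaled by the tract's
#' latent behavior propensity for the POI's category. Zero-count pairs are
#' omitted, mirroring how visit panels only record observed flows.
#'
#' @param tracts Tract table from [sim_tracts()] (must carry the `"latent"`
#'   attribute).
#' @param pois POI table from [sim_pois()].
#' @param config A [sim_config()].
#' @return A tibble of true-count visit records: `tract_id`, `poi_id`,
#'   `category`, `true_count` (all >= 1).
#' @export
sim_visits <- function(tracts, pois, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(tracts) == 0 || nrow(pois) == 0) {
    abort("invalid-input: tracts and pois must be non-empty",
          class = "mobesity_invalid_config")
  }
  latent <- attr(tracts, "latent")
  if (is.null(latent)) {
    abort("tracts table lacks the 'latent' attribute; use sim_tracts()",
          class = "mobesity_invalid_config")
  }
  withr::with_seed(derive_seed(config$seed, 3L), {
    d <- cross_dist(cbind(tracts$x, tracts$y), cbind(pois$x, pois$y))
    decay <- (1 + d)^(-config$gravity_decay)
    prop <- cbind(fast_food = latent$prop_fast_food,
                  fitness = latent$prop_fitness,
                  nature_park = latent$prop_nature_park)
    boost <- exp(prop[, pois$category, drop = FALSE])
    mu <- config$visit_rate * tracts$device_count * decay * boost
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = config$nb_dispersion),
      nrow = nrow(tracts))
    keep <- which(counts > 0, arr.ind = TRUE)
    tibble::tibble(
      tract_id = tracts$tract_id[keep[, 1]],
      poi_id = pois$poi_id[keep[, 2]],
      category = pois$category[keep[, 2]],
      true_count = as.integer(counts[keep])) |>
      dplyr::arrange(.data$tract_id, .data$poi_id)
  })
}

#' Apply SafeGraph-style privacy censoring to true visit counts
#'
#' Records with a single visitor are removed outright; counts of 2-4 are
#' recorded as 4; larger counts pass through unchanged. The true count is
#' retained in a separate column for validation only.
#'
#' @param records True-count visit records from [sim_visits()].
#' @return A tibble of recorded (censored) visit records: `tract_id`,
#'   `poi_id`, `category`, `recorded_count`, `true_count`.
#' @export
#' @examples
#' rec <- tibble::tibble(tract_id = "t1", poi_id = "ff_1",
#'                       category = "fast_food", true_count = c(1L, 3L, 9L))
#' censor_visits(rec)  # first record dropped, 3 -> 4, 9 -> 9
censor_visits <- function(records) {
  if (nrow(records) > 0 && any(records$true_count < 1)) {
    abort("invalid-record: true visit counts must be >= 1",
          class = "mobesity_invalid_record")
  }
  records |>
    dplyr::filter(.data$true_count >= 2) |>
    dplyr::mutate(recorded_count = ifelse(.data$true_count <= 4L, 4L,
                                          .data$true_count),
                  recorded_count = as.integer(.data$recorded_count)) |>
    dplyr::relocate("recorded_count", .before = "true_count")
}

#' Fill in the simulated obesity outcome
#'
#' The outcome is a linear predictor on standardized covariates (with
#' coefficients from `config$true_coefficients`, the first of which may vary
#' smoothly over space with amplitude `spatial_coef_amplitude`), plus a
#' simultaneous-autoregressive error on row-standardized k-nearest-neighbor
#' weights, plus iid noise, plus (when `behavior_share > 0`) the latent
#' visit-behavior composite scaled to the requested share of variance. The
#' result is affinely mapped to a prevalence-like scale (mean 30, sd 7,
#' clamped to the 0-100 percentage range) and a fraction of tracts is set
#' missing.
#'
#' @param tracts Tract table from [sim_tracts()].
#' @param config A [sim_config()].
#' @param measures Optional visit-measures table; when supplied, any
#'   `true_coefficients` entries naming visit-frequency columns load on it.
#' @return The tract table with `obesity_prevalence` filled and a
#'   `"ground_truth"` attribute (true coefficients, spatially varying
#'   coefficient surface, SAR parameters, behavior composite).
#' @export
sim_obesity <- function(tracts, config, measures = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(config$sar_rho) >= 1) {
    abort("invalid-config: |sar_rho| must be < 1",
          class = "mobesity_invalid_config")
  }
  n <- nrow(tracts)
  beta <- config$true_coefficients
  design <- tracts
  if (!is.null(measures)) {
    design <- dplyr::left_join(design, measures, by = "tract_id")
  }
  missing_vars <- setdiff(names(beta), names(design))
  if (length(missing_vars) > 0) {
    abort(sprintf("invalid-config: coefficient variable(s) not in design: %s",
                  paste(missing_vars, collapse = ", ")),
          class = "mobesity_invalid_config")
  }
  withr::with_seed(derive_seed(config$seed, 4L), {
    Xs <- vapply(names(beta), function(v) zstd(design[[v]]), numeric(n))
    lp <- as.vector(Xs %*% beta)
    surf <- zstd(tracts$x)  # smooth east-west gradient for varying coefficients
    if (config$spatial_coef_amplitude > 0 && length(beta) > 0) {
      lp <- lp + config$spatial_coef_amplitude * surf * Xs[, 1]
    }

    u <- rnorm(n, 0, config$noise_sd)
    if (config$sar_rho != 0 && n > config$knn_k) {
      W <- weights_matrix(knn_weights(tracts, k = config$knn_k))
      e_sar <- solve(diag(n) - config$sar_rho * W, u)
    } else {
      e_sar <- u
    }
    eps <- rnorm(n, 0, config$noise_sd / 2)
    base <- lp + e_sar + eps

    latent <- attr(tracts, "latent")
    comp <- NULL
    lambda <- 0
    if (config$behavior_share > 0) {
      if (is.null(latent)) {
        abort("behavior coupling requires the 'latent' attribute from sim_tracts()",
              class = "mobesity_invalid_config")
      }
      comp <- zstd(latent$prop_fast_food - latent$prop_fitness -
                     0.5 * latent$prop_nature_park)
      s <- config$behavior_share
      base_sd <- stats::sd(base)
      if (base_sd == 0) base_sd <- 1
      lambda <- base_sd * sqrt(s / (1 - s))
      base <- base + lambda * comp
    }

    s_base <- stats::sd(base)
    z <- if (s_base > 0) (base - mean(base)) / s_base else base
    prev <- clamp(30 + 7 * z, 0, 100)

    out <- tracts
    out$obesity_prevalence <- prev
    if (config$missing_rate > 0) {
      miss <- runif(n) < config$missing_rate
      out$obesity_prevalence[miss] <- NA_real_
    }
    attr(out, "latent") <- latent
    attr(out, "ground_truth") <- list(
      true_coefficients = beta,
      coefficient_surface = surf,
      spatial_coef_amplitude = config$spatial_coef_amplitude,
      sar_rho = config$sar_rho,
      behavior_share = config$behavior_share,
      behavior_lambda = lambda,
      behavior_composite = comp,
      linear_predictor = lp)
    out
  })
}

#' Run the whole synthetic study
#'
#' Convenience wrapper chaining tract, POI, visit, censoring, outcome, and
#' visit-measure generation under one configuration.
#'
#' @param config A [sim_config()].
#' @return A list with elements `tracts` (outcome filled), `pois`,
#'   `visits_true`, `visits` (censored), `measures`, and `config`.
#' @export
sim_study <- function(config = sim_config()) {
  tracts <- sim_tracts(config)
  pois <- sim_pois(config)
  visits_true <- sim_visits(tracts, pois, config)
  visits <- censor_visits(visits_true)
  tracts <- sim_obesity(tracts, config)
  measures <- derive_visit_measures(visits, pois, tracts, impute = TRUE,
                                    alpha = config$impute_alpha,
                                    seed = derive_seed(config$seed, 5L))
  list(tracts = tracts, pois = pois, visits_true = visits_true,
       visits = visits, measures = measures, config = config)
}
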