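# Internal helpers shared across modules.

# Clamp to a closed interval.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Column-standardize a numeric vector; constant input maps to zeros.
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Euclidean distance matrix between two sets of planar points.
cross_dist <- function(a, b) {
  # a: n x 2, b: m x 2
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# A smooth random surface over [0, extent]^2, built from a few low-frequency
# cosine terms and standardized. Draws from the caller's RNG stream.
random_surface <- function(x, y, extent, n_terms = 6) {
  z <- numeric(length(x))
  for (t in seq_len(n_terms)) {
    a <- stats::rnorm(1)
    fx <- sample(0:2, 1)
    fy <- sample(0:2, 1)
    if (fx == 0 && fy == 0) fx <- 1
    ph <- stats::runif(2, 0, 2 * pi)
    z <- z + a * cos(2 * pi * fx * x / extent + ph[1]) *
      cos(2 * pi * fy * y / extent + ph[2])
  }
  zstd(z)
}

# Stable stage-specific seeds derived from one master seed, kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483647)
}

assert_positive_int <- function(x, name) {
  if (length(x) < 1 || any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    abort(sprintf("invalid-config: `%s` must be a positive integer", name),
          class = "mobesity_invalid_config")
  }
}

#' Names of the simulated socioeconomic and demographic variables
#'
#' The 24 tract-level covariates emulated by the synthetic generator, spanning
#' six groups: race/ethnicity, gender-marital-age structure, education
#' (a compositional triplet summing to 100), economic status, housing
#' condition, and urbanicity (population density).
#'
#' @return Character vector of 24 column names.
#' @export
demographic_variables <- function() {
  c("pct_white", "pct_black", "pct_am_indian", "pct_asian", "pct_pacific",
    "pct_hispanic",
    "pct_male", "pct_married", "pct_age_18_29", "pct_age_30_39",
    "pct_age_40_49", "pct_age_50_59", "pct_age_60_plus",
    "pct_no_highschool", "pct_highschool_no_univ", "pct_university",
    "median_income", "pct_unemployed", "pct_below_poverty", "pct_food_stamp",
    "median_home_value", "median_year_built", "pct_renter_occupied",
    "pop_density")
}

#' Names of the three derived visit-frequency measures
#'
#' @return Character vector: fast-food, fitness-center, and nature-park
#'   visit frequencies.
#' @export
visit_measure_variables <- function() {
  c("fast_food_vf", "fitness_vf", "nature_park_vf")
}

#' POI categories linked to diet and physical activity
#'
#' @return Character vector of the three place categories.
#' @export
poi_categories <- function() {
  c("fast_food", "fitness", "nature_park")
}
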