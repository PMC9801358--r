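# From the censored POI-centric visit panel to tract-centric diet and
# physical activity measures: impute censored counts, reverse the data focus
# from POIs to tracts, divide by resident device counts.

#' Impute privacy-censored visit counts
#'
#' A recorded count of 4 stands for a true count of 2, 3, or 4 under the
#' censoring rule. Each censored record is replaced by a draw from
#' `{2, 3, 4}` with probability proportional to `k^-alpha`, the power-law
#' form typical of human travel behavior. Counts above 4 are returned
#' unchanged. Draws come from the caller's RNG stream; wrap in
#' [withr::with_seed()] (or pass `seed` to [derive_visit_measures()]) for
#' reproducibility.
#'
#' @param recorded_count Integer vector of recorded counts, all >= 4.
#' @param alpha Nonnegative power-law exponent; `alpha = 0` gives the
#'   uniform distribution on `{2, 3, 4}`.
#' @return Integer vector of imputed counts.
#' @export
#' @examples
#' withr::with_seed(1, impute_visit_count(c(4L, 4L, 7L), alpha = 2))
impute_visit_count <- function(recorded_count, alpha = 2) {
  if (length(recorded_count) == 0) return(integer(0))
  if (any(recorded_count < 4)) {
    abort("invalid-record: censored counts below 4 cannot occur (2-3 are recorded as 4)",
          class = "mobesity_invalid_record")
  }
  if (!is.numeric(alpha) || alpha < 0) {
    abort("invalid-config: `alpha` must be nonnegative",
          class = "mobesity_invalid_config")
  }
  p <- censoring_pmf(alpha)
  out <- as.integer(recorded_count)
  at4 <- which(out == 4L)
  if (length(at4) > 0) {
    out[at4] <- sample(2:4, length(at4), replace = TRUE, prob = p)
  }
  out
}

# pmf on {2,3,4} proportional to k^-alpha.
censoring_pmf <- function(alpha) {
  w <- (2:4)^(-alpha)
  w / sum(w)
}

#' Aggregate visit records from POIs to tracts
#'
#' Reverses the panel's focus: for each tract and POI category, sums the
#' (optionally imputed) visitor counts over every POI of that category,
#' wherever the POI lies. Tracts present in `tracts` but absent from the
#' records receive 0 for all categories — under the data model, no recorded
#' visits is informative, not missing.
#'
#' @param records Censored visit records (`tract_id`, `poi_id`,
#'   `recorded_count`).
#' @param pois POI table resolving every `poi_id` to a category.
#' @param tracts Optional tract table; when given, all its tracts appear in
#'   the output.
#' @param impute Impute censored counts (recorded 4 -> draw from 2-4)?
#' @param alpha Power-law exponent for imputation.
#' @return A tibble in long form: `tract_id`, `category`, `total_visitors`.
#' @export
aggregate_visits <- function(records, pois, tracts = NULL, impute = TRUE,
                             alpha = 2) {
  dangling <- setdiff(unique(records$poi_id), pois$poi_id)
  if (length(dangling) > 0) {
    abort(sprintf("referential-integrity: unknown poi_id(s): %s",
                  paste(head(dangling, 5), collapse = ", ")),
          class = "mobesity_referential_error")
  }
  ids <- if (!is.null(tracts)) tracts$tract_id else unique(records$tract_id)
  recs <- records |>
    dplyr::arrange(.data$tract_id, .data$poi_id) |>
    dplyr::inner_join(dplyr::select(pois, "poi_id", poi_category = "category"),
                      by = "poi_id")
  count <- if (nrow(recs) == 0) {
    integer(0)
  } else if (impute) {
    impute_visit_count(recs$recorded_count, alpha = alpha)
  } else {
    recs$recorded_count
  }
  recs$count <- count
  totals <- recs |>
    dplyr::group_by(tract_id = .data$tract_id, category = .data$poi_category) |>
    dplyr::summarise(total_visitors = sum(.data$count), .groups = "drop")
  tidyr::expand_grid(tract_id = ids, category = poi_categories()) |>
    dplyr::left_join(totals, by = c("tract_id", "category")) |>
    dplyr::mutate(total_visitors = dplyr::coalesce(.data$total_visitors, 0L))
}

#' Place visit frequency per tract and category
#'
#' Divides each tract's total visitors per POI category by the tract's
#' resident device count: `vf_jc = sum_i V_ijc / S_j`. This is the measure
#' entering the obesity models for the three categories.
#'
#' @param totals Long-form totals from [aggregate_visits()].
#' @param tracts Tract table supplying `device_count` (all >= 1).
#' @return A tibble with one row per tract: `tract_id`, `fast_food_vf`,
#'   `fitness_vf`, `nature_park_vf`.
#' @export
#' @examples
#' totals <- tibble::tibble(tract_id = "t1",
#'                          category = c("fast_food", "fitness", "nature_park"),
#'                          total_visitors = c(30, 10, 0))
#' tracts <- tibble::tibble(tract_id = "t1", device_count = 100L)
#' visit_frequency(totals, tracts)
visit_frequency <- function(totals, tracts) {
  bad <- tracts$tract_id[tracts$device_count <= 0]
  if (length(bad) > 0) {
    abort(sprintf("division-contract: device_count <= 0 for tract(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mobesity_division_error")
  }
  totals |>
    dplyr::inner_join(dplyr::select(tracts, "tract_id", "device_count"),
                      by = "tract_id") |>
    dplyr::mutate(vf = .data$total_visitors / .data$device_count,
                  measure = paste0(.data$category, "_vf")) |>
    dplyr::select("tract_id", "measure", "vf") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "vf",
                       values_fill = 0) |>
    (\(d) {
      for (m in visit_measure_variables()) if (!m %in% names(d)) d[[m]] <- 0
      dplyr::select(d, "tract_id", dplyr::all_of(visit_measure_variables()))
    })() |>
    dplyr::arrange(.data$tract_id)
}

#' Derive the three visit-frequency measures from a censored panel
#'
#' End-to-end wrapper: impute censored counts, reverse-aggregate to tracts,
#' divide by device counts.
#'
#' @param visits Censored visit records.
#' @param pois POI table.
#' @param tracts Tract table (every tract receives a row, zero-filled when
#'   unvisited).
#' @param impute Impute censored counts?
#' @param alpha Power-law exponent for imputation.
#' @param seed Optional seed for the imputation draws; with `impute = FALSE`
#'   the computation is fully deterministic.
#' @return A [visit_frequency()] table.
#' @export
derive_visit_measures <- function(visits, pois, tracts, impute = TRUE,
                                  alpha = 2, seed = NULL) {
  run <- function() {
    aggregate_visits(visits, pois, tracts, impute = impute, alpha = alpha) |>
      visit_frequency(tracts)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
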