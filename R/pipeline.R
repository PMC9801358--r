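# Formats, configuration, and the end-to-end pipeline:
# simulate -> derive -> diagnose -> compare -> stepwise, with on-disk
# intermediates, structured logging, and byte-stable JSON reports.

tract_required_cols <- function() {
  c("tract_id", "x", "y", "population", "device_count", "obesity_prevalence")
}

#' Assemble a pipeline configuration
#'
#' @param sim A [sim_config()] for the synthetic stage.
#' @param derive List: `impute` flag and power-law `alpha` for censored-count
#'   imputation.
#' @param diagnose List: `knn` (spatial-weights neighbors), `cutoff` (VIF),
#'   `permutations` (Moran's I null).
#' @param models Character vector of model kinds for the comparison.
#' @param specs Named list of per-model hyperparameter lists.
#' @param comparison List: `k` folds, stepwise `p_enter` / `p_remove`,
#'   `min_population`.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            derive = list(impute = TRUE, alpha = 2),
                            diagnose = list(knn = 8, cutoff = 5,
                                            permutations = 999),
                            models = c("ols", "gwr", "rf", "dnn", "grf"),
                            specs = list(),
                            comparison = list(k = 10, p_enter = 0.05,
                                              p_remove = 0.05,
                                              min_population = 50),
                            seed = 1L) {
  structure(list(sim = sim, derive = derive, diagnose = diagnose,
                 models = models, specs = specs, comparison = comparison,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' holds [sim_config()] arguments. Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$n_pois_per_category)) {
    sim_args$n_pois_per_category <- unlist(sim_args$n_pois_per_category)
  }
  if (!is.null(sim_args$true_coefficients)) {
    sim_args$true_coefficients <- unlist(sim_args$true_coefficients)
  }
  args <- list(sim = do.call(sim_config, sim_args))
  for (key in c("derive", "diagnose", "models", "specs", "comparison", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(pipeline_config, args)
}

#' Read the three study tables from CSV
#'
#' Validates the documented schemas (header names) and referential
#' integrity: every visit record must resolve to a known tract and POI.
#'
#' @param tracts_path,pois_path,visits_path CSV paths as written by
#'   [write_study_tables()].
#' @return A list `tracts`, `pois`, `visits` of tibbles.
#' @export
read_study_tables <- function(tracts_path, pois_path, visits_path) {
  tracts <- readr::read_csv(tracts_path, show_col_types = FALSE)
  pois <- readr::read_csv(pois_path, show_col_types = FALSE)
  visits <- readr::read_csv(visits_path, show_col_types = FALSE)
  check_schema <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("schema: %s is missing column(s): %s", file,
                    paste(miss, collapse = ", ")),
            class = "mobesity_schema_error")
    }
  }
  check_schema(tracts, tract_required_cols(), basename(tracts_path))
  check_schema(pois, c("poi_id", "category", "x", "y"), basename(pois_path))
  check_schema(visits, c("tract_id", "poi_id", "recorded_count"),
               basename(visits_path))
  dangling_poi <- setdiff(unique(visits$poi_id), pois$poi_id)
  dangling_tract <- setdiff(unique(visits$tract_id), tracts$tract_id)
  if (length(dangling_poi) > 0 || length(dangling_tract) > 0) {
    abort(sprintf("referential-integrity: visits reference unknown id(s): %s",
                  paste(head(c(dangling_poi, dangling_tract), 5),
                        collapse = ", ")),
          class = "mobesity_referential_error")
  }
  list(tracts = tracts, pois = pois, visits = visits)
}

#' Write the study tables (and ground truth) to a directory
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tracts = file.path(dir, "tracts.csv"),
                pois = file.path(dir, "pois.csv"),
                visits = file.path(dir, "visits.csv"),
                ground_truth = file.path(dir, "ground_truth.json"))
  readr::write_csv(study$tracts, paths$tracts)
  readr::write_csv(study$pois, paths$pois)
  readr::write_csv(study$visits, paths$visits)
  gt <- attr(study$tracts, "ground_truth")
  cfg <- study$config
  jsonlite::write_json(
    list(config_hash = rlang::hash(cfg), seed = cfg$seed,
         n_tracts = cfg$n_tracts, sar_rho = cfg$sar_rho,
         noise_sd = cfg$noise_sd, behavior_share = cfg$behavior_share,
         gravity_decay = cfg$gravity_decay,
         spatial_coef_amplitude = cfg$spatial_coef_amplitude,
         true_coefficients = as.list(cfg$true_coefficients),
         behavior_lambda = gt$behavior_lambda),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# Optional GeoJSON Point export of tract centroids.
#' Write tract centroids as a GeoJSON point collection
#'
#' @param tracts Tract table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_centroids_geojson <- function(tracts, path) {
  features <- purrr::pmap(list(tracts$tract_id, tracts$x, tracts$y),
    function(id, x, y) {
      list(type = "Feature",
           properties = list(tract_id = id),
           geometry = list(type = "Point", coordinates = c(x, y)))
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

comparison_markdown <- function(comp) {
  df <- tibble::as_tibble(comp)
  lines <- c("| Model | Fit measure | Baseline | Test | Source |",
             "|---|---|---|---|---|")
  for (m in unique(df$model)) {
    sub <- df[df$model == m, ]
    for (metric in c("r2", "rmse", "adjusted_r2", "aic")) {
      b <- sub[[metric]][sub$set == "baseline"]
      t <- sub[[metric]][sub$set == "test"]
      if (all(is.na(c(b, t)))) next
      src <- stats::na.omit(sub$source)[1]
      lines <- c(lines, sprintf("| %s | %s | %.3f | %.3f | %s |",
                                m, metric, b, t, src))
    }
    if (all(is.na(sub$r2))) {
      lines <- c(lines, sprintf("| %s | — | failed | failed | %s |",
                                m, stats::na.omit(sub$note)[1]))
    }
  }
  paste(lines, collapse = "\n")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, derive, diagnose, compare,
#' stepwise — writing each stage's artifacts under `out_dir`. Stages whose
#' outputs already exist are skipped unless `force = TRUE`, so an
#' interrupted run resumes from its on-disk intermediates. Every JSON
#' artifact embeds the configuration hash and seed that produced it; the
#' log records seeds, exclusion counts, and cascade rounds.
#'
#' @param config A [pipeline_config()], or the path to a YAML file readable
#'   by [read_pipeline_config()].
#' @param out_dir Artifact directory.
#' @param force Recompute stages even when their outputs exist?
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   results (`comparison`, `moran`, `vif_trace`, `correlations`,
#'   `stepwise`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  seed <- config$seed
  p <- function(f) file.path(out_dir, f)

  # --- simulate ---------------------------------------------------------
  sim_files <- c(p("tracts.csv"), p("pois.csv"), p("visits.csv"))
  if (force || !all(file.exists(sim_files))) {
    stage_log("simulate", "generating synthetic study (n_tracts = %d, seed = %d)",
              config$sim$n_tracts, config$sim$seed)
    study <- sim_study(config$sim)
    write_study_tables(study, out_dir)
    tracts <- study$tracts; pois <- study$pois; visits <- study$visits
  } else {
    stage_log("simulate", "outputs exist; skipping (use force = TRUE to redo)")
    tabs <- read_study_tables(p("tracts.csv"), p("pois.csv"), p("visits.csv"))
    tracts <- tabs$tracts; pois <- tabs$pois; visits <- tabs$visits
  }

  # --- derive -----------------------------------------------------------
  if (force || !file.exists(p("measures.csv"))) {
    alpha <- config$derive$alpha %||% 2
    stage_log("derive", "deriving visit measures (impute = %s, alpha = %g, seed = %d)",
              isTRUE(config$derive$impute), alpha, derive_seed(seed, 5L))
    measures <- derive_visit_measures(visits, pois, tracts,
                                      impute = isTRUE(config$derive$impute),
                                      alpha = alpha,
                                      seed = derive_seed(seed, 5L))
    readr::write_csv(measures, p("measures.csv"))
  } else {
    stage_log("derive", "measures.csv exists; skipping")
    measures <- readr::read_csv(p("measures.csv"), show_col_types = FALSE)
  }

  # --- diagnose ---------------------------------------------------------
  min_pop <- config$comparison$min_population %||% 50
  kept <- filter_tracts(tracts, min_pop)
  exc <- attr(kept, "exclusions")
  stage_log("diagnose", "excluded %d tract(s) (%.1f%%); %d retained",
            exc$n_excluded, exc$pct_excluded, exc$n_retained)
  data <- dplyr::inner_join(kept, measures, by = "tract_id")

  knn <- config$diagnose$knn %||% 8
  perms <- config$diagnose$permutations %||% 999
  cutoff <- config$diagnose$cutoff %||% 5
  w <- knn_weights(data, k = knn)
  moran <- morans_i(data$obesity_prevalence, w, n_permutations = perms,
                    seed = derive_seed(seed, 6L))
  stage_log("diagnose", "Moran's I of prevalence: %.3f (perm p = %.4g, k = %d)",
            moran$statistic, moran$p_perm, knn)
  demo <- standardize_columns(data[, demographic_variables()])
  cascade <- vif_cascade(demo, cutoff = cutoff)
  stage_log("diagnose", "VIF cascade: %d round(s), %d variable(s) retained",
            length(cascade$rounds), length(cascade$retained))
  cors <- measure_outcome_correlations(data)

  if (force || !file.exists(p("moran.json"))) {
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = seed, knn = knn,
           n = moran$n, statistic = moran$statistic,
           expected = moran$expected, p_perm = moran$p_perm,
           p_norm = moran$p_norm, n_permutations = perms),
      p("moran.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = seed, cutoff = cutoff,
           rounds = lapply(cascade$rounds, function(r) {
             list(removed = r$removed,
                  vifs = setNames(as.list(r$vifs$vif), r$vifs$variable))
           }),
           retained = cascade$retained,
           final_vifs = setNames(as.list(cascade$final_vifs$vif),
                                 cascade$final_vifs$variable)),
      p("vif_trace.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(cors, p("correlations.csv"))
  }

  # --- compare ----------------------------------------------------------
  k <- config$comparison$k %||% 10
  if (force || !file.exists(p("comparison_report.json"))) {
    stage_log("compare", "running %s on baseline and test sets (k = %d, seed = %d)",
              paste(config$models, collapse = "/"), k, seed)
    comp <- compare_models(kept, measures, baseline_vars = cascade$retained,
                           models = config$models, k = k, seed = seed,
                           specs = config$specs, min_population = min_pop)
    rows <- tibble::as_tibble(comp)
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = seed, n = attr(comp, "n"), k = k,
           baseline_vars = attr(comp, "baseline_vars"),
           results = rows, flags = tidy(comp)),
      p("comparison_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(comparison_markdown(comp), p("comparison.md"))
  } else {
    stage_log("compare", "comparison_report.json exists; skipping")
    comp <- NULL
  }

  # --- stepwise ---------------------------------------------------------
  if (force || !file.exists(p("stepwise_trace.json"))) {
    all_vars <- c(visit_measure_variables(), cascade$retained)
    des <- standardize_columns(data[, all_vars])
    sw <- stepwise_regression(des, data$obesity_prevalence,
                              start_vars = visit_measure_variables(),
                              candidate_vars = cascade$retained,
                              p_enter = config$comparison$p_enter %||% 0.05,
                              p_remove = config$comparison$p_remove %||% 0.05)
    stage_log("stepwise", "%d step(s); final model keeps %d variable(s)",
              max(sw$step), length(attr(sw, "final_vars")))
    readr::write_csv(tibble::as_tibble(sw), p("stepwise_trace.csv"))
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = seed,
           trace = tibble::as_tibble(sw),
           final_vars = attr(sw, "final_vars")),
      p("stepwise_trace.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stage_log("stepwise", "stepwise_trace.json exists; skipping")
    sw <- NULL
  }

  invisible(list(
    paths = list(tracts = p("tracts.csv"), pois = p("pois.csv"),
                 visits = p("visits.csv"), measures = p("measures.csv"),
                 moran = p("moran.json"), vif_trace = p("vif_trace.json"),
                 correlations = p("correlations.csv"),
                 comparison = p("comparison_report.json"),
                 comparison_md = p("comparison.md"),
                 stepwise = p("stepwise_trace.json")),
    comparison = comp, moran = moran, vif_trace = cascade,
    correlations = cors, stepwise = sw))
}
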