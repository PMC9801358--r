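#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline:
#   Rscript scripts/pipeline.R run-all --config config.yaml --out run_dir
#   Rscript scripts/pipeline.R simulate --out run_dir --seed 1
# Stages (simulate, derive, diagnose, compare, stepwise) resume from on-disk
# intermediates; `run-all` executes everything.

suppressPackageStartupMessages({
  library(mobesity)
  library(optparse)
})

parser <- OptionParser(
  usage = "%prog [run-all|simulate] [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML pipeline configuration"),
    make_option("--out", type = "character", default = "mobesity_run",
                help = "artifact directory [default %default]"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the configured seed"),
    make_option("--force", action = "store_true", default = FALSE,
                help = "recompute stages whose outputs exist")
  ))
parsed <- parse_args(parser, positional_arguments = TRUE)
cmd <- if (length(parsed$args) >= 1) parsed$args[[1]] else "run-all"
opts <- parsed$options

cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config) else pipeline_config()
if (!is.null(opts$seed)) {
  cfg$seed <- opts$seed
  cfg$sim$seed <- opts$seed
}

if (cmd == "simulate") {
  study <- sim_study(cfg$sim)
  write_study_tables(study, opts$out)
  message(sprintf("wrote study tables for %d tracts to %s",
                  cfg$sim$n_tracts, opts$out))
} else if (cmd == "run-all") {
  run_pipeline(cfg, opts$out, force = opts$force)
} else {
  stop(sprintf("unknown command '%s'; use run-all or simulate", cmd))
}
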