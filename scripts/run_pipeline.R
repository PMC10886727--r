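#!/usr/bin/env Rscript
# Thin command-line wrapper over phaseconn::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R --config study.yaml [--out run_dir] [--seed 1]

suppressPackageStartupMessages({
  library(optparse)
  library(phaseconn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON pipeline configuration (optional)"),
  make_option("--out", type = "character", default = NULL,
              help = "run directory (overrides the config's out_dir)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides the config's sim seed)")
)))

config <- if (is.null(opts$config)) list() else opts$config
if (is.character(config)) {
  config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
            else jsonlite::read_json(config, simplifyVector = TRUE)
}
if (!is.null(opts$out)) config$out_dir <- opts$out
if (!is.null(opts$seed)) config$sim$seed <- opts$seed

res <- run_pipeline(config)
cat("run directory:", res$out_dir, "\n")
cat("stage outputs:", length(res$manifest$outputs), "\n")
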