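#!/usr/bin/env Rscript

# Thin shell wrapper over pitflux::run_pipeline(): simulate (or ingest) a
# recording, process it end to end, and write the stage tables.
#
# Usage:
#   Rscript scripts/run_pipeline.R --out runs/demo [--config cfg.yaml]
#     [--seed 1] [--compress-protocol 10]

suppressPackageStartupMessages({
  library(optparse)
  library(pitflux)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML config; absent keys resolve to package defaults"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--compress-protocol", type = "double", default = NULL,
              dest = "compress", help = "wash compression factor")
)))

config <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
if (!is.null(opts$seed)) config$seed <- opts$seed
if (!is.null(opts$compress)) config$protocol$compress <- opts$compress

run <- run_pipeline(config, out_dir = opts$out)
print(run)
message("outputs written to ", opts$out)
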