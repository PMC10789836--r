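#!/usr/bin/env Rscript
# Thin command-line wrapper over mealtrial::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--config <yaml>]
#                                  [--seed <int>] [--resume]

suppressPackageStartupMessages({
  library(optparse)
  library(mealtrial)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML file of simulation_config() overrides"),
  make_option("--out", type = "character", default = "pipeline-out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed"),
  make_option("--resume", action = "store_true", default = FALSE,
              help = "skip stages whose outputs already exist")
))
opt <- parse_args(parser)

config <- if (is.null(opt$config)) simulation_config() else
  load_config(opt$config)
manifest <- run_pipeline(config, out_dir = opt$out, seed = opt$seed,
                         resume = opt$resume)
cat(readLines(file.path(opt$out, "report.txt")), sep = "\n")
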