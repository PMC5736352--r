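#!/usr/bin/env Rscript

# Thin shell wrapper around floraltherm::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --out <dir> [--config <yaml>] [--seed <int>]

suppressPackageStartupMessages(library(floraltherm))

args <- commandArgs(trailingOnly = TRUE)
opts <- list(config = NULL, seed = NULL, out = NULL)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opts)) stop("unknown argument: ", args[i])
  opts[[key]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opts$out)) stop("--out <directory> is required")

cfg <- if (is.null(opts$config)) run_config() else read_run_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
cfg$outdir <- opts$out

res <- run_pipeline(cfg)
cat("pipeline complete; outputs:\n")
cat(paste(" ", res$files), sep = "\n")
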