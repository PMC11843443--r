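#!/usr/bin/env Rscript
# Thin command-line front end over subcellevo::run_pipeline().
#
#   Rscript scripts/pipeline.R [stages...] --outdir DIR [--seed INT]
#                              [--config FILE]
#
# Stages default to the full run: simulate age enrich pairs diverge ppi
# paralogs.

suppressPackageStartupMessages(library(subcellevo))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1]
}
flag_idx <- grep("^--", args)
drop <- unique(c(flag_idx, flag_idx + 1))
stages <- if (length(drop) > 0) args[-drop] else args
if (length(stages) == 0) {
  stages <- c("simulate", "age", "enrich", "pairs", "diverge", "ppi",
              "paralogs")
}

cfg <- default_run_config(
  seed = as.integer(get_arg("--seed", "1")),
  outdir = get_arg("--outdir", "subcellevo_run"))
cfg_file <- get_arg("--config", NA)
if (!is.na(cfg_file)) {
  overrides <- read_run_config(cfg_file)
  cfg[names(overrides)] <- overrides
}

res <- run_pipeline(cfg, stages = stages)
cat("pipeline finished; manifest at", res$manifest_path, "\n")
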