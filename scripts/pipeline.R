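#!/usr/bin/env Rscript
# Thin command-line wrapper over mguard::run_pipeline().
#   Rscript scripts/pipeline.R --config path/to/config.yaml [--out DIR] [--seed N]
# With no --config, the packaged demo configuration is used.

suppressMessages({
  library(optparse)
  library(mguard)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline configuration"),
  make_option("--out", type = "character", default = NULL,
              help = "override the output directory"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the RNG seed")
))
opt <- parse_args(parser)

cfg_path <- if (is.null(opt$config)) {
  system.file("extdata", "demo_config.yaml", package = "mguard")
} else opt$config
cfg <- yaml::read_yaml(cfg_path)
if (!is.null(opt$out)) cfg$out_dir <- opt$out
if (!is.null(opt$seed)) cfg$seed <- opt$seed

res <- run_pipeline(cfg)
message("pipeline complete; outputs in ", cfg$out_dir)
print(res$lrt_summary)
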