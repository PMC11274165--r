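#!/usr/bin/env Rscript
# Thin shell entry point over the package pipeline functions.
#
# Usage:
#   Rscript scripts/vedopkpd.R <simulate|analyze|fit-link|generate>
#       [--config PATH] [--seed INT] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(vedopkpd)
})

parser <- OptionParser(
  usage = "%prog <simulate|analyze|fit-link|generate> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML run configuration [default: packaged defaults]"),
    make_option("--seed", type = "integer", default = NULL,
                help = "seed override for cohort generation"),
    make_option("--out", type = "character", default = ".",
                help = "output directory [default: %default]")
  ))
parsed <- parse_args(parser, positional_arguments = 1)
cmd <- parsed$args
opt <- parsed$options

config <- read_run_config(opt$config)
status <- tryCatch({
  switch(cmd,
    "simulate" = cli_simulate(config, opt$out),
    "analyze" = cli_analyze(config, opt$out),
    "fit-link" = cli_fit_link(config, opt$out),
    "generate" = cli_generate(config, opt$out, seed = opt$seed),
    stop("unknown command: ", cmd))
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
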