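#!/usr/bin/env Rscript

## Thin shell entry point over nrfscope::runPipeline().
##
## Usage: Rscript scripts/run_pipeline.R --outdir DIR [--config config.yaml]

suppressPackageStartupMessages(library(nrfscope))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
outdir <- getArg("--outdir")
if (is.null(outdir)) stop("--outdir is required")
configPath <- getArg("--config")
config <- if (is.null(configPath)) {
    defaultPipelineConfig()
} else {
    readPipelineConfig(configPath)
}
out <- runPipeline(config, outdir)
cat("pipeline complete; manifest:", out$manifestPath, "\n")
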