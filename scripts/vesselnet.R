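#!/usr/bin/env Rscript
# Thin command-line wrapper over the vesselnet package.
#   Rscript scripts/vesselnet.R <subcommand> [--config FILE] [--seed INT] [--out DIR]
suppressMessages(library(vesselnet))
quit(status = cli_main(commandArgs(trailingOnly = TRUE)), save = "no")
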