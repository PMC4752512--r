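#!/usr/bin/env Rscript
# Stage 1: generate a synthetic study scenario.
#
# Emulates the inputs of the regulator-identification study: a PWM
# library standing in for an immune-cell TRANSFAC profile, -2000/+1000
# promoter windows with planted binding sites, a signed literature
# cascade downstream of LPS, and a two-condition expression matrix with
# planted DEGs. The planted ground truth (which TF regulates the target,
# which sites exist, which genes respond) is written alongside so later
# stages can be judged against it.

suppressPackageStartupMessages(library(grnctx))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

out <- file.path("results", "scenario")
sc <- gen_full_scenario(out_dir = out, seed = seed)

cat("Scenario written to", out, "\n")
cat("  TFs:", paste(names(sc$pwms), collapse = ", "), "\n")
cat("  planted regulator of", sc$config$target, ":",
    sc$truth$true_regulators, "\n")
cat("  planted sites:", nrow(sc$truth$planted_sites), "\n")
cat("  literature edges:", n_edges(sc$literature), "\n")
cat("  expression:", nrow(sc$expression$mat), "genes x",
    ncol(sc$expression$mat), "samples\n")
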