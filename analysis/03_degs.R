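#!/usr/bin/env Rscript
# Stage 3: differential expression and booleanization.
#
# Calls DEGs from the two-condition matrix with the logFC >= |1|,
# p < 0.01 rule (equal-variance two-sided t-test) and reports how the
# calls compare with the planted truth.

suppressPackageStartupMessages(library(grnctx))

dir <- file.path("results", "scenario")
sc <- load_scenario(dir)

lfc <- log_fold_change(sc$expression$mat, sc$expression$conditions)
p <- deg_test(sc$expression$mat, sc$expression$conditions)
degs <- call_degs(lfc, p)

write.table(degs, file.path("results", "degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("DEG calls:", sum(degs$call == "up"), "up,",
    sum(degs$call == "down"), "down of", nrow(degs), "genes\n")
truth <- unlist(sc$truth$deg_truth)
agree <- sum(degs$call == truth[degs$gene_id])
cat("Agreement with planted truth:", agree, "/", nrow(degs), "\n")
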