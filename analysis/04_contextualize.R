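#!/usr/bin/env Rscript
# Stage 4: merge and Boolean contextualization.
#
# Union-merges the unsigned upstream network with the signed literature
# cascade, booleanizes the DEG calls into control/stimulated phenotype
# constraints, and prunes/signs the merged network with the genetic
# algorithm so both phenotypes are stable steady states of the
# synchronous Boolean dynamics. Stimulus edges touching retained nodes
# are then re-attached from the literature network.

suppressPackageStartupMessages(library(grnctx))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dir <- file.path("results", "scenario")
sc <- load_scenario(dir)
upstream <- load_edge_list(file.path("results", "upstream.tsv"))
degs <- read.delim(file.path("results", "degs.tsv"))

merged <- merge_grn(upstream, sc$literature)
cat("Merged network:", length(merged$nodes), "nodes,", n_edges(merged),
    "edges (", n_edges(upstream), "+", n_edges(sc$literature),
    "with shared keys resolved )\n")

phen <- booleanize(degs, merged$nodes, sc$config$stimulus)
cat("Constraints:", length(phen$stimulated$state), "nodes per phenotype\n")

ctx <- contextualize_ga(merged, phen, sc$config$stimulus,
                        sc$config$target,
                        ga = list(pop = 60, generations = 80, seed = seed))
print(ctx)
final <- attach_stimulus_edges(ctx$grn, sc$literature, sc$config$stimulus)

write_edge_list(final, file.path("results", "contextualized.tsv"))
jsonlite::write_json(
  c(unclass(ctx$fitness),
    list(ga = list(pop = 60, generations = 80, seed = seed))),
  file.path("results", "fitness.json"), auto_unbox = TRUE, digits = NA)
cat("Contextualized network written:", length(final$nodes), "nodes,",
    n_edges(final), "edges\n")
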