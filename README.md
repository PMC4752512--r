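# grnctx: gene regulatory network contextualization and regulator ranking

`grnctx` identifies candidate transcriptional regulators of an inducible
gene under a stimulus — the motivating case is the itaconate-producing
gene *IRG1* (*ACOD1*) induced by LPS in macrophages — by rebuilding the
network-inference pipeline behind that discovery as reusable, tested R
code. It is aimed at systems biologists who want to run (or stress-test)
this class of analysis on their own promoter, interaction and expression
data, or on fully synthetic data with planted ground truth.

The pipeline has five stages:

1. **TFBS scan.** Promoter windows (−2000/+1000 around the TSS) are
   scanned with a PWM library using MATCH-style similarity scores. For a
   window *s* against a PWM with per-position frequencies *f(i,b)* and
   information vector *I(i) = Σ_b f(i,b)·ln(4 f(i,b))*, the matrix
   similarity is

   MSS = (Current − Min) / (Max − Min),  Current = Σ_i I(i)·f(i, s_i),

   with Min/Max the analogous sums over per-position extreme
   frequencies, and the core similarity (CSS) is the same score on the
   5-position maximal-information core. Sites with both scores ≥ 0.90
   become unsigned, directed TF → gene edges.
2. **Differential expression.** A two-condition matrix is reduced to DEG
   calls (logFC ≥ |1|, two-sided equal-variance t-test p < 0.01), then
   booleanized: up-genes are 0 in control / 1 stimulated, down-genes the
   reverse, unchanged genes unconstrained.
3. **Merge.** The unsigned upstream network and a signed literature
   network are union-merged per (source, target) key; known signs
   resolve unknown ones.
4. **Contextualization.** A genetic algorithm removes edges and assigns
   signs so that both booleanized phenotypes are stable steady states
   (fixed points) of a synchronous Boolean update — a node is active iff
   at least one activator and no inhibitor is active. Fitness is the
   satisfied-constraint fraction minus a parsimony penalty λ on removed
   edges.
5. **Ranking.** All simple paths stimulus → target are enumerated, and
   each gene *j* is scored with the essentiality metric

   EM_j = (N_TP − N_jP) / N_TP,

   the fraction of the N_TP paths that pass through *j* (N_jP = paths
   missing *j*). EM = 1 means removing the gene disconnects the stimulus
   from the target.

A synthetic-data module (`gen_full_scenario()` and friends) generates
every input with planted ground truth, so the whole pipeline is testable
without proprietary PWM libraries, curated interaction databases or
expression repositories.

## Worked example

The `analysis/` directory holds the pipeline as numbered driver scripts
(`Rscript analysis/01_simulate.R 1`, then `02_scan.R` … `05_rank.R`),
writing their tables under `results/`. The same run in a session:

```r
library(grnctx)
sc  <- gen_full_scenario(seed = 1)          # 6 TFs, planted regulator TF01
res <- run_pipeline(sc, ga = list(pop = 60, generations = 80, seed = 1))
res$contextualized
#> Contextualized GRN: 13 nodes, 12 edges; fitness 1.0000
#>   (18/18 constraints, 0 edge(s) removed)
res$ranking
#>   regulator total_paths paths_absent essentiality essentiality_exact rank
#> 1      TF01           1            0            1                  1    1
```

All 6 planted binding sites are recovered at the 0.90/0.90 threshold,
the 32-gene DEG calls match the planted truth exactly, the contextualized
network satisfies all 18 phenotype constraints without removing an edge,
and the planted regulator TF01 is ranked first with EM = 1: it lies on
every LPS → IRG1 path.

The essentiality module also reproduces the published worked examples
directly from their path counts, e.g. N_TP = 92 with N_jP = 14 gives
EM = 78/92 → 0.85 (the top-ranked mouse regulator, IRF1):

```r
essentiality(table_of_92_paths, "IRF1")$em_rounded
#> [1] 0.85
```

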