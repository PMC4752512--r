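---
title: "Methods: network contextualization and path-based regulator ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network contextualization and path-based regulator ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnctx)
```

# The problem

When a gene is strongly induced by a stimulus — the motivating case is
*IRG1*/*ACOD1*, the itaconate-producing enzyme switched on by LPS in
macrophages — the regulators that carry the signal from stimulus to gene
are usually not directly observable. `grnctx` triangulates them from
three heterogeneous evidence sources: sequence (which TFs *can* bind the
promoter), literature (which signed interactions are *known* downstream
of the stimulus) and expression (which genes actually *moved* in this
cell type under this stimulus). The first two produce a generous,
partly unsigned candidate network; the third is used to prune and sign
it; path analysis of the result ranks the candidates.

# Stage models and their assumptions

## PWM scanning

A PWM is a per-position base-frequency matrix. We score windows with
the information-vector-weighted min–max normalization: position weights
$I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))$ (0 for uniform positions,
$\ln 4$ for fully conserved ones), and

$$\mathrm{MSS} = \frac{\sum_i I(i) f(i, s_i) - \mathrm{Min}}
                     {\mathrm{Max} - \mathrm{Min}},$$

with Min and Max the same weighted sums over per-position minimum and
maximum frequencies, so the consensus scores exactly 1 and the
anti-consensus 0. CSS is the identical quantity restricted to the core
— the 5 consecutive positions with maximal summed information, leftmost
on ties (5 is the conventional MATCH core width, and the leftmost rule
makes the core deterministic). A span whose Max equals Min carries no
information and scores 1 by convention, so it can never reject a site.
Both strands are scanned; minus-strand hits are reported at
forward-strand window-start coordinates (0-based). No pseudocounts are
added at scan time: scoring uses frequencies, not log-odds, so zero
entries are legal. Overlapping hits are all reported — network
construction collapses all hits of a TF on a promoter into one unsigned
edge anyway. The retention rule is the dual threshold CSS ≥ 0.90 and
MSS ≥ 0.90 on the −2000/+1000 window around the TSS; both thresholds
and the window are configurable in `scan_config()`.

## Differential expression and booleanization

DEG calling uses the classical dual rule: |logFC| ≥ 1 (closed bound)
and p < 0.01 (open bound), with logFC the stimulated-minus-control mean
on the log2 scale and p from a two-sided equal-variance t-test. The
t-test is a deliberate simplification: moderated array pipelines
(GCRMA + limma/eBayes) operate on probe-level data that is out of scope
here, and the downstream contextualization consumes only the binary
calls. Multiple-testing correction is off by default (the rule is a raw
p-value cut) but any `p.adjust` method can be switched on. A probe →
gene mean-collapse pre-step is available for probe-level matrices.

Booleanization maps calls to phenotype constraints symmetrically: an
up-gene must be 0 in the control attractor and 1 in the stimulated one,
a down-gene the reverse, and unchanged genes are unconstrained in both.
The symmetric convention for down-genes is our choice — the
control-state convention is genuinely open — and has the virtue that
every DEG constrains both attractors. Leaving unchanged genes
unconstrained is the permissive reading; constraining them to be equal
across conditions would sharpen the fitness signal but also hard-code
an assumption about genes the data says nothing about.

## Merge

Networks are merged as unions keyed by the ordered (source, target)
pair: edge identity ignores provenance, because the contextualization
genome is per-edge and duplicate pairs would double-count. A known
literature sign resolves an unknown TFBS sign on key collision; two
*conflicting* known signs are treated as an input error rather than
silently resolved — no published case exercises this, and silent
resolution would be order-dependent. Self-loops are dropped (under the
fixed-point semantics below they would be trivially self-justifying).
With disjoint key sets the merged edge count is exactly additive.

## Boolean contextualization

The dynamics are the simplest sign-respecting synchronous semantics:
a node with regulators becomes active iff at least one activator is
active and no inhibitor is; regulator-free nodes hold their state; the
stimulus is clamped. Phenotypes are required to be *fixed points* —
stable steady states — not general cyclic attractors.

The search space has one locus per merged edge: {absent, +, −} for
unknown-sign edges, {absent, keep} for literature-signed edges
(literature edges are eligible for removal; whether the original runs
allowed that is unstated, and making them removable is the more
flexible choice). Fitness is

$$\mathrm{fitness} = \frac{\mathrm{matched}}{\mathrm{total\ constraints}}
  - \lambda\,\frac{\mathrm{removed}}{|E|},$$

where `matched` counts, per phenotype, the constraints satisfied by the
best fixed point of the decoded network. The parsimony penalty is
essential: removing *every* edge makes all nodes regulator-free, any
state a fixed point and every constraint satisfiable, so with λ = 0 the
empty network ties the true one. The default λ = 0.01 is small enough
that satisfying one extra constraint always beats keeping any number of
edges, and only breaks ties among equally consistent networks toward
keeping more of the evidence.

Fixed points are found exactly, not by simulation: deleting the clamped
stimulus splits the network into independent weak components; within an
acyclic component every fixed point is the topological propagation of
an assignment of its regulator-free nodes, and all of them are
enumerated; cyclic components are enumerated state-exhaustively up to
$2^{12}$ states. Only larger cyclic components (which none of the
shipped analyses produce) fall back to a restart heuristic, and results
are then flagged approximate.

The GA itself is a standard generational scheme: tournament selection
(size 2), uniform crossover (probability 0.7), per-locus mutation
(default 1/|E|), elitism 2, plus one seeded all-kept genome — a common
warm start, since the merged network with default signs is often close
to consistent. Defaults are population 100 and 200 generations; the
shipped analyses use 40–80/40–80 because their merged networks have
~12 edges and the GA recovers the exhaustive-search optimum there (this
is asserted against full genome-space enumeration on 100 random ≤8-edge
instances in the test suite). Ties are broken toward fewer removed
edges, then the lexicographically smallest genome, so a fixed seed gives
a unique, reproducible result.

## Path ranking

All simple paths from stimulus to target are enumerated by exhaustive
DFS — exact and parameter-free, unlike k-shortest-path truncation; a
`max_paths` cap (default $10^6$) aborts cleanly on pathological graphs,
and `max_len` can bound path length. Edge signs are ignored during
enumeration: inhibitory paths still transmit signal and are counted.
Each gene is scored with $EM_j = (N_{TP} - N_{jP})/N_{TP}$. Note the
denominator: the published table footnote divides by $N_{jP}$ instead,
but only the $N_{TP}$ denominator reproduces every printed value
(e.g. $(92-14)/92 = 0.848 \to 0.85$), so it is adopted as normative and
the footnote treated as a typo. Scores are reported both exact and
rounded to 2 decimals half-away-from-zero, which matches all 13
published values. The stimulus and target are excluded from the ranking
table by default (both trivially have EM = 1); ties rank alphabetically.

# The synthetic-data generator

`gen_full_scenario()` builds a complete study in miniature: a PWM
library (Dirichlet-sampled motifs), promoters with the regulator's
consensus planted on the target and each decoy TF's consensus on one
decoy gene, a one-layer signed literature cascade stimulus → TFs (the
regulator's edge forced activating so a consistent scenario exists),
and a log2-scale expression matrix whose planted DEG truth follows the
cascade signs. By construction the regulator lies on every
stimulus-to-target path, so a correct pipeline must give it EM = 1 and
rank 1.

Defaults and why:

* **Motif lengths 12–16, concentration 50.** Chosen by a mismatch-cost
  argument: the planted consensus always scores exactly 1.0 on both
  similarity scores, while a random 3-kb window must match the 5-mer
  core exactly *and* nearly every remaining position to clear the dual
  0.90 threshold — below one expected spurious edge per thousand
  TF–promoter pairs at these lengths, so chance hits almost never
  contaminate the planted path structure.
* **Window −2000/+1000** (3000 bp), the study's promoter geometry.
* **Expression: 3 replicates, effect size 4 log2 units, noise SD
  0.25.** Strong induction of the kind that motivates this analysis
  (*IRG1* is one of the most induced genes under LPS); at these values
  the t-test power calculation gives essentially certain recovery of
  planted DEGs, and the null false-call rate stays at the nominal 1%.
* **6 TFs (1 regulator + 5 decoys), 20 null genes.** Small enough that
  contextualization is exactly solvable, large enough that the
  upstream/literature/merge bookkeeping is non-trivial.
* **Background: i.i.d. with configurable GC.** No repeat structure or
  real promoter composition — real genomic windows would require
  downloads and add nothing to the logic being tested.

What the generator does *not* emulate: probe-level array artifacts,
correlated noise between replicates, motif self-similarity and family
cross-hybridization (TRANSFAC matrices for related TFs are often nearly
identical), indirect literature edges, and networks with feedback.
Passing the planted-recovery tests therefore shows the pipeline's logic
is correct, not that it would disentangle closely related TF families
on real data.

All generators are pure functions of (arguments, seed): seeds are
applied locally (`withr::with_seed`), never via global RNG state, so
two calls with the same seed are bitwise identical regardless of
context.

# Numerical and degenerate-input choices

* Frequency rows must sum to 1 within $10^{-9}$; generated matrices are
  normalized by construction within $10^{-12}$.
* Zero-information spans score 1 (see above); scores are clipped to
  [0, 1] against floating-point drift.
* Zero pooled variance in the t-test: p = 0 when means differ, 1 when
  equal.
* PWMs shorter than 5 positions are rejected (the core needs 5
  consecutive positions); the library generator additionally keeps
  lengths ≥ 6.
* A gene on zero paths would score EM = 0; `essentiality()` emits it
  with a warning flag, preserving as a checkable condition the claim
  that network genes always lie on at least one path.
* Windows containing non-ACGT characters are skipped during scanning;
  `score_window()` on such a window raises instead, since the caller
  asked for that exact span.

# Problem sizes in the shipped tests

The test suite runs the end-to-end planted-recovery experiment on 100
seeds (6 TFs, ~13-node merged networks, GA 40×40), the GA-vs-exhaustive
comparison on 100 random instances (≤6 nodes, ≤8 edges, full
genome-space enumeration as oracle), path-enumeration equivalence
against both a recursive brute force and igraph on 50 random ≤10-node
graphs, and DEG calibration on a few thousand null genes. These sizes
were picked so each property is exercised in full while the whole suite
stays comfortably interactive.

# Known limitations

* The contextualization objective is a documented stand-in: the
  original algorithm's exact objective (and its use of feedback circuits
  as building blocks) is not reproducible from public material, so
  fixed-point consistency over the whole network with a parsimony
  penalty replaces it.
* Only two phenotypes (control/stimulated) and fixed-point attractors
  are supported; asynchronous update and cyclic attractors are out of
  scope.
* Per-matrix score thresholds (as in profile-based MATCH setups) are
  not modeled; one global CSS/MSS threshold pair applies to all
  matrices.
* The equal-variance t-test is not a moderated test; with few
  replicates and gene-specific variance structure it will be
  conservative for some genes and liberal for others.
* Simple-path enumeration is exponential in the worst case; the
  `max_paths` guard makes failure explicit rather than slow.
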