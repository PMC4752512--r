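#' Run the full regulator-identification pipeline on a scenario
#'
#' Chains the five stages on in-memory scenario inputs (as produced by
#' [gen_full_scenario()] or loaded from its files): (1) MATCH-style
#' promoter scan and unsigned upstream network construction; (2) DEG
#' calling and booleanization into two phenotype constraints; (3) union
#' merge of the upstream and literature networks; (4) Boolean
#' contextualization of the merged network by genetic algorithm, followed
#' by re-attachment of stimulus edges; (5) simple-path enumeration and
#' essentiality ranking.
#'
#' @param scenario List with elements `pwms`, `promoters` (with
#'   `$sequences`), `literature`, `expression` (with `$mat`,
#'   `$conditions`), `config` (with `stimulus`, `target`) — the shape
#'   returned by [gen_full_scenario()].
#' @param scan_cfg A [scan_config()].
#' @param ga GA settings passed to [contextualize_ga()].
#' @param lambda Removed-edge penalty weight.
#' @param lfc_min,p_max DEG thresholds.
#' @return List with the intermediate products: `hits`, `upstream`,
#'   `degs`, `phenotypes`, `merged`, `contextualized`, `final_grn` (after
#'   stimulus-edge re-attachment), `paths`, `ranking`.
#' @export
run_pipeline <- function(scenario, scan_cfg = scan_config(),
                         ga = list(), lambda = 0.01,
                         lfc_min = 1, p_max = 0.01) {
  stimulus <- scenario$config$stimulus
  target <- scenario$config$target

  hits <- scan_library(scenario$pwms, scenario$promoters$sequences,
                       scan_cfg)
  upstream <- build_upstream_network(hits)

  lfc <- log_fold_change(scenario$expression$mat,
                         scenario$expression$conditions)
  p <- deg_test(scenario$expression$mat, scenario$expression$conditions)
  degs <- call_degs(lfc, p, lfc_min = lfc_min, p_max = p_max)

  merged <- merge_grn(upstream, scenario$literature)
  phenotypes <- booleanize(degs, merged$nodes, stimulus)

  ctx <- contextualize_ga(merged, phenotypes, stimulus, target,
                          ga = ga, lambda = lambda)
  final_grn <- attach_stimulus_edges(ctx$grn, scenario$literature,
                                     stimulus)

  paths <- enumerate_simple_paths(final_grn, stimulus, target)
  ranking <- rank_regulators(paths)

  list(hits = hits, upstream = upstream, degs = degs,
       phenotypes = phenotypes, merged = merged, contextualized = ctx,
       final_grn = final_grn, paths = paths, ranking = ranking)
}

#' Load a scenario directory written by [gen_full_scenario()]
#'
#' @param dir Directory containing promoters.fasta, pwms.transfac,
#'   literature.tsv, expression.tsv, conditions.tsv and truth.json.
#' @param stimulus,target Node ids (must match what the files encode).
#' @return A scenario list accepted by [run_pipeline()].
#' @export
load_scenario <- function(dir, stimulus = "LPS", target = "IRG1") {
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "conditions.tsv"))
  list(pwms = read_transfac(file.path(dir, "pwms.transfac")),
       promoters = list(sequences = read_fasta(
         file.path(dir, "promoters.fasta"))),
       literature = load_edge_list(file.path(dir, "literature.tsv")),
       expression = list(mat = expr$mat, conditions = expr$conditions),
       truth = read_truth(file.path(dir, "truth.json")),
       config = list(stimulus = stimulus, target = target))
}
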