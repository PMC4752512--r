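check_conditions <- function(mat, conditions) {
  stopifnot(is.matrix(mat), is.data.frame(conditions),
            all(c("sample", "condition") %in% names(conditions)))
  conditions$condition <- as.character(conditions$condition)
  bad <- setdiff(unique(conditions$condition), c("control", "stimulated"))
  if (length(bad))
    stop("conditions must be 'control' or 'stimulated', got: ",
         paste(bad, collapse = ", "))
  if (!all(conditions$sample %in% colnames(mat)))
    stop("condition map names samples absent from the matrix")
  ctrl <- conditions$sample[conditions$condition == "control"]
  trt <- conditions$sample[conditions$condition == "stimulated"]
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("need at least 2 replicates per condition")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  list(ctrl = ctrl, trt = trt)
}

#' Per-gene log2 fold change
#'
#' For a log2-scale matrix, the mean of the stimulated samples minus the
#' mean of the control samples, per gene.
#'
#' @param mat Numeric matrix, genes x samples, log2 scale, with rownames.
#' @param conditions Data frame with columns `sample` and `condition`
#'   (`control` / `stimulated`).
#' @return Named numeric vector of logFC values.
#' @export
log_fold_change <- function(mat, conditions) {
  g <- check_conditions(mat, conditions)
  rowMeans(mat[, g$trt, drop = FALSE]) -
    rowMeans(mat[, g$ctrl, drop = FALSE])
}

#' Per-gene two-sample equal-variance t-test p-values
#'
#' Two-sided Student t-test assuming equal variances, evaluated directly
#' from the pooled-variance formula for speed over thousands of genes.
#' Genes with zero pooled variance get p = 0 when the group means differ
#' and p = 1 when they are equal.
#'
#' @inheritParams log_fold_change
#' @return Named numeric vector of p-values.
#' @export
deg_test <- function(mat, conditions) {
  g <- check_conditions(mat, conditions)
  x <- mat[, g$trt, drop = FALSE]
  y <- mat[, g$ctrl, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  p <- rep(NA_real_, nrow(mat))
  zero <- se == 0
  p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
  tt <- (mx[!zero] - my[!zero]) / se[!zero]
  p[!zero] <- 2 * pt(abs(tt), df = nx + ny - 2, lower.tail = FALSE)
  names(p) <- rownames(mat)
  p
}

#' Call differentially expressed genes
#'
#' Applies the dual threshold: `up` when logFC >= `lfc_min` and p <
#' `p_max`; `down` when logFC <= -`lfc_min` and p < `p_max`; otherwise
#' `unchanged`. The boundaries are closed on logFC and open on p.
#'
#' @param logFC Named numeric vector (see [log_fold_change()]).
#' @param p Named numeric vector of p-values aligned with `logFC`.
#' @param lfc_min Absolute logFC threshold (default 1).
#' @param p_max p-value threshold (default 0.01).
#' @param p_adjust Multiple-testing adjustment applied to `p` before
#'   thresholding; any method of [stats::p.adjust()], default `"none"`.
#' @return Data frame: `gene_id`, `logFC`, `p`, `call`.
#' @export
call_degs <- function(logFC, p, lfc_min = 1, p_max = 0.01,
                      p_adjust = "none") {
  stopifnot(length(logFC) == length(p),
            identical(names(logFC), names(p)))
  p_use <- p.adjust(p, method = p_adjust)
  call <- rep("unchanged", length(logFC))
  call[logFC >= lfc_min & p_use < p_max] <- "up"
  call[logFC <= -lfc_min & p_use < p_max] <- "down"
  data.frame(gene_id = names(logFC), logFC = unname(logFC),
             p = unname(p), call = call, stringsAsFactors = FALSE)
}

#' Collapse probe-level rows to genes
#'
#' Optional pre-step merging redundant probe sets mapped to the same gene
#' by their mean value.
#'
#' @param mat Numeric matrix, probes x samples, with probe rownames.
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @param by Aggregation function name; only `"mean"` is provided.
#' @return Gene-level matrix.
#' @export
collapse_probes <- function(mat, probe_map, by = "mean") {
  stopifnot(by == "mean", all(rownames(mat) %in% probe_map$probe))
  gene <- probe_map$gene[match(rownames(mat), probe_map$probe)]
  out <- rowsum(mat, gene) / as.vector(table(gene)[sort(unique(gene))])
  out
}

#' Booleanize DEG calls into phenotype constraints
#'
#' Maps differential-expression calls onto binary node states for the two
#' conditions: an up-regulated gene is constrained 0 in control and 1 in
#' stimulated; a down-regulated gene 1 in control and 0 in stimulated;
#' unchanged or absent genes are left unconstrained. The stimulus node is
#' clamped 0 (control) / 1 (stimulated). Only nodes of the supplied network
#' carry constraints.
#'
#' @param degs DEG data frame from [call_degs()].
#' @param grn_nodes Character vector of network node ids.
#' @param stimulus Stimulus node id (must not appear among the DEG genes).
#' @return List of two `boolean_phenotype` objects (`control`,
#'   `stimulated`), each a list with `condition` and `state` (named 0/1
#'   vector over constrained nodes).
#' @export
booleanize <- function(degs, grn_nodes, stimulus) {
  if (stimulus %in% degs$gene_id)
    stop("stimulus node '", stimulus,
         "' appears in the DEG table; it is an input, not a gene")
  keep <- degs[degs$gene_id %in% grn_nodes & degs$call != "unchanged", ,
               drop = FALSE]
  up <- keep$gene_id[keep$call == "up"]
  down <- keep$gene_id[keep$call == "down"]
  mk <- function(condition, stim_val) {
    state <- c(setNames(rep(if (condition == "control") 0 else 1,
                            length(up)), up),
               setNames(rep(if (condition == "control") 1 else 0,
                            length(down)), down))
    state[stimulus] <- stim_val
    structure(list(condition = condition, state = state[order(names(state))]),
              class = "boolean_phenotype")
  }
  list(control = mk("control", 0), stimulated = mk("stimulated", 1))
}

#' Read an expression matrix and condition map from TSV
#'
#' @param expr_path TSV: first column gene id, remaining columns samples.
#' @param cond_path TSV with columns `sample`, `condition`.
#' @return List with `mat` (numeric matrix) and `conditions` (data frame).
#' @export
read_expression <- function(expr_path, cond_path) {
  df <- read.delim(expr_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  conditions <- read.delim(cond_path, stringsAsFactors = FALSE)
  list(mat = mat, conditions = conditions)
}

#' Write an expression matrix and condition map to TSV
#' @param mat Genes x samples matrix with dimnames.
#' @param conditions Condition map data frame.
#' @param expr_path,cond_path Output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(mat, conditions, expr_path, cond_path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(conditions, cond_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}
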