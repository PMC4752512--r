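SIGN_TOKENS <- c("+", "-", "?")

#' Construct a gene regulatory network
#'
#' A GRN is a directed graph of regulatory influences: transcription factors,
#' genes and stimuli as nodes, edges optionally signed (`+` activation, `-`
#' inhibition, `?` unknown) and tagged with provenance (`tfbs`, `literature`
#' or both, comma-joined). At most one edge exists per ordered (source,
#' target) pair; self-loops are dropped with a warning.
#'
#' @param edges Data frame with columns `source`, `target`, `sign`,
#'   `provenance`. Missing `sign`/`provenance` default to `"?"` /
#'   `"unknown"`.
#' @param nodes Optional character vector of node ids; edge endpoints are
#'   always included.
#' @return An object of class `grn`: list with `nodes` (character) and
#'   `edges` (data frame).
#' @export
grn <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$sign)) edges$sign <- "?"
    if (is.null(edges$provenance)) edges$provenance <- "unknown"
    edges <- edges[, c("source", "target", "sign", "provenance")]
    for (cl in names(edges)) edges[[cl]] <- as.character(edges[[cl]])
    if (any(edges$source == "" | edges$target == "" |
            is.na(edges$source) | is.na(edges$target)))
      stop("edge list contains blank or missing node ids")
    bad <- setdiff(unique(edges$sign), SIGN_TOKENS)
    if (length(bad))
      stop("malformed sign token(s): ", paste(bad, collapse = ", "))
    self <- edges$source == edges$target
    if (any(self)) {
      warning("dropping ", sum(self), " self-loop edge(s)")
      edges <- edges[!self, , drop = FALSE]
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      edges <- collapse_duplicate_edges(edges, key)
    }
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

# Collapse duplicate (source, target) rows: identical known signs collapse,
# "?" yields to a known sign, conflicting known signs are an input error.
collapse_duplicate_edges <- function(edges, key) {
  out <- lapply(split(seq_len(nrow(edges)), key), function(idx) {
    e <- edges[idx, , drop = FALSE]
    known <- setdiff(unique(e$sign), "?")
    if (length(known) > 1L)
      stop("conflicting signs for edge ", e$source[1], " -> ", e$target[1],
           ": ", paste(sort(unique(e$sign)), collapse = " vs "))
    data.frame(source = e$source[1], target = e$target[1],
               sign = if (length(known)) known else "?",
               provenance = paste(sort(unique(unlist(
                 strsplit(e$provenance, ",")))), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("GRN: %d nodes, %d edges (%d signed, %d unknown)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign != "?"),
              sum(x$edges$sign == "?")))
  invisible(x)
}

edge_keys <- function(g) paste(g$edges$source, g$edges$target, sep = "\r")

#' Number of edges of a GRN
#' @param g A `grn`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Read a signed edge list from TSV
#'
#' Expects columns `source`, `target`, `sign` (one of `+`, `-`, `?`) and
#' `provenance`. Duplicate rows with identical key and sign collapse to one
#' edge; identical keys carrying conflicting known signs raise an error
#' naming the offending pair.
#'
#' @param path TSV path.
#' @return A `grn`.
#' @export
load_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("source", "target", "sign", "provenance")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  grn(df)
}

#' Write a GRN edge list to TSV
#' @param g A `grn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a GRN in SIF format
#'
#' Writes `source<TAB>relation<TAB>target` with relation `activates`,
#' `inhibits` or `regulates` for signs `+`, `-`, `?`.
#'
#' @param g A `grn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  rel <- c("+" = "activates", "-" = "inhibits", "?" = "regulates")
  df <- data.frame(g$edges$source, rel[g$edges$sign], g$edges$target)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Union-merge two regulatory networks
#'
#' Merges the unsigned TFBS upstream network with the signed literature
#' network (or any two GRNs) by taking the union of nodes and of edges keyed
#' by (source, target). When a key occurs in both, a known sign wins over
#' `?` and the provenance becomes the union; two conflicting known signs
#' raise an error. With disjoint edge keys the merged edge count is exactly
#' the sum of the two inputs.
#'
#' @param upstream,downstream `grn` objects.
#' @return The merged `grn`.
#' @export
merge_grn <- function(upstream, downstream) {
  stopifnot(inherits(upstream, "grn"), inherits(downstream, "grn"))
  edges <- rbind(upstream$edges, downstream$edges)
  g <- grn(edges, nodes = c(upstream$nodes, downstream$nodes))
  g
}

#' Convert a GRN to an igraph graph
#' @param g A `grn`.
#' @return An `igraph` directed graph with a `sign` edge attribute.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges[, c("source", "target")],
                                      directed = TRUE, vertices = g$nodes)
  igraph::E(ig)$sign <- g$edges$sign
  ig
}
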