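#' Construct a simple-path set
#'
#' @param source,target Endpoint node ids.
#' @param paths List of character vectors, each a node sequence from
#'   `source` to `target` with no repeated node.
#' @return A `path_set` list: `source`, `target`, `paths`, `n_tp` (total
#'   path count).
#' @export
path_set <- function(source, target, paths) {
  for (p in paths) {
    if (p[1] != source || p[length(p)] != target)
      stop("path does not run from ", source, " to ", target, ": ",
           paste(p, collapse = "->"))
    if (anyDuplicated(p))
      stop("path repeats a node: ", paste(p, collapse = "->"))
  }
  structure(list(source = source, target = target, paths = paths,
                 n_tp = length(paths)), class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("PathSet %s -> %s: %d simple path(s)\n", x$source, x$target,
              x$n_tp))
  invisible(x)
}

#' Enumerate all simple paths from stimulus to target
#'
#' Exhaustive depth-first enumeration of every directed path from `source`
#' to `target` visiting no node twice. Edge signs are ignored: inhibitory
#' paths count, since signal propagation is what is being enumerated.
#' Paths are returned in lexicographic order of their node sequences.
#'
#' @param g A `grn`.
#' @param source,target Node ids; must differ and be present in `g`.
#' @param max_len Optional cap on path length in nodes (default unbounded).
#' @param max_paths Safety cap; enumeration aborts with an error beyond it
#'   (default 1e6).
#' @return A [path_set()].
#' @export
enumerate_simple_paths <- function(g, source, target, max_len = Inf,
                                   max_paths = 1e6) {
  stopifnot(inherits(g, "grn"))
  if (identical(source, target))
    stop("source and target must differ")
  missing <- setdiff(c(source, target), g$nodes)
  if (length(missing))
    stop("node(s) absent from the network: ",
         paste(missing, collapse = ", "))
  adj <- split(g$edges$target, g$edges$source)
  paths <- list()
  visit <- function(node, trail) {
    if (node == target) {
      if (length(paths) >= max_paths)
        stop("more than ", max_paths,
             " simple paths; raise max_paths to continue")
      paths[[length(paths) + 1L]] <<- trail
      return()
    }
    if (length(trail) >= max_len) return()
    for (nxt in adj[[node]])
      if (!(nxt %in% trail)) visit(nxt, c(trail, nxt))
  }
  visit(source, source)
  if (length(paths) > 1L) {
    key <- vapply(paths, paste, character(1), collapse = "\x01")
    paths <- paths[order(key, method = "radix")]
  }
  path_set(source, target, paths)
}

#' Round half away from zero
#'
#' Decimal rounding in which .005 at the last kept digit always moves away
#' from zero, matching how the ranking table values are printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Essentiality of a gene for signal propagation
#'
#' For a set of N_TP simple stimulus-to-target paths, a gene absent from
#' N_jP of them has essentiality `EM_j = (N_TP - N_jP) / N_TP`: the
#' fraction of paths passing through it. EM is 1 for a gene on every path
#' (removing it disconnects stimulus from target) and positive for every
#' gene on at least one path.
#'
#' @param pathset A [path_set()] with at least one path.
#' @param gene Gene id.
#' @return List: `gene`, `n_tp`, `n_jp` (paths missing the gene), `em`
#'   (exact), `em_rounded` (2 decimals, half away from zero),
#'   `off_all_paths` (TRUE when the gene lies on no path, i.e. EM = 0).
#' @export
essentiality <- function(pathset, gene) {
  stopifnot(inherits(pathset, "path_set"), pathset$n_tp >= 1)
  n_jp <- sum(!vapply(pathset$paths, function(p) gene %in% p, logical(1)))
  em <- (pathset$n_tp - n_jp) / pathset$n_tp
  if (em == 0)
    warning("gene ", gene, " lies on no ", pathset$source, " -> ",
            pathset$target, " path; EM = 0")
  list(gene = gene, n_tp = pathset$n_tp, n_jp = n_jp, em = em,
       em_rounded = round_half_away(em, 2), off_all_paths = em == 0)
}

#' Rank transcriptional regulators by essentiality
#'
#' Scores every node appearing on at least one stimulus-to-target simple
#' path and ranks them by descending essentiality, ties broken
#' alphabetically; the dense rank is reported. The source and target are
#' excluded from the table by default (both trivially have EM = 1).
#'
#' @param pathset A non-empty [path_set()].
#' @param include_endpoints Include source and target rows?
#' @return Data frame: `regulator`, `total_paths`, `paths_absent`,
#'   `essentiality` (2-decimal), `essentiality_exact`, `rank`.
#' @export
rank_regulators <- function(pathset, include_endpoints = FALSE) {
  stopifnot(inherits(pathset, "path_set"), pathset$n_tp >= 1)
  genes <- sort(unique(unlist(pathset$paths)))
  if (!include_endpoints)
    genes <- setdiff(genes, c(pathset$source, pathset$target))
  if (!length(genes))
    return(data.frame(regulator = character(), total_paths = integer(),
                      paths_absent = integer(), essentiality = numeric(),
                      essentiality_exact = numeric(), rank = integer()))
  rows <- lapply(genes, function(gname) {
    e <- essentiality(pathset, gname)
    data.frame(regulator = gname, total_paths = e$n_tp,
               paths_absent = e$n_jp, essentiality = e$em_rounded,
               essentiality_exact = e$em, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$essentiality_exact, out$regulator), , drop = FALSE]
  out$rank <- cumsum(!duplicated(out$essentiality_exact))
  rownames(out) <- NULL
  out
}

#' Write a path set to TSV (one semicolon-joined path per row)
#' @param pathset A `path_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paths <- function(pathset, path) {
  df <- data.frame(path = vapply(pathset$paths, paste, character(1),
                                 collapse = ";"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
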