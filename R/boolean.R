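#' Boolean network over a fully signed GRN
#'
#' Wraps a signed GRN for synchronous Boolean simulation. The update rule
#' is sign-respecting: a node with regulators becomes 1 iff at least one of
#' its activators is 1 and none of its inhibitors is 1; a node with no
#' incoming edges holds its current state; input nodes (the stimulus) stay
#' clamped at their current value.
#'
#' @param g A `grn` with every edge signed `+` or `-`.
#' @param inputs Character vector of clamped input node ids.
#' @return An object of class `boolean_net`.
#' @export
boolean_net <- function(g, inputs = character()) {
  stopifnot(inherits(g, "grn"))
  if (any(g$edges$sign == "?"))
    stop("boolean_net requires all edges signed; ",
         sum(g$edges$sign == "?"), " edge(s) have unknown sign")
  n <- length(g$nodes)
  idx <- setNames(seq_len(n), g$nodes)
  Ap <- matrix(0, n, n); An <- matrix(0, n, n)
  e <- g$edges
  if (nrow(e)) {
    pos <- e$sign == "+"
    Ap[cbind(idx[e$source[pos]], idx[e$target[pos]])] <- 1
    An[cbind(idx[e$source[!pos]], idx[e$target[!pos]])] <- 1
  }
  structure(list(grn = g, nodes = g$nodes, inputs = intersect(inputs, g$nodes),
                 Ap = Ap, An = An,
                 has_reg = (colSums(Ap) + colSums(An)) > 0,
                 update_rule = "any_activator_no_inhibitor"),
            class = "boolean_net")
}

# Synchronous update of a state matrix (rows = states, cols = nodes).
update_states <- function(net, S) {
  act <- (S %*% net$Ap) > 0
  inh <- (S %*% net$An) > 0
  newS <- (act & !inh) + 0
  hold <- !net$has_reg | net$nodes %in% net$inputs
  newS[, hold] <- S[, hold]
  newS
}

#' Synchronous Boolean update of one state
#'
#' Applies one synchronous step: all non-input nodes recompute their state
#' simultaneously; a node becomes 1 iff it has at least one active
#' activator and no active inhibitor; nodes without regulators hold their
#' state; inputs stay clamped.
#'
#' @param net A [boolean_net()].
#' @param state Named 0/1 vector covering every node of the network.
#' @return The updated named 0/1 vector.
#' @export
update_state <- function(net, state) {
  missing <- setdiff(net$nodes, names(state))
  if (length(missing))
    stop("state is missing node(s): ", paste(missing, collapse = ", "))
  S <- matrix(state[net$nodes], 1L, dimnames = list(NULL, net$nodes))
  setNames(drop(update_states(net, S)), net$nodes)
}

# All assignments of k binary variables as a (2^k) x k matrix, in binary
# counting order (deterministic witness order); memoized.
.grid_cache <- new.env(parent = emptyenv())
binary_grid <- function(k) {
  if (k == 0L) return(matrix(0, 1L, 0L))
  key <- as.character(k)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- as.matrix(expand.grid(rep(list(c(0, 1)), k))[, k:1, drop = FALSE])
    dimnames(g) <- NULL
    .grid_cache[[key]] <- g
  }
  g
}

#' Test whether a phenotype is a stable steady state of the network
#'
#' A phenotype constrains a subset of nodes to 0/1. The network admits the
#' phenotype as a stable steady state iff some assignment of the
#' unconstrained nodes makes the full state a fixed point of
#' [update_state()]. The search over unconstrained assignments is
#' exhaustive up to 2^12 free nodes; above that a restart heuristic is used
#' and the result is flagged approximate.
#'
#' @param net A [boolean_net()].
#' @param phenotype A `boolean_phenotype` (see [booleanize()]).
#' @param max_exhaustive Free-node count up to which the search is
#'   exhaustive (default 12).
#' @param restarts,max_steps Heuristic parameters used above the exhaustive
#'   limit.
#' @return List: `stable` (logical), `witness` (named state vector or
#'   NULL), `approximate` (logical).
#' @export
is_stable <- function(net, phenotype, max_exhaustive = 12L,
                      restarts = 64L, max_steps = 64L) {
  cons <- phenotype$state
  cons <- cons[names(cons) %in% net$nodes]
  free <- setdiff(net$nodes, names(cons))
  base <- setNames(numeric(length(net$nodes)), net$nodes)
  base[names(cons)] <- cons
  if (length(free) <= max_exhaustive) {
    Sfree <- binary_grid(length(free))
    S <- matrix(rep(base, each = nrow(Sfree)), nrow(Sfree),
                dimnames = list(NULL, net$nodes))
    if (length(free)) S[, free] <- Sfree
    fixed <- rowSums(update_states(net, S) != S) == 0
    if (any(fixed)) {
      w <- S[which(fixed)[1], ]
      return(list(stable = TRUE, witness = setNames(w, net$nodes),
                  approximate = FALSE))
    }
    return(list(stable = FALSE, witness = NULL, approximate = FALSE))
  }
  # greedy-with-restarts: iterate the update on free nodes with the
  # constrained nodes re-clamped each step, then verify the full state
  for (r in seq_len(restarts)) {
    s <- base
    s[free] <- as.numeric((seq_along(free) + r) %% 2L)
    if (r > 2L) s[free] <- as.numeric(((seq_along(free) * r) %% 3L) == 0L)
    for (step in seq_len(max_steps)) {
      s2 <- update_state(net, s)
      s2[names(cons)] <- cons
      if (all(s2 == s)) break
      s <- s2
    }
    if (all(update_state(net, s) == s) && all(s[names(cons)] == cons))
      return(list(stable = TRUE, witness = s, approximate = TRUE))
  }
  list(stable = FALSE, witness = NULL, approximate = TRUE)
}

# Weakly connected component membership from a directed adjacency matrix.
weak_components <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(integer())
  U <- (A + t(A)) > 0
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(U[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# Kahn topological order of a directed adjacency matrix; NULL if cyclic.
topo_order <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(integer())
  indeg <- colSums(A)
  done <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!done & indeg == 0)
    if (!length(ready)) break
    ord <- c(ord, ready)
    done[ready] <- TRUE
    indeg <- indeg - colSums(A[ready, , drop = FALSE])
  }
  if (length(ord) < n) NULL else ord
}

# ---- exact fixed-point engine used by the contextualization fitness ----
#
# Fixed points of the update rule decompose over the weakly connected
# components obtained after deleting the clamped input nodes (their value
# is a known constant feeding each component). Within a component:
#   * acyclic case: a fixed point is determined by the values of its
#     in-degree-0 nodes (which hold state, hence are free); all fixed
#     points are enumerated by propagating every assignment of those nodes
#     in topological order;
#   * cyclic case: all component states are enumerated when the component
#     has <= max_exhaustive nodes; otherwise a restart heuristic is used
#     and the result is flagged approximate.
# The returned value is, per phenotype, the maximum number of constraints
# matched by any fixed point (summed over components), plus a flag.
# Component decomposition shared by both phenotypes of one decoded
# network. Each component record restricts the state space to the columns
# inputs + component nodes and lists per-node regulator indices in that
# reduced space.
fp_decompose <- function(net) {
  nodes <- net$nodes
  inputs <- net$inputs
  others <- setdiff(nodes, inputs)
  if (!length(others)) return(list(comps = list(), others = others))
  oi <- match(others, nodes)
  A <- (net$Ap + net$An)[oi, oi, drop = FALSE]  # adjacency among non-inputs
  comp <- weak_components(A)
  ii <- match(inputs, nodes)
  comps <- lapply(split(seq_along(others), comp), function(loc) {
    cn <- others[loc]
    cidx <- oi[loc]
    cols <- c(ii, cidx)            # reduced state space, inputs first
    colnames_red <- nodes[cols]
    topo <- topo_order(A[loc, loc, drop = FALSE])
    regs <- lapply(cidx, function(j)
      list(act = match(which(net$Ap[, j] > 0), cols),
           inh = match(which(net$An[, j] > 0), cols)))
    list(cn = cn, cols = colnames_red, n_inputs = length(ii),
         free_local = which(!net$has_reg[cidx]),
         has_reg_local = net$has_reg[cidx],
         topo = topo, regs = regs)
  })
  list(comps = comps, others = others)
}

# Maximum number of constraints in `cons` matched by any fixed point of
# the network with inputs clamped to stim_val, evaluated exactly per
# component (see fp_decompose). Returns matched count + approximate flag.
fp_match <- function(net, decomp, cons, stim_val, max_exhaustive = 12L) {
  matched <- 0
  approx <- FALSE
  # input nodes themselves can be constrained (the stimulus clamp)
  for (iv in intersect(names(cons), net$inputs))
    matched <- matched + (cons[[iv]] == stim_val)
  for (cp in decomp$comps) {
    ccons <- cons[names(cons) %in% cp$cn]
    k <- length(cp$cn)
    nin <- cp$n_inputs
    if (!is.null(cp$topo) && length(cp$free_local) <= max_exhaustive) {
      # acyclic: every fixed point is the topological propagation of an
      # assignment of the regulator-free nodes
      grid <- binary_grid(length(cp$free_local))
      S <- matrix(0, nrow(grid), nin + k)
      if (nin) S[, seq_len(nin)] <- stim_val
      if (length(cp$free_local)) S[, nin + cp$free_local] <- grid
      for (v in cp$topo) {
        if (!cp$has_reg_local[v]) next
        r <- cp$regs[[v]]
        act <- if (length(r$act))
          rowSums(S[, r$act, drop = FALSE]) > 0 else FALSE
        inh <- if (length(r$inh))
          rowSums(S[, r$inh, drop = FALSE]) > 0 else FALSE
        S[, nin + v] <- (act & !inh) + 0
      }
    } else if (k <= max_exhaustive) {
      # cyclic: enumerate all component states, keep the fixed points
      grid <- binary_grid(k)
      S <- matrix(0, nrow(grid), nin + k)
      if (nin) S[, seq_len(nin)] <- stim_val
      S[, nin + seq_len(k)] <- grid
      new <- S
      for (v in seq_len(k)) {
        if (!cp$has_reg_local[v]) next
        r <- cp$regs[[v]]
        act <- if (length(r$act))
          rowSums(S[, r$act, drop = FALSE]) > 0 else FALSE
        inh <- if (length(r$inh))
          rowSums(S[, r$inh, drop = FALSE]) > 0 else FALSE
        new[, nin + v] <- (act & !inh) + 0
      }
      fixed <- rowSums(new != S) == 0
      if (!any(fixed)) next  # component admits no fixed point: 0 matched
      S <- S[fixed, , drop = FALSE]
    } else {
      # large cyclic component: settle for an all-or-nothing heuristic
      approx <- TRUE
      res <- is_stable(net, structure(list(
        condition = "heuristic",
        state = c(setNames(rep(stim_val, length(net$inputs)), net$inputs),
                  ccons)), class = "boolean_phenotype"))
      if (res$stable) matched <- matched + length(ccons)
      next
    }
    if (length(ccons)) {
      ci <- nin + match(names(ccons), cp$cn)
      m <- rowSums(S[, ci, drop = FALSE] ==
                     matrix(unlist(ccons), nrow(S), length(ccons),
                            byrow = TRUE))
      matched <- matched + max(m)
    }
  }
  list(matched = matched, approximate = approx)
}

best_fixed_point_match <- function(net, cons, stim_val,
                                   max_exhaustive = 12L) {
  fp_match(net, fp_decompose(net), cons, stim_val, max_exhaustive)
}
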