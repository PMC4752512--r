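#' Decode a candidate genome into a signed sub-network
#'
#' The genome has one locus per merged edge. For edges whose original sign
#' is unknown the locus takes values 0 (edge removed), 1 (kept, activating)
#' or 2 (kept, inhibiting); for literature-signed edges 0 (removed) or 1
#' (kept with its sign). All merged nodes are retained, so constraints on
#' nodes that lose their regulators remain meaningful (they hold state).
#'
#' @param genome Integer vector of length `n_edges(merged)`.
#' @param merged The merged `grn`.
#' @return A fully signed `grn`.
#' @export
decode_genome <- function(genome, merged) {
  e <- merged$edges
  stopifnot(length(genome) == nrow(e))
  unknown <- e$sign == "?"
  if (any(genome < 0 | genome > ifelse(unknown, 2, 1)))
    stop("genome locus out of range for its edge type")
  keep <- genome > 0
  sign <- ifelse(unknown, c(NA, "+", "-")[genome + 1L], e$sign)
  kept <- e[keep, , drop = FALSE]
  kept$sign <- sign[keep]
  grn(kept, nodes = merged$nodes)
}

#' Fitness of a candidate contextualization
#'
#' Decodes the genome, then for each phenotype finds the fixed point of the
#' synchronous update that matches the largest number of the phenotype's
#' node constraints (exactly, via the component-wise fixed-point engine).
#' The scalar fitness is
#' `matched/total_constraints - lambda * removed_edges/n_edges(merged)`,
#' so full constraint satisfaction with nothing removed scores 1 and
#' parsimony pressure (`lambda > 0`) penalizes trivial all-removed
#' solutions, which otherwise satisfy every constraint through the
#' hold-state rule.
#'
#' @param genome Integer genome (see [decode_genome()]).
#' @param merged Merged `grn`.
#' @param phenotypes List of two `boolean_phenotype`s (see [booleanize()]).
#' @param stimulus Clamped input node id.
#' @param lambda Removed-edge penalty weight (default 0.01).
#' @return A `fitness_record` list: `matched`, `total_constraints`,
#'   `removed_edges`, `penalty_weight`, `fitness`, `approximate`.
#' @export
ga_fitness <- function(genome, merged, phenotypes, stimulus,
                       lambda = 0.01) {
  decoded <- decode_genome(genome, merged)
  net <- boolean_net(decoded, inputs = stimulus)
  matched <- 0
  total <- 0
  approx <- FALSE
  for (ph in phenotypes) {
    cons <- ph$state
    total <- total + length(cons)
    res <- best_fixed_point_match(net, cons,
                                  stim_val = unname(cons[stimulus]))
    matched <- matched + res$matched
    approx <- approx || res$approximate
  }
  removed <- sum(genome == 0)
  structure(list(
    matched = matched, total_constraints = total,
    removed_edges = removed, penalty_weight = lambda,
    fitness = matched / total - lambda * removed / max(1L, nrow(merged$edges)),
    approximate = approx), class = "fitness_record")
}

# strictly-better comparison implementing the tie-break chain:
# fitness, then fewer removed edges, then lexicographically smaller genome
genome_better <- function(fit_a, genome_a, fit_b, genome_b) {
  if (fit_a$fitness != fit_b$fitness) return(fit_a$fitness > fit_b$fitness)
  if (fit_a$removed_edges != fit_b$removed_edges)
    return(fit_a$removed_edges < fit_b$removed_edges)
  d <- which(genome_a != genome_b)
  length(d) > 0 && genome_a[d[1]] < genome_b[d[1]]
}

#' Contextualize a merged network with a genetic algorithm
#'
#' Searches over per-edge removal/sign-assignment genomes for the network
#' that best reproduces the booleanized control and stimulated phenotypes
#' as stable steady states (fixed points) of the synchronous Boolean
#' update, following [ga_fitness()]. Standard generational GA: tournament
#' selection, uniform crossover, per-locus mutation, elitism. Ties are
#' broken toward fewer removed edges, then the lexicographically smallest
#' genome, so a fixed seed gives a unique result.
#'
#' @param merged Merged `grn`; must connect the stimulus to the target.
#' @param phenotypes List of two `boolean_phenotype`s.
#' @param stimulus,target Node ids of the clamped input and the gene of
#'   interest.
#' @param ga List of GA settings: `pop` (default 100), `generations`
#'   (200), `crossover_p` (0.7), `mutation_p` (default `1/n_edges`),
#'   `elitism` (2), `seed` (1).
#' @param lambda Removed-edge penalty weight.
#' @return A `contextualized_grn` list: `grn` (the decoded best network,
#'   always containing stimulus and target), `net` (its `boolean_net`),
#'   `fitness` (the best `fitness_record` with `seed` and `generations`
#'   echoed), `genome`.
#' @export
contextualize_ga <- function(merged, phenotypes, stimulus, target,
                             ga = list(), lambda = 0.01) {
  stopifnot(inherits(merged, "grn"))
  if (!all(c(stimulus, target) %in% merged$nodes))
    stop("stimulus and target must be nodes of the merged network")
  ig <- as_igraph(merged)
  if (!is.finite(igraph::distances(ig, v = stimulus, to = target,
                                   mode = "out")[1, 1]))
    stop("no path from ", stimulus, " to ", target,
         " in the merged network; nothing to contextualize")
  cfg <- utils::modifyList(
    list(pop = 100L, generations = 200L, crossover_p = 0.7,
         mutation_p = NULL, elitism = 2L, seed = 1L), ga)
  nE <- nrow(merged$edges)
  if (is.null(cfg$mutation_p)) cfg$mutation_p <- 1 / nE
  max_allele <- ifelse(merged$edges$sign == "?", 2L, 1L)

  # Fast inner-loop fitness: same computation as ga_fitness() but the
  # boolean_net adjacency is assembled directly from precomputed edge
  # indices, skipping per-genome data-frame construction. Results are
  # cached (fitness is a pure function of the genome).
  nodes <- merged$nodes
  n_nodes <- length(nodes)
  idx <- setNames(seq_len(n_nodes), nodes)
  esrc <- idx[merged$edges$source]
  etgt <- idx[merged$edges$target]
  e_unknown <- merged$edges$sign == "?"
  e_neg <- merged$edges$sign == "-"
  total_cons <- sum(lengths(lapply(phenotypes, `[[`, "state")))
  cache <- new.env(parent = emptyenv())
  eval_fitness <- function(genome) {
    key <- paste(genome, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    keep <- genome > 0L
    neg <- ifelse(e_unknown, genome == 2L, e_neg)
    Ap <- matrix(0, n_nodes, n_nodes)
    An <- matrix(0, n_nodes, n_nodes)
    kp <- keep & !neg; kn <- keep & neg
    Ap[cbind(esrc[kp], etgt[kp])] <- 1
    An[cbind(esrc[kn], etgt[kn])] <- 1
    net <- structure(list(nodes = nodes, inputs = stimulus, Ap = Ap,
                          An = An,
                          has_reg = (colSums(Ap) + colSums(An)) > 0),
                     class = "boolean_net")
    decomp <- fp_decompose(net)
    matched <- 0; approx <- FALSE
    for (ph in phenotypes) {
      res <- fp_match(net, decomp, ph$state,
                      stim_val = unname(ph$state[stimulus]))
      matched <- matched + res$matched
      approx <- approx || res$approximate
    }
    removed <- sum(!keep)
    cache[[key]] <- structure(list(
      matched = matched, total_constraints = total_cons,
      removed_edges = removed, penalty_weight = lambda,
      fitness = matched / total_cons - lambda * removed / max(1L, nE),
      approximate = approx), class = "fitness_record")
  }

  withr::with_seed(as.integer(cfg$seed), {
    pop <- lapply(seq_len(cfg$pop), function(i) {
      if (i == 1L) {
        # seed one all-kept genome (unknown signs activating)
        rep(1L, nE)
      } else {
        vapply(max_allele, function(m) sample.int(m + 1L, 1L) - 1L,
               integer(1))
      }
    })
    fits <- lapply(pop, eval_fitness)
    best_i <- 1L
    for (i in seq_along(pop))
      if (genome_better(fits[[i]], pop[[i]], fits[[best_i]], pop[[best_i]]))
        best_i <- i
    best_genome <- pop[[best_i]]
    best_fit <- fits[[best_i]]

    for (gen in seq_len(cfg$generations)) {
      score <- vapply(fits, `[[`, numeric(1), "fitness")
      # elites carried over unchanged
      elite_idx <- order(-score,
                         vapply(fits, `[[`, numeric(1), "removed_edges"))
      elites <- pop[elite_idx[seq_len(min(cfg$elitism, cfg$pop))]]
      offspring <- elites
      while (length(offspring) < cfg$pop) {
        pick <- function() {
          cand <- sample.int(cfg$pop, 2L, replace = TRUE)
          cand[which.max(score[cand])]
        }
        a <- pop[[pick()]]; b <- pop[[pick()]]
        if (runif(1) < cfg$crossover_p) {
          mask <- runif(nE) < 0.5
          tmp <- a; a[mask] <- b[mask]; b[mask] <- tmp[mask]
        }
        mutate <- function(gn) {
          hit <- which(runif(nE) < cfg$mutation_p)
          for (j in hit) {
            choices <- setdiff(0:max_allele[j], gn[j])
            gn[j] <- if (length(choices) == 1L) choices else
              sample(choices, 1L)
          }
          gn
        }
        offspring[[length(offspring) + 1L]] <- mutate(a)
        if (length(offspring) < cfg$pop)
          offspring[[length(offspring) + 1L]] <- mutate(b)
      }
      pop <- offspring
      fits <- lapply(pop, eval_fitness)
      for (i in seq_along(pop))
        if (genome_better(fits[[i]], pop[[i]], best_fit, best_genome)) {
          best_genome <- pop[[i]]
          best_fit <- fits[[i]]
        }
    }
    decoded <- decode_genome(best_genome, merged)
    # the pruned network always keeps nodes incident to kept edges plus
    # the stimulus and target
    keep_nodes <- sort(unique(c(stimulus, target,
                                decoded$edges$source, decoded$edges$target)))
    out <- grn(decoded$edges, nodes = keep_nodes)
    best_fit$seed <- cfg$seed
    best_fit$generations <- cfg$generations
    structure(list(grn = out, net = boolean_net(out, inputs = stimulus),
                   fitness = best_fit, genome = best_genome),
              class = "contextualized_grn")
  })
}

#' @export
print.contextualized_grn <- function(x, ...) {
  f <- x$fitness
  cat(sprintf(paste0("Contextualized GRN: %d nodes, %d edges; fitness ",
                     "%.4f (%d/%d constraints, %d edge(s) removed)\n"),
              length(x$grn$nodes), nrow(x$grn$edges), f$fitness,
              f$matched, f$total_constraints, f$removed_edges))
  invisible(x)
}

#' Re-attach stimulus edges from the literature network
#'
#' Adds every edge of the downstream (literature) network whose source is
#' the stimulus and whose target is already a node of the contextualized
#' network. No other nodes are introduced, and edges already present are
#' left untouched (the operation is idempotent).
#'
#' @param contextualized A `grn` (e.g. `$grn` of [contextualize_ga()]).
#' @param downstream The literature `grn`.
#' @param stimulus Stimulus node id.
#' @return The augmented `grn`.
#' @export
attach_stimulus_edges <- function(contextualized, downstream, stimulus) {
  add <- downstream$edges[downstream$edges$source == stimulus &
                            downstream$edges$target %in%
                            contextualized$nodes, , drop = FALSE]
  have <- edge_keys(contextualized)
  add <- add[!(paste(add$source, add$target, sep = "\r") %in% have), ,
             drop = FALSE]
  grn(rbind(contextualized$edges, add), nodes = contextualized$nodes)
}
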