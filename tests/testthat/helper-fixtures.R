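# Shared in-code fixtures for the test suite.

# A deterministic toy PWM: 3 informative rows padded with uniform rows to
# reach the 5-position minimum.
toy_pwm <- function() {
  freq <- rbind(c(0.7, 0.1, 0.1, 0.1),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.4, 0.4, 0.1, 0.1),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.25, 0.25, 0.25, 0.25))
  pwm("TOY", freq)
}

# Brute-force MATCH-style scorer evaluating the similarity formula
# term by term, independent of the vectorized implementation.
brute_score <- function(freq, seq_chars) {
  info <- vapply(seq_len(nrow(freq)), function(i) {
    s <- 0
    for (b in 1:4) if (freq[i, b] > 0)
      s <- s + freq[i, b] * log(4 * freq[i, b])
    s
  }, numeric(1))
  span <- function(rows) {
    cur <- mn <- mx <- 0
    for (i in rows) {
      b <- match(seq_chars[i], c("A", "C", "G", "T"))
      cur <- cur + info[i] * freq[i, b]
      mn <- mn + info[i] * min(freq[i, ])
      mx <- mx + info[i] * max(freq[i, ])
    }
    if (mx - mn <= 0) return(1)
    min(max((cur - mn) / (mx - mn), 0), 1)
  }
  sums <- vapply(seq_len(nrow(freq) - 4L), function(i)
    sum(info[i:(i + 4L)]), numeric(1))
  core <- which.max(sums)
  c(css = span(core:(core + 4L)),
    mss = span(seq_len(nrow(freq))))
}

# Small literature-style GRN builders.
edge_df <- function(src, tgt, sign = "+", provenance = "literature") {
  data.frame(source = src, target = tgt, sign = sign,
             provenance = provenance, stringsAsFactors = FALSE)
}

toy_phenotype <- function(state, condition = "stimulated") {
  structure(list(condition = condition, state = state),
            class = "boolean_phenotype")
}

# Random small contextualization instance with a reachable target,
# signed and unknown edges, and random constraints on both phenotypes.
random_ctx_instance <- function(seed, max_nodes = 6L, max_edges = 8L) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- c("S", paste0("N", seq_len(n - 1)))
  ne <- sample(4:max_edges, 1)
  pairs <- expand.grid(src = nodes, tgt = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$tgt & pairs$tgt != "S" &
                   !(pairs$src == "S" & pairs$tgt == "N1"), ]
  pick <- pairs[sample(nrow(pairs), min(ne - 1L, nrow(pairs))), ]
  sign <- sample(c("+", "-", "?"), nrow(pick), replace = TRUE)
  df <- data.frame(source = c("S", pick$src), target = c("N1", pick$tgt),
                   sign = c("+", sign), provenance = "literature",
                   stringsAsFactors = FALSE)
  df$provenance[df$sign == "?"] <- "tfbs"
  g <- grn(df)
  d <- igraph::distances(as_igraph(g), v = "S", mode = "out")
  reach <- setdiff(colnames(d)[is.finite(d[1, ])], "S")
  target <- sort(reach)[length(reach)]
  cons_nodes <- sample(setdiff(g$nodes, "S"),
                       min(3, length(g$nodes) - 1L))
  mk <- function(cond, sv)
    toy_phenotype(c(setNames(sample(0:1, length(cons_nodes),
                                    replace = TRUE), cons_nodes), S = sv),
                  cond)
  list(g = g, target = target,
       ph = list(control = mk("control", 0),
                 stimulated = mk("stimulated", 1)))
}

# Exhaustive enumeration of every genome of a merged network, returning
# the optimal fitness value; the independent oracle for the GA search.
exhaustive_best_fitness <- function(g, ph, stimulus = "S", lambda = 0.01) {
  ma <- ifelse(g$edges$sign == "?", 2L, 1L)
  best <- -Inf
  gi <- rep(0L, length(ma))
  repeat {
    f <- ga_fitness(gi, g, ph, stimulus, lambda)
    if (f$fitness > best) best <- f$fitness
    j <- 1L
    repeat {
      gi[j] <- gi[j] + 1L
      if (gi[j] <= ma[j]) break
      gi[j] <- 0L
      j <- j + 1L
      if (j > length(ma)) return(best)
    }
  }
}

# Construct a path set with a prescribed (n_tp, n_jp) profile per gene:
# gene j appears on the first n_tp - n_jp[j] paths.
table_path_set <- function(n_tp, n_jp, source = "LPS", target = "IRG1") {
  paths <- lapply(seq_len(n_tp), function(i) {
    mid <- names(n_jp)[i <= n_tp - n_jp]
    c(source, mid, if (!length(mid)) paste0("via", i), target)
  })
  path_set(source, target, paths)
}
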