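# Independent recursive brute-force enumerator used as the oracle.
oracle_paths <- function(g, source, target) {
  adj <- split(g$edges$target, g$edges$source)
  out <- list()
  rec <- function(v, trail) {
    if (v == target) {
      out[[length(out) + 1L]] <<- trail
      return()
    }
    for (w in adj[[v]]) if (!(w %in% trail)) rec(w, c(trail, w))
  }
  rec(source, source)
  out
}

random_dag <- function(seed, max_nodes = 10L) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- paste0("v", seq_len(n))  # topological order by index
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.4
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e)) e <- pairs[1, , drop = FALSE]
  grn(data.frame(source = nodes[e[, 1]], target = nodes[e[, 2]],
                 sign = "+", provenance = "literature"), nodes = nodes)
}

test_that("simple-path enumeration handles the textbook shapes", {
  g1 <- grn(edge_df("S", "T"))
  expect_equal(enumerate_simple_paths(g1, "S", "T")$paths,
               list(c("S", "T")))
  diamond <- grn(rbind(edge_df("S", "A"), edge_df("A", "T"),
                       edge_df("S", "B"), edge_df("B", "T")))
  ps <- enumerate_simple_paths(diamond, "S", "T")
  expect_equal(ps$n_tp, 2L)
  expect_equal(ps$paths, list(c("S", "A", "T"), c("S", "B", "T")))
  expect_error(enumerate_simple_paths(g1, "S", "S"), "differ")
  expect_error(enumerate_simple_paths(g1, "S", "Q"), "absent")
  # a cycle off the path does not trap the search
  cyc <- grn(rbind(edge_df("S", "A"), edge_df("A", "B"),
                   edge_df("B", "A"), edge_df("A", "T")))
  expect_equal(enumerate_simple_paths(cyc, "S", "T")$n_tp, 1L)
  # sign-blind: inhibitory paths count
  inh <- grn(rbind(edge_df("S", "A", "-"), edge_df("A", "T", "-")))
  expect_equal(enumerate_simple_paths(inh, "S", "T")$n_tp, 1L)
})

test_that("enumeration equals both a recursive brute force and igraph on
           random graphs up to 10 nodes", {
  for (seed in 1:50) {
    g <- random_dag(seed)
    src <- "v1"; tgt <- paste0("v", length(g$nodes))
    ps <- enumerate_simple_paths(g, src, tgt)
    ora <- oracle_paths(g, src, tgt)
    key <- function(lst) sort(vapply(lst, paste, character(1),
                                     collapse = ";"))
    expect_equal(key(ps$paths), key(ora))
    ig <- as_igraph(g)
    igp <- igraph::all_simple_paths(ig, from = src, to = tgt,
                                    mode = "out")
    expect_equal(key(ps$paths),
                 key(lapply(igp, function(v) igraph::V(ig)$name[v])))
  }
})

test_that("the path cap and length cap behave as documented", {
  # complete DAG on 9 nodes has 128 v1 -> v9 paths
  nodes <- paste0("v", 1:9)
  e <- do.call(rbind, lapply(1:8, function(i)
    data.frame(source = nodes[i], target = nodes[(i + 1):9],
               sign = "+", provenance = "literature")))
  g <- grn(e)
  expect_error(enumerate_simple_paths(g, "v1", "v9", max_paths = 10),
               "max_paths")
  # max_len in nodes: only the direct edge survives a cap of 2
  expect_equal(enumerate_simple_paths(g, "v1", "v9", max_len = 2)$paths,
               list(c("v1", "v9")))
})

test_that("essentiality follows the path-fraction formula", {
  diamond <- grn(rbind(edge_df("S", "A"), edge_df("A", "T"),
                       edge_df("S", "B"), edge_df("B", "T")))
  ps <- enumerate_simple_paths(diamond, "S", "T")
  e <- essentiality(ps, "A")
  expect_equal(e$n_jp, 1L)
  expect_equal(e$em, 0.5)
  # the published mouse worked example: 14 of 92 paths bypass the gene
  ps2 <- table_path_set(92, c(IRF1 = 14))
  e2 <- essentiality(ps2, "IRF1")
  expect_equal(e2$n_jp, 14L)
  expect_equal(e2$em, 78 / 92)
  expect_equal(e2$em_rounded, 0.85)
  # a gene on every path scores exactly 1
  expect_equal(essentiality(ps2, "IRG1")$em, 1)
  expect_warning(off <- essentiality(ps, "Q"), "no")
  expect_true(off$off_all_paths)
})

test_that("rounding is half away from zero at 2 decimals", {
  expect_equal(round_half_away(0.845, 2), 0.85)
  expect_equal(round_half_away(0.005, 2), 0.01)
  expect_equal(round_half_away(-0.845, 2), -0.85)
  expect_equal(round_half_away(0.844999, 2), 0.84)
})

test_that("the full published ranking tables are reproduced from their
           (N_TP, N_jP) inputs", {
  mouse <- c(IRF1 = 14, CEBPB = 15, CEBPD = 18, PRDM1 = 22, STAT1 = 26,
             JUNB = 45)
  ps <- table_path_set(92, mouse)
  rk <- rank_regulators(ps)
  rk <- rk[match(names(mouse), rk$regulator), ]
  expect_equal(rk$paths_absent, unname(mouse))
  expect_equal(rk$essentiality, c(0.85, 0.84, 0.80, 0.76, 0.72, 0.51))
  expect_equal(rank_regulators(ps)$regulator[1], "IRF1")

  human <- c(IRF1 = 27, ETS2 = 44, FOS = 46, VDR = 57, RUNX1 = 65,
             RARA = 70, STAT4 = 73)
  psh <- table_path_set(100, human)
  rkh <- rank_regulators(psh)
  rkh <- rkh[match(names(human), rkh$regulator), ]
  expect_equal(rkh$essentiality,
               c(0.73, 0.56, 0.54, 0.43, 0.35, 0.30, 0.27))
  expect_equal(rank_regulators(psh)$regulator[1], "IRF1")
})

test_that("ranking excludes endpoints by default and breaks ties
           alphabetically", {
  chain <- grn(rbind(edge_df("S", "B"), edge_df("B", "A"),
                     edge_df("A", "T")))
  ps <- enumerate_simple_paths(chain, "S", "T")
  rk <- rank_regulators(ps)
  expect_equal(rk$regulator, c("A", "B"))  # tie at EM = 1, alphabetical
  expect_equal(rk$rank, c(1L, 1L))
  expect_false(any(c("S", "T") %in% rk$regulator))
  rk2 <- rank_regulators(ps, include_endpoints = TRUE)
  expect_true(all(c("S", "T") %in% rk2$regulator))
})

test_that("path-count conservation and the EM = 1 disconnection
           property hold on random graphs", {
  for (seed in 1:10) {
    g <- random_dag(seed + 500)
    src <- "v1"; tgt <- paste0("v", length(g$nodes))
    ps <- enumerate_simple_paths(g, src, tgt)
    if (ps$n_tp == 0) next
    rk <- rank_regulators(ps)
    expect_true(all(rk$essentiality_exact > 0 &
                      rk$essentiality_exact <= 1))
    # conservation: sum over genes of paths-through = total interior size
    expect_equal(sum(ps$n_tp - rk$paths_absent),
                 sum(lengths(ps$paths) - 2L))
    # removing an EM = 1 gene disconnects source from target
    ess <- rk$regulator[rk$essentiality_exact == 1]
    for (gname in ess) {
      keep <- g$edges$source != gname & g$edges$target != gname
      g2 <- grn(g$edges[keep, ], nodes = setdiff(g$nodes, gname))
      expect_equal(enumerate_simple_paths(g2, src, tgt)$n_tp, 0L)
    }
  }
})
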