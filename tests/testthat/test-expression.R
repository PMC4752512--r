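mk_mat <- function(ctrl, trt) {
  m <- cbind(ctrl, trt)
  colnames(m) <- c(paste0("c", seq_len(ncol(ctrl))),
                   paste0("t", seq_len(ncol(trt))))
  m
}
mk_cond <- function(n_ctrl, n_trt) {
  data.frame(sample = c(paste0("c", seq_len(n_ctrl)),
                        paste0("t", seq_len(n_trt))),
             condition = rep(c("control", "stimulated"),
                             c(n_ctrl, n_trt)))
}

test_that("log fold change is the stimulated-minus-control mean", {
  ctrl <- matrix(c(1, 1.2, 0.9, 5, 5, 5), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), NULL))
  trt <- ctrl + 2
  m <- mk_mat(ctrl, trt)
  lfc <- log_fold_change(m, mk_cond(3, 3))
  expect_equal(unname(lfc), c(2, 2))
  expect_equal(unname(log_fold_change(mk_mat(ctrl, ctrl),
                                      mk_cond(3, 3))), c(0, 0))
  # hand-entered toy: means 31/30 and 92/30
  m2 <- mk_mat(matrix(c(1.0, 1.2, 0.9), 1), matrix(c(3.1, 2.8, 3.3), 1))
  rownames(m2) <- "g"
  expect_equal(unname(log_fold_change(m2, mk_cond(3, 3))),
               mean(c(3.1, 2.8, 3.3)) - mean(c(1.0, 1.2, 0.9)))
})

test_that("t-test p-values match stats::t.test and the edge rules", {
  m <- mk_mat(matrix(c(1.0, 1.2, 0.9), 1), matrix(c(3.1, 2.8, 3.3), 1))
  rownames(m) <- "g"
  p <- deg_test(m, mk_cond(3, 3))
  ref <- t.test(c(3.1, 2.8, 3.3), c(1.0, 1.2, 0.9),
                var.equal = TRUE)$p.value
  expect_equal(unname(p), ref, tolerance = 1e-12)
  # zero pooled variance: equal means -> 1, different means -> 0
  same <- mk_mat(matrix(c(2, 2, 2), 1), matrix(c(2, 2, 2), 1))
  rownames(same) <- "g"
  expect_equal(unname(deg_test(same, mk_cond(3, 3))), 1)
  diff <- mk_mat(matrix(c(0, 0, 0), 1), matrix(c(1, 1, 1), 1))
  rownames(diff) <- "g"
  expect_equal(unname(deg_test(diff, mk_cond(3, 3))), 0)
  expect_error(deg_test(m, mk_cond(3, 3)[-(1:2), ]), "2 replicates")
})

test_that("DEG thresholds are closed on logFC and open on p", {
  lfc <- c(a = 2.0, b = 2.0, c = -1.0, d = 1.0, e = 0.5, f = -2.0)
  p <- c(a = 0.001, b = 0.02, c = 0.005, d = 0.01, e = 0.001, f = 0.0099)
  calls <- call_degs(lfc, p)
  expect_equal(setNames(calls$call, calls$gene_id),
               c(a = "up", b = "unchanged", c = "down",
                 d = "unchanged",  # p exactly 0.01 fails the open bound
                 e = "unchanged", f = "down"))
  # logFC exactly +1 with small p is up (closed bound)
  one <- call_degs(c(g = 1.0), c(g = 0.0005))
  expect_equal(one$call, "up")
  # order invariance
  sh <- sample(seq_along(lfc))
  calls2 <- call_degs(lfc[sh], p[sh])
  expect_equal(calls2[order(calls2$gene_id), "call"],
               calls[order(calls$gene_id), "call"])
})

test_that("booleanization maps up/down to condition states and clamps
           the stimulus", {
  degs <- data.frame(gene_id = c("U", "D", "X"), logFC = c(2, -2, 0),
                     p = c(1e-4, 1e-4, 0.5),
                     call = c("up", "down", "unchanged"))
  ph <- booleanize(degs, grn_nodes = c("U", "D", "X", "LPS"),
                   stimulus = "LPS")
  expect_equal(ph$control$state, c(D = 1, U = 0, LPS = 0)[
    order(names(c(D = 1, U = 0, LPS = 0)))])
  expect_equal(ph$stimulated$state, c(D = 0, U = 1, LPS = 1)[
    order(names(c(D = 0, U = 1, LPS = 1)))])
  # unchanged-only input constrains just the stimulus
  ph2 <- booleanize(degs[3, ], c("X", "LPS"), "LPS")
  expect_equal(names(ph2$control$state), "LPS")
  # nodes outside the network are ignored
  ph3 <- booleanize(degs, c("U", "LPS"), "LPS")
  expect_setequal(names(ph3$stimulated$state), c("U", "LPS"))
  expect_error(booleanize(rbind(degs,
    data.frame(gene_id = "LPS", logFC = 2, p = 0.001, call = "up")),
    c("U", "LPS"), "LPS"), "input")
})

test_that("planted DEGs are called and the null rate is calibrated", {
  genes <- sprintf("g%03d", 1:220)
  truth <- setNames(rep("unchanged", 220), genes)
  truth[1:10] <- "up"
  truth[11:20] <- "down"
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    ex <- gen_expression(genes, truth, n_reps = 3, lfc_effect = 4,
                         noise_sd = 0.25, seed = s)
    lfc <- log_fold_change(ex$mat, ex$conditions)
    p <- deg_test(ex$mat, ex$conditions)
    calls <- setNames(call_degs(lfc, p)$call, genes)
    if (all(calls[1:10] == "up") && all(calls[11:20] == "down"))
      hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)

  # null generator: fraction of p < 0.01 within binomial 99% bounds
  null_genes <- sprintf("n%03d", 1:400)
  n_p <- 0L; n_tot <- 0L
  for (s in 1:5) {
    ex <- gen_expression(null_genes, NULL, n_reps = 3, lfc_effect = 0,
                         noise_sd = 0.25, seed = 100 + s)
    p <- deg_test(ex$mat, ex$conditions)
    n_p <- n_p + sum(p < 0.01)
    n_tot <- n_tot + length(p)
  }
  bounds <- qbinom(c(0.005, 0.995), n_tot, 0.01)
  expect_gte(n_p, bounds[1])
  expect_lte(n_p, bounds[2])
})

test_that("probe collapsing averages redundant probe sets", {
  m <- matrix(c(1, 3, 10, 2, 4, 12), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("g", "g", "h"))
  out <- collapse_probes(m, map)
  expect_equal(out["g", ], c(s1 = 2, s2 = 3))
  expect_equal(out["h", ], c(s1 = 10, s2 = 12))
})
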