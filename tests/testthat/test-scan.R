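test_that("consensus scores exactly 1 and anti-consensus 0 on MSS", {
  lib <- gen_pwm_library(5, c(8, 14), concentration = 8, seed = 11)
  for (p in lib) {
    s <- score_window(p, consensus(p))
    expect_equal(unname(s["css"]), 1)
    expect_equal(unname(s["mss"]), 1)
    anti <- paste(c("A", "C", "G", "T")[apply(p$freq, 1, which.min)],
                  collapse = "")
    expect_equal(unname(score_window(p, anti)["mss"]), 0)
  }
  expect_error(score_window(lib[[1]], strrep("N", nrow(lib[[1]]$freq))),
               "non-ACGT")
})

test_that("scores agree with a term-by-term brute-force evaluation", {
  p <- toy_pwm()
  set.seed(42)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
               collapse = "")
    expect_equal(score_window(p, s),
                 brute_score(p$freq, strsplit(s, "")[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("hit sets equal a window-by-window brute-force scan", {
  set.seed(9)
  lib <- gen_pwm_library(3, c(6, 8), concentration = 4, seed = 5)
  for (p in lib) {
    seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    cfg <- scan_config(css_min = 0.7, mss_min = 0.7)
    hits <- scan_promoter(p, seq, cfg, gene_id = "g")
    mL <- nrow(p$freq)
    chars <- strsplit(seq, "")[[1]]
    rc <- strsplit(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq))), "")[[1]]
    expected <- 0L
    for (o in 0:(30 - mL)) {
      for (str in c("+", "-")) {
        w <- if (str == "+") chars[(o + 1):(o + mL)]
             else rc[(30 - o - mL + 1):(30 - o)]
        sc <- brute_score(p$freq, w)
        if (sc["css"] >= 0.7 && sc["mss"] >= 0.7) {
          expected <- expected + 1L
          row <- hits[hits$offset == o & hits$strand == str, ]
          expect_equal(nrow(row), 1L)
          expect_equal(c(css = row$css, mss = row$mss), sc,
                       tolerance = 1e-12)
        }
      }
    }
    expect_equal(nrow(hits), expected)
  }
})

test_that("planted consensus sites are recovered at the planted offsets", {
  lib <- gen_pwm_library(4, c(10, 12), concentration = Inf, seed = 2)
  pr <- gen_promoters(c("g1", "g2", "g3"), lib, window = c(300, 150),
                      sites_per_gene = 2, seed = 8)
  hits <- scan_library(lib, pr$sequences)
  for (i in seq_len(nrow(pr$truth))) {
    row <- pr$truth[i, ]
    found <- hits[hits$tf_id == row$tf_id & hits$gene_id == row$gene_id &
                    hits$offset == row$offset & hits$strand == row$strand, ]
    expect_equal(nrow(found), 1L)
    expect_equal(found$mss, 1)
    expect_equal(found$css, 1)
  }
})

test_that("strand involution: scanning the reverse complement swaps
           strands but keeps the hit set", {
  lib <- gen_pwm_library(2, c(8, 8), concentration = 6, seed = 13)
  set.seed(1)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  cfg <- scan_config(css_min = 0.6, mss_min = 0.6)
  for (p in lib) {
    fwd <- scan_promoter(p, seq, cfg, gene_id = "g")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    rev <- scan_promoter(p, rc, cfg, gene_id = "g")
    # a + hit at offset o maps to a - hit at L - o - mL on the rc
    mL <- nrow(p$freq)
    mapped <- data.frame(offset = 120 - rev$offset - mL,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         css = rev$css, mss = rev$mss)
    o1 <- fwd[order(fwd$offset, fwd$strand), c("offset", "strand", "css", "mss")]
    o2 <- mapped[order(mapped$offset, mapped$strand), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2, tolerance = 1e-12)
  }
})

test_that("raising thresholds never adds hits; impossible thresholds
           return an empty set", {
  lib <- gen_pwm_library(2, c(8, 10), concentration = 4, seed = 17)
  set.seed(2)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  p <- lib[[1]]
  lo <- scan_promoter(p, seq, scan_config(0.5, 0.5), "g")
  hi <- scan_promoter(p, seq, scan_config(0.8, 0.8), "g")
  expect_true(all(paste(hi$offset, hi$strand) %in%
                    paste(lo$offset, lo$strand)))
  none <- scan_promoter(p, seq, scan_config(1.01, 1.01), "g")
  expect_equal(nrow(none), 0L)
})

test_that("windows containing ambiguous bases are skipped", {
  p <- gen_pwm_library(1, c(6, 6), concentration = Inf, seed = 1)[[1]]
  seq <- paste0(consensus(p), "NNN", consensus(p))
  hits <- scan_promoter(p, seq, scan_config(0.9, 0.9), "g")
  expect_equal(hits$offset[hits$strand == "+"], c(0L, 9L))
})

test_that("upstream network collapses multiple hits to one edge", {
  hits <- data.frame(tf_id = c("A", "A", "A", "B"),
                     gene_id = c("G", "G", "G", "G"),
                     offset = c(1, 5, 9, 2), strand = "+",
                     css = 1, mss = 1)
  g <- build_upstream_network(hits)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(g$nodes, c("A", "B", "G"))
  expect_true(all(g$edges$sign == "?"))
  expect_true(all(g$edges$provenance == "tfbs"))
  expect_equal(nrow(build_upstream_network(hits[0, ])$edges), 0L)
})
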