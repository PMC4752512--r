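#' Generate promoter sequences with planted binding sites
#'
#' Draws i.i.d. background sequence with configurable GC content over the
#' promoter window and plants transcription-factor binding sites as exact
#' consensus strings of the chosen PWMs (optionally with a fixed number of
#' point mutations) at recorded offsets and strands. A minus-strand plant
#' inserts the reverse complement of the consensus into the forward
#' sequence. Plants never overlap each other or run past the sequence end:
#' positions are redrawn, never truncated.
#'
#' @param gene_ids Character vector of gene ids (one promoter each).
#' @param pwms A `pwm_library`.
#' @param window Integer pair (upstream, downstream) around the TSS;
#'   default c(2000, 1000), i.e. 3000 bp sequences.
#' @param site_plan Data frame with columns `tf_id`, `gene_id`: one row per
#'   site to plant. Alternatively use `sites_per_gene` to plant random TFs.
#' @param sites_per_gene Integer; ignored when `site_plan` is given.
#' @param background_gc GC fraction of the background, in (0, 1).
#' @param mutations Point mutations applied to each planted consensus
#'   (default 0: exact plants).
#' @param plus_strand_only Plant on the + strand only (default FALSE).
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector, names
#'   `gene|window=-U:+D|strand=+`), `truth` (data frame `tf_id`,
#'   `gene_id`, `offset` 0-based from window start, `strand`).
#' @export
gen_promoters <- function(gene_ids, pwms, window = c(2000L, 1000L),
                          site_plan = NULL, sites_per_gene = 1L,
                          background_gc = 0.5, mutations = 0L,
                          plus_strand_only = FALSE, seed = 1L) {
  stopifnot(length(window) == 2, all(window > 0),
            background_gc > 0, background_gc < 1)
  L <- sum(window)
  withr::with_seed(as.integer(seed), {
    probs <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
               G = background_gc / 2, T = (1 - background_gc) / 2)
    if (is.null(site_plan)) {
      site_plan <- do.call(rbind, lapply(gene_ids, function(g) {
        if (sites_per_gene == 0L) return(NULL)
        data.frame(tf_id = sample(names(pwms), sites_per_gene,
                                  replace = TRUE),
                   gene_id = g, stringsAsFactors = FALSE)
      }))
    }
    seqs <- setNames(vapply(gene_ids, function(g)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
            collapse = ""), character(1)), gene_ids)
    truth <- data.frame(tf_id = character(), gene_id = character(),
                        offset = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    occupied <- setNames(rep(list(integer()), length(gene_ids)), gene_ids)
    if (!is.null(site_plan) && nrow(site_plan)) {
      for (i in seq_len(nrow(site_plan))) {
        tf <- site_plan$tf_id[i]; g <- site_plan$gene_id[i]
        cons <- consensus(pwms[[tf]])
        if (mutations > 0L) {
          ch <- strsplit(cons, "")[[1]]
          pos <- sample(length(ch), min(mutations, length(ch)))
          for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
          cons <- paste(ch, collapse = "")
        }
        mL <- nchar(cons)
        strand <- if (plus_strand_only) "+" else sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cons else revcomp(cons)
        # redraw until the plant fits without overlapping a previous one
        for (try in 1:1000) {
          off <- sample.int(L - mL + 1L, 1L) - 1L  # 0-based
          span <- (off + 1L):(off + mL)
          if (!any(span %in% occupied[[g]])) break
          if (try == 1000) stop("cannot place site without overlap")
        }
        occupied[[g]] <- c(occupied[[g]], span)
        substr(seqs[[g]], off + 1L, off + mL) <- ins
        truth <- rbind(truth, data.frame(
          tf_id = tf, gene_id = g, offset = off, strand = strand,
          stringsAsFactors = FALSE))
      }
    }
    names(seqs) <- sprintf("%s|window=-%d:+%d|strand=+", gene_ids,
                           window[1], window[2])
    list(sequences = seqs, truth = truth)
  })
}

#' Generate a signed literature-style stimulus cascade
#'
#' Builds an acyclic signed network downstream of a stimulus node: TFs are
#' assigned to layers 1..`depth`, each node gets at least one parent in the
#' previous layer, and each edge is inhibitory with probability
#' `sign_mix`. The stimulus has in-degree 0 and out-degree >= 1.
#'
#' @param tfs Non-empty character vector of TF ids.
#' @param stimulus Stimulus node id.
#' @param depth Number of layers (>= 1).
#' @param sign_mix Fraction of inhibitory edges in (0, 1); 0 gives an
#'   all-activating network.
#' @param extra_edge_p Probability of an extra shortcut edge from any
#'   earlier layer (default 0.2).
#' @param seed Integer seed.
#' @return A `grn` with provenance `literature`.
#' @export
gen_literature_network <- function(tfs, stimulus = "LPS", depth = 1L,
                                   sign_mix = 0.2, extra_edge_p = 0.2,
                                   seed = 1L) {
  if (!length(tfs)) stop("tf list must be non-empty")
  stopifnot(depth >= 1, sign_mix >= 0, sign_mix <= 1)
  depth <- min(as.integer(depth), length(tfs))  # every layer non-empty
  withr::with_seed(as.integer(seed), {
    layer <- sort(rep_len(seq_len(depth), length(tfs)))
    tfs <- sample(tfs)  # random layer assignment
    edges <- list()
    draw_sign <- function() if (runif(1) < sign_mix) "-" else "+"
    for (i in seq_along(tfs)) {
      parents <- if (layer[i] == 1L) stimulus else {
        prev <- tfs[layer == layer[i] - 1L]
        sample(prev, 1L)
      }
      for (p in parents)
        edges[[length(edges) + 1L]] <- c(p, tfs[i], draw_sign())
      if (layer[i] > 1L && runif(1) < extra_edge_p) {
        anc <- c(stimulus, tfs[layer < layer[i] - 1L])
        a <- sample(anc, 1L)
        edges[[length(edges) + 1L]] <- c(a, tfs[i], draw_sign())
      }
    }
    e <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    names(e) <- c("source", "target", "sign")
    e$provenance <- "literature"
    grn(e, nodes = c(stimulus, tfs))
  })
}

#' Generate a two-condition log-normal expression matrix
#'
#' Log2-scale expression with per-gene baselines, a mean shift of
#' `+lfc_effect` (up) or `-lfc_effect` (down) in the stimulated condition
#' for planted DEGs, and i.i.d. Gaussian noise.
#'
#' @param genes Character vector of gene ids.
#' @param deg_truth Named character vector over `genes` with values `up`,
#'   `down` or `unchanged`; missing genes default to `unchanged`.
#' @param n_reps Replicates per condition (>= 2).
#' @param lfc_effect Planted absolute log2 fold change (>= 0).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return List: `mat` (genes x 2*n_reps matrix), `conditions` (data frame
#'   `sample`, `condition`).
#' @export
gen_expression <- function(genes, deg_truth = NULL, n_reps = 3L,
                           lfc_effect = 4, noise_sd = 0.25, seed = 1L) {
  if (n_reps < 2L) stop("need n_reps >= 2 (variance undefined otherwise)")
  stopifnot(lfc_effect >= 0, noise_sd > 0)
  truth <- setNames(rep("unchanged", length(genes)), genes)
  if (!is.null(deg_truth)) {
    bad <- setdiff(unique(deg_truth), c("up", "down", "unchanged"))
    if (length(bad)) stop("bad deg_truth value(s): ",
                          paste(bad, collapse = ", "))
    truth[intersect(names(deg_truth), genes)] <-
      deg_truth[intersect(names(deg_truth), genes)]
  }
  withr::with_seed(as.integer(seed), {
    base <- runif(length(genes), 6, 10)
    shift <- ifelse(truth == "up", lfc_effect,
                    ifelse(truth == "down", -lfc_effect, 0))
    samples <- c(sprintf("ctrl_%d", seq_len(n_reps)),
                 sprintf("stim_%d", seq_len(n_reps)))
    mat <- matrix(rnorm(length(genes) * 2 * n_reps, sd = noise_sd),
                  length(genes), 2 * n_reps,
                  dimnames = list(genes, samples))
    mat <- mat + base
    mat[, (n_reps + 1):(2 * n_reps)] <-
      mat[, (n_reps + 1):(2 * n_reps)] + shift
    conditions <- data.frame(
      sample = samples,
      condition = rep(c("control", "stimulated"), each = n_reps),
      stringsAsFactors = FALSE)
    list(mat = mat, conditions = conditions)
  })
}

#' Generate a complete synthetic pipeline scenario
#'
#' Produces every input the pipeline consumes, with planted ground truth:
#' a PWM library; promoters for the target gene and decoy genes, with the
#' designated regulator's consensus planted on the target promoter and
#' each decoy TF's consensus on one decoy promoter; a literature cascade
#' stimulus -> TFs (the regulator's edge forced activating); and a
#' two-condition expression matrix whose planted DEG calls are consistent
#' with the cascade signs. By construction the regulator lies on every
#' stimulus-to-target path of the planted network.
#'
#' @param config List overriding any of the defaults: `stimulus` ("LPS"),
#'   `target` ("IRG1"), `n_tfs` (6; the first TF is the regulator),
#'   `window` (c(2000, 1000)), `motif_len_range` (c(12, 16)),
#'   `concentration` (50), `background_gc` (0.5), `sign_mix` (0.3, decoys
#'   only), `n_reps` (3), `lfc_effect` (4), `noise_sd` (0.25),
#'   `n_null_genes` (20, unregulated background genes in the expression
#'   matrix).
#' @param out_dir Optional directory; when given, writes promoters.fasta,
#'   pwms.transfac, literature.tsv, expression.tsv, conditions.tsv and
#'   truth.json.
#' @param seed Integer seed (all component seeds derive from it).
#' @return List: `pwms`, `promoters` (sequences + plant truth),
#'   `literature` (`grn`), `expression` (mat + conditions), `truth`
#'   (`scenario_truth` list: `planted_sites`, `true_regulators`,
#'   `true_signs`, `deg_truth`, `seed`), `config`.
#' @export
gen_full_scenario <- function(config = list(), out_dir = NULL, seed = 1L) {
  cfg <- utils::modifyList(
    list(stimulus = "LPS", target = "IRG1", n_tfs = 6L,
         window = c(2000L, 1000L), motif_len_range = c(12L, 16L),
         concentration = 50, background_gc = 0.5, sign_mix = 0.3,
         n_reps = 3L, lfc_effect = 4, noise_sd = 0.25,
         n_null_genes = 20L), config)
  if (cfg$n_tfs < 1L)
    stop("scenario needs at least one TF to regulate the target")
  seed <- as.integer(seed)
  pwms <- gen_pwm_library(cfg$n_tfs, cfg$motif_len_range,
                          cfg$concentration, seed = seed)
  tf_ids <- names(pwms)
  regulator <- tf_ids[1]
  decoys <- tf_ids[-1]
  decoy_genes <- if (length(decoys)) sprintf("G%02d", seq_along(decoys))
                 else character()

  # one site per gene: regulator on the target, each decoy TF on one decoy
  plan <- data.frame(tf_id = c(regulator, decoys),
                     gene_id = c(cfg$target, decoy_genes),
                     stringsAsFactors = FALSE)
  promoters <- gen_promoters(c(cfg$target, decoy_genes), pwms,
                             window = cfg$window, site_plan = plan,
                             background_gc = cfg$background_gc,
                             seed = seed + 1L)

  literature <- gen_literature_network(tf_ids, cfg$stimulus, depth = 1L,
                                       sign_mix = cfg$sign_mix,
                                       seed = seed + 2L)
  # the regulator must transmit the stimulus: force its edge activating
  li <- literature$edges$target == regulator
  literature$edges$sign[li] <- "+"

  # DEG truth consistent with the cascade: a gene is up iff the signal
  # reaches it through activating edges under stimulation
  stim_sign <- setNames(literature$edges$sign,
                        literature$edges$target)[tf_ids]
  tf_truth <- setNames(ifelse(stim_sign == "+", "up", "unchanged"), tf_ids)
  gene_truth <- setNames(
    ifelse(stim_sign[match(plan$tf_id, tf_ids)] == "+", "up", "unchanged"),
    plan$gene_id)
  null_genes <- if (cfg$n_null_genes > 0L)
    sprintf("N%03d", seq_len(cfg$n_null_genes)) else character()
  all_genes <- c(cfg$target, decoy_genes, tf_ids, null_genes)
  deg_truth <- c(gene_truth, tf_truth,
                 setNames(rep("unchanged", length(null_genes)), null_genes))
  expression <- gen_expression(all_genes, deg_truth, n_reps = cfg$n_reps,
                               lfc_effect = cfg$lfc_effect,
                               noise_sd = cfg$noise_sd, seed = seed + 3L)

  true_signs <- c(
    setNames(literature$edges$sign,
             paste(literature$edges$source, literature$edges$target,
                   sep = "->")),
    setNames(rep("+", nrow(plan)),
             paste(plan$tf_id, plan$gene_id, sep = "->")))
  truth <- structure(list(
    planted_sites = promoters$truth,
    true_regulators = regulator,
    true_signs = as.list(true_signs),
    deg_truth = as.list(deg_truth),
    seed = seed), class = "scenario_truth")

  out <- list(pwms = pwms, promoters = promoters, literature = literature,
              expression = expression, truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(promoters$sequences, file.path(out_dir, "promoters.fasta"))
    write_transfac(pwms, file.path(out_dir, "pwms.transfac"))
    write_edge_list(literature, file.path(out_dir, "literature.tsv"))
    write_expression(expression$mat, expression$conditions,
                     file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "conditions.tsv"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write scenario ground truth to JSON
#' @param truth A `scenario_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read scenario ground truth from JSON
#' @param path JSON path.
#' @return A `scenario_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_sites <- as.data.frame(x$planted_sites,
                                   stringsAsFactors = FALSE)
  x$true_signs <- as.list(x$true_signs)
  x$deg_truth <- as.list(x$deg_truth)
  x$seed <- as.integer(x$seed)
  structure(x, class = "scenario_truth")
}
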