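#' Scan configuration
#'
#' Thresholds and window geometry for the MATCH-style promoter scan. The
#' defaults are the dual similarity threshold of 0.90 on both the core and
#' matrix scores and the -2000/+1000 promoter window around the TSS.
#'
#' @param css_min,mss_min Minimum core / matrix similarity in \[0, 1\].
#' @param window Integer pair (upstream, downstream) of the promoter window.
#' @param scan_both_strands Scan the reverse complement as well?
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(css_min = 0.90, mss_min = 0.90,
                        window = c(2000L, 1000L),
                        scan_both_strands = TRUE) {
  # thresholds above 1 are tolerated (they simply retain nothing)
  stopifnot(css_min >= 0, mss_min >= 0, length(window) == 2,
            all(window > 0))
  structure(list(css_min = css_min, mss_min = mss_min,
                 window = as.integer(window),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "scan_config")
}

seq_to_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  match(chars, DNA_BASES)  # NA for non-ACGT
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Weighted sums of the information-vector score for one motif span.
# rows: positions of the pwm to use (full matrix or the core window).
span_min_max <- function(pwm, rows) {
  w <- pwm$info[rows]
  f <- pwm$freq[rows, , drop = FALSE]
  c(min = sum(w * apply(f, 1, min)), max = sum(w * apply(f, 1, max)))
}

#' Core and matrix similarity of one sequence window
#'
#' Scores a window of exactly motif length against a PWM with the
#' information-vector-weighted min-max normalization:
#' `mss = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, seq_i)` and Min/Max are the analogous sums
#' over per-position minimum/maximum frequencies. The core similarity `css`
#' is the same quantity restricted to the 5-position high-information core.
#' Degenerate spans with `Max == Min` score 1. Both scores are clipped to
#' \[0, 1\].
#'
#' @param pwm A `pwm`.
#' @param seq Character scalar of exactly motif length over A/C/G/T.
#' @return Named numeric vector `c(css, mss)`.
#' @export
score_window <- function(pwm, seq) {
  codes <- seq_to_codes(seq)
  if (length(codes) != nrow(pwm$freq))
    stop("sequence length ", length(codes), " != motif length ",
         nrow(pwm$freq))
  if (anyNA(codes))
    stop("window contains non-ACGT characters")
  score_span <- function(rows) {
    mm <- span_min_max(pwm, rows)
    cur <- sum(pwm$info[rows] *
                 pwm$freq[cbind(rows, codes[rows])])
    if (mm["max"] - mm["min"] <= 0) return(1)
    min(max((cur - mm["min"]) / (mm["max"] - mm["min"]), 0), 1)
  }
  core <- pwm$core_start:(pwm$core_start + CORE_WIDTH - 1L)
  c(css = unname(score_span(core)),
    mss = unname(score_span(seq_len(nrow(pwm$freq)))))
}

# Vectorized scores of every window of `codes` on one strand.
# Returns data.frame(offset0, css, mss) for valid (all-ACGT) windows.
scan_codes <- function(pwm, codes) {
  L <- length(codes); mL <- nrow(pwm$freq)
  if (L < mL) return(data.frame(offset0 = integer(), css = numeric(),
                                mss = numeric()))
  n_win <- L - mL + 1L
  wfreq <- pwm$info * pwm$freq  # positions x 4
  cur_full <- numeric(n_win)
  cur_core <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  core <- pwm$core_start:(pwm$core_start + CORE_WIDTH - 1L)
  for (i in seq_len(mL)) {
    b <- codes[i:(i + n_win - 1L)]
    miss <- is.na(b)
    if (any(miss)) valid <- valid & !miss
    v <- wfreq[i, ifelse(miss, 1L, b)]
    v[miss] <- 0
    cur_full <- cur_full + v
    if (i %in% core) cur_core <- cur_core + v
  }
  mm_full <- span_min_max(pwm, seq_len(mL))
  mm_core <- span_min_max(pwm, core)
  norm <- function(cur, mm) {
    if (mm["max"] - mm["min"] <= 0) return(rep(1, length(cur)))
    pmin(pmax((cur - mm["min"]) / (mm["max"] - mm["min"]), 0), 1)
  }
  data.frame(offset0 = which(valid) - 1L,
             css = norm(cur_core, mm_core)[valid],
             mss = norm(cur_full, mm_full)[valid])
}

#' Scan a promoter sequence with one PWM
#'
#' Slides the PWM over every window of the forward strand and (by default)
#' the reverse complement, mapping minus-strand hits back to forward-strand
#' window-start coordinates, and retains windows with both `css >= css_min`
#' and `mss >= mss_min`. Offsets are 0-based relative to the window start.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param pwm A `pwm`.
#' @param seq Promoter sequence (character scalar).
#' @param cfg A [scan_config()].
#' @param gene_id Gene identifier recorded in the hits.
#' @return Data frame of hits: `tf_id`, `gene_id`, `offset` (0-based),
#'   `strand`, `css`, `mss`, sorted by offset then strand.
#' @export
scan_promoter <- function(pwm, seq, cfg = scan_config(), gene_id = NA_character_) {
  seq <- toupper(seq)
  mL <- nrow(pwm$freq)
  fwd <- scan_codes(pwm, seq_to_codes(seq))
  fwd$strand <- "+"
  hits <- fwd
  if (cfg$scan_both_strands) {
    L <- nchar(seq)
    rev <- scan_codes(pwm, seq_to_codes(revcomp(seq)))
    if (nrow(rev)) {
      # position o (0-based) on the reverse complement covers forward
      # window starting at L - o - mL
      rev$offset0 <- L - rev$offset0 - mL
      rev$strand <- "-"
      hits <- rbind(hits, rev)
    }
  }
  hits <- hits[hits$css >= cfg$css_min & hits$mss >= cfg$mss_min, ,
               drop = FALSE]
  hits <- hits[order(hits$offset0, hits$strand), , drop = FALSE]
  data.frame(tf_id = rep(pwm$tf_id, nrow(hits)),
             gene_id = rep(gene_id, nrow(hits)),
             offset = hits$offset0, strand = hits$strand,
             css = hits$css, mss = hits$mss,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a set of promoters with a PWM library
#'
#' @param lib A `pwm_library`.
#' @param seqs Named character vector or `DNAStringSet` of promoter
#'   sequences; names are gene ids (anything after `|` in a FASTA header is
#'   dropped).
#' @param cfg A [scan_config()].
#' @return Combined hits data frame (see [scan_promoter()]).
#' @export
scan_library <- function(lib, seqs, cfg = scan_config()) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  nm <- sub("\\|.*$", "", names(seqs))
  out <- list()
  for (p in lib)
    for (i in seq_along(seqs))
      out[[length(out) + 1L]] <- scan_promoter(p, seqs[[i]], cfg,
                                               gene_id = nm[i])
  do.call(rbind, out)
}

#' Build the unsigned upstream network from scan hits
#'
#' Collapses all retained binding-site hits of a TF on a gene's promoter to
#' a single directed, unsigned edge TF -> gene with provenance `tfbs`.
#'
#' @param hits Hits data frame from [scan_promoter()]/[scan_library()].
#' @return A `grn` whose nodes are the TFs and genes with at least one hit.
#' @export
build_upstream_network <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(grn())
  pairs <- unique(hits[, c("tf_id", "gene_id")])
  grn(data.frame(source = pairs$tf_id, target = pairs$gene_id,
                 sign = "?", provenance = "tfbs",
                 stringsAsFactors = FALSE))
}
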