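#' @importFrom stats rgamma runif rnorm pt setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")
CORE_WIDTH <- 5L

#' Construct a position weight matrix (PWM)
#'
#' A PWM describes a transcription factor's binding motif as per-position
#' nucleotide frequencies. On construction the per-position information
#' vector and the 5-position high-information core are derived; both are
#' used by the MATCH-style similarity scores.
#'
#' @param tf_id Identifier of the transcription factor.
#' @param freq Numeric matrix, positions x 4, columns A, C, G, T; each row
#'   must be a frequency distribution (non-negative, summing to 1 within
#'   1e-9). Matrices of raw counts should be normalized first (the TRANSFAC
#'   reader does this on load).
#' @return An object of class `pwm`: a list with elements `tf_id`, `freq`,
#'   `info` (per-position information vector) and `core_start` (1-based
#'   index of the 5-position core window).
#' @seealso [information_vector()], [score_window()], [read_transfac()]
#' @export
pwm <- function(tf_id, freq) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L)
    stop("PWM frequency matrix must have 4 columns (A, C, G, T)")
  colnames(freq) <- DNA_BASES
  if (nrow(freq) < CORE_WIDTH)
    stop("PWM for ", tf_id, " has length ", nrow(freq),
         "; at least ", CORE_WIDTH,
         " positions are required for the 5-position core")
  if (any(freq < 0))
    stop("PWM frequencies must be non-negative")
  info <- information_vector(freq)
  structure(
    list(tf_id = as.character(tf_id), freq = freq, info = info,
         core_start = core_start(info)),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: %d positions, core at %d-%d\n", x$tf_id,
              nrow(x$freq), x$core_start, x$core_start + CORE_WIDTH - 1L))
  invisible(x)
}

#' Per-position information vector of a PWM
#'
#' For position i with base frequencies f(i, b), the information content is
#' I(i) = sum_b f(i, b) * ln(4 f(i, b)), with 0 * ln 0 taken as 0. A fully
#' degenerate position (one base with frequency 1) scores ln 4; a uniform
#' position scores 0. The vector weights motif positions in the similarity
#' scores so conserved positions dominate.
#'
#' @param freq Frequency matrix, positions x 4; rows must sum to 1 within
#'   1e-9.
#' @return Numeric vector of length `nrow(freq)`.
#' @export
information_vector <- function(freq) {
  freq <- as.matrix(freq)
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9))
    stop("PWM rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")")
  term <- freq * log(4 * freq)
  term[freq == 0] <- 0
  rowSums(term)
}

# Leftmost 5-window maximizing summed information.
core_start <- function(info) {
  n <- length(info)
  sums <- vapply(seq_len(n - CORE_WIDTH + 1L),
                 function(i) sum(info[i:(i + CORE_WIDTH - 1L)]), numeric(1))
  which.max(sums)  # which.max is leftmost on ties
}

#' Consensus sequence of a PWM
#'
#' The per-position most frequent base (leftmost of A, C, G, T on exact
#' frequency ties).
#'
#' @param x A `pwm` object.
#' @return A character scalar over A/C/G/T.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$freq, 1, which.max)], collapse = "")
}

#' Generate a synthetic PWM library
#'
#' Draws `n_tf` motifs with lengths sampled uniformly from
#' `motif_len_range`. Each position's frequency vector is Dirichlet with
#' parameter `concentration` on a randomly chosen consensus base and 1 on
#' the other three, so larger `concentration` gives sharper motifs;
#' `concentration = Inf` yields consensus-only (one-hot) matrices.
#'
#' @param n_tf Number of matrices (>= 1).
#' @param motif_len_range Integer pair (min, max) of motif lengths; minimum 6.
#' @param concentration Positive Dirichlet concentration on the consensus
#'   base; `Inf` allowed.
#' @param seed Integer seed; the call is a pure function of its arguments.
#' @return A named list of `pwm` objects (class `pwm_library`), names
#'   `TF01`, `TF02`, ...
#' @export
gen_pwm_library <- function(n_tf, motif_len_range = c(12L, 16L),
                            concentration = 50, seed = 1L) {
  stopifnot(n_tf >= 1, length(motif_len_range) == 2,
            concentration > 0)
  motif_len_range <- as.integer(motif_len_range)
  if (min(motif_len_range) < CORE_WIDTH)
    stop("motif length ", min(motif_len_range), " is below the ",
         CORE_WIDTH, "-position core width required of every PWM")
  withr::with_seed(as.integer(seed), {
    lib <- lapply(seq_len(n_tf), function(i) {
      lens <- seq(motif_len_range[1], motif_len_range[2])
      len <- lens[sample.int(length(lens), 1L)]
      cons <- sample.int(4L, len, replace = TRUE)
      freq <- matrix(0, len, 4L, dimnames = list(NULL, DNA_BASES))
      if (is.infinite(concentration)) {
        freq[cbind(seq_len(len), cons)] <- 1
      } else {
        for (p in seq_len(len)) {
          alpha <- rep(1, 4L)
          alpha[cons[p]] <- concentration
          g <- rgamma(4L, shape = alpha)
          # guarantee the sampled consensus base is the argmax
          if (which.max(g) != cons[p]) {
            mx <- which.max(g)
            g[c(mx, cons[p])] <- g[c(cons[p], mx)]
          }
          freq[p, ] <- g / sum(g)
        }
      }
      pwm(sprintf("TF%02d", i), freq)
    })
    names(lib) <- vapply(lib, `[[`, character(1), "tf_id")
    structure(lib, class = "pwm_library")
  })
}

#' Read a TRANSFAC-format matrix file
#'
#' Parses the conventional flat format: an `ID` line naming the factor, a
#' `P0` (or `PO`) header over A C G T, numbered count rows, and a `//`
#' record terminator. Counts are row-normalized to frequencies on load.
#'
#' @param path Path to the matrix file.
#' @return A `pwm_library` (named list of `pwm`).
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  lib <- list()
  id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (!length(rows)) stop("TRANSFAC record ", id, " has no count rows")
    m <- do.call(rbind, rows)
    m <- m / rowSums(m)
    lib[[id]] <<- pwm(id, m)
    id <<- NULL
    rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || grepl("^(XX|BF|P[0O]\\b)", ln)) next
    if (grepl("^ID\\s", ln)) {
      flush()
      id <- sub("^ID\\s+", "", ln)
    } else if (grepl("^//", ln)) {
      flush()
    } else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 5L) stop("malformed TRANSFAC count row: ", ln)
      rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
    }
  }
  flush()
  structure(lib, class = "pwm_library")
}

#' Write a PWM library in TRANSFAC matrix format
#'
#' Frequencies are written scaled to counts out of 100 (two decimals kept),
#' which the reader renormalizes on load.
#'
#' @param lib A `pwm_library` or list of `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in lib) {
    writeLines(paste("ID", p$tf_id), con)
    writeLines("P0\tA\tC\tG\tT", con)
    cnt <- round(p$freq * 100, 2)
    for (i in seq_len(nrow(cnt)))
      writeLines(sprintf("%02d\t%s", i,
                         paste(format(cnt[i, ], trim = TRUE),
                               collapse = "\t")), con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
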