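# Position-weight-matrix machinery: log-odds scoring, exact score
# distribution by column-wise convolution, and a two-strand scanner over
# peak sequences.

#' Log2-odds position weight matrix from count matrix
#'
#' Adds a pseudocount to the counts, converts each column to probabilities,
#' and takes log2 against the background composition.
#'
#' @param pfm A `"pfm"` object (see [read_jaspar_pfm()]).
#' @param background Length-4 probability vector (A, C, G, T), summing to 1,
#'   all positive. Default uniform.
#' @param pseudocount Added to every count cell (default 1).
#' @return A 4 x width numeric matrix of log2-odds scores (rows A, C, G, T).
#' @export
pwm_matrix <- function(pfm, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  cnt <- pfm$counts + pseudocount
  probs <- sweep(cnt, 2, colSums(cnt), "/")
  log2(probs / background)
}

#' Score threshold for a PWM at a given match p-value
#'
#' Computes the exact distribution of the log2-odds score of a random
#' sequence drawn i.i.d. from the background, by convolving the per-column
#' score distributions on a discretized grid (bin width at most 0.01 bits),
#' and returns the smallest attainable score `t` with
#' `P(score >= t) <= p_cutoff`. If even the maximal score is attained with
#' probability above `p_cutoff` (possible for short motifs), `Inf` is
#' returned and nothing can match.
#'
#' @inheritParams pwm_matrix
#' @param p_cutoff Match p-value in (0, 1); default `5e-5`.
#' @param bin Discretization bin width in bits (default 0.001, must be
#'   <= 0.01).
#' @return Threshold score in bits (possibly `-Inf` for `p_cutoff = 1`).
#' @export
pwm_threshold <- function(pfm, background = rep(0.25, 4), p_cutoff = 5e-5,
                          pseudocount = 1, bin = 0.001) {
  if (!(p_cutoff > 0 && p_cutoff <= 1)) {
    stop("domain error: p_cutoff must be in (0, 1]")
  }
  stopifnot(bin > 0, bin <= 0.01)
  M <- pwm_matrix(pfm, background, pseudocount)
  # integer score grid: column scores rounded to multiples of `bin`
  Mi <- round(M / bin)
  w <- ncol(Mi)
  # convolve column by column
  cur_lo <- 0
  dist <- c(1)  # P(score sum == cur_lo) = 1 before any column
  for (j in seq_len(w)) {
    col <- Mi[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(dist) - 1 + max(col)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- col[b] - min(col)
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    cur_lo <- new_lo
  }
  # upper tail: smallest attained score with tail probability <= p_cutoff
  attained <- which(dist > 0)
  scores <- (attained - 1 + cur_lo) * bin
  tail_p <- rev(cumsum(rev(dist[attained])))
  ok <- which(tail_p <= p_cutoff)
  if (!length(ok)) return(Inf)
  scores[ok[1]]
}

# Encode a sequence as indices 1..4 (A,C,G,T), NA for anything else (N etc.)
.encode_seq <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  match(v, c("A", "C", "G", "T"))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Score every offset of an encoded sequence against a log-odds matrix.
# Windows containing NA (N bases) score -Inf.
.scan_scores <- function(idx, M) {
  w <- ncol(M)
  L <- length(idx)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1
  sc <- numeric(n_off)
  ok <- !logical(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1)]
    nas <- is.na(b)
    ok <- ok & !nas
    contrib <- M[cbind(b, j)]
    contrib[nas] <- 0
    sc <- sc + contrib
  }
  sc[!ok] <- -Inf
  sc
}

#' Scan peak sequences for motif matches
#'
#' Extracts each peak's sequence from the genome, scores every offset on both
#' strands against each PWM, and reports all positions scoring at or above
#' the motif's threshold. Positions whose window contains an `N` never match.
#' Minus-strand hits are reported at the forward-strand offset of the matched
#' window.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param peaks A `"narrowpeak"` data frame (0-based half-open coordinates).
#' @param pfms List of `"pfm"` objects.
#' @param background,pseudocount Passed to [pwm_matrix()].
#' @param p_cutoff Match p-value passed to [pwm_threshold()]; ignored when
#'   `thresholds` is given.
#' @param thresholds Optional named numeric vector of score thresholds per
#'   motif id, overriding `p_cutoff`.
#' @return A `data.frame` of hits: `peak_name`, `chrom`, `peak_start`,
#'   `peak_end`, `motif_id`, `offset` (0-based within the peak), `strand`,
#'   `score`.
#' @export
scan_motifs <- function(genome, peaks, pfms, background = rep(0.25, 4),
                        pseudocount = 1, p_cutoff = 5e-5, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- vapply(pfms, function(p) {
      pwm_threshold(p, background, p_cutoff, pseudocount)
    }, numeric(1))
    names(thresholds) <- vapply(pfms, `[[`, character(1), "motif_id")
  }
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("coordinate error: chromosome ", chrom, " not in genome")
    }
    if (peaks$start[i] < 0 || peaks$end[i] > chrlen[[chrom]]) {
      stop("coordinate error: peak ", peaks$name[i], " outside ", chrom)
    }
    s <- as.character(Biostrings::subseq(genome[[chrom]],
                                         start = peaks$start[i] + 1L,
                                         end = peaks$end[i]))
    fwd <- .encode_seq(s)
    rev_idx <- .encode_seq(.revcomp(s))
    L <- nchar(s)
    for (p in pfms) {
      thr <- thresholds[[p$motif_id]]
      if (!is.finite(thr) && thr > 0) next  # Inf: unreachable
      M <- pwm_matrix(p, background, pseudocount)
      wdt <- ncol(M)
      sc_f <- .scan_scores(fwd, M)
      sc_r <- .scan_scores(rev_idx, M)
      f_at <- which(sc_f >= thr)
      r_at <- which(sc_r >= thr)
      if (length(f_at)) {
        hits[[length(hits) + 1]] <- data.frame(
          peak_name = peaks$name[i], chrom = chrom,
          peak_start = peaks$start[i], peak_end = peaks$end[i],
          motif_id = p$motif_id, offset = f_at - 1L, strand = "+",
          score = sc_f[f_at], stringsAsFactors = FALSE)
      }
      if (length(r_at)) {
        # offset o' on the reverse-complement maps to forward L - o' - w
        hits[[length(hits) + 1]] <- data.frame(
          peak_name = peaks$name[i], chrom = chrom,
          peak_start = peaks$start[i], peak_end = peaks$end[i],
          motif_id = p$motif_id, offset = L - (r_at - 1L) - wdt,
          strand = "-", score = sc_r[r_at], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(peak_name = character(0), chrom = character(0),
                      peak_start = integer(0), peak_end = integer(0),
                      motif_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
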