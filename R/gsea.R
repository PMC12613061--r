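# Ranked gene set enrichment: weighted Kolmogorov-Smirnov running sum,
# gene-permutation null, normalized enrichment score.

#' Build a ranked gene list
#'
#' Sorts genes by decreasing ranking metric (log2 fold change), breaking ties
#' by symbol so the ordering is deterministic.
#'
#' @param genes Character vector of unique (harmonized) gene symbols.
#' @param metric Numeric ranking metric, same length, finite.
#' @return A named numeric vector sorted in decreasing metric order.
#' @export
ranked_list <- function(genes, metric) {
  if (anyDuplicated(genes)) stop("ranked list requires unique gene symbols")
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  ord <- order(-metric, genes)
  setNames(metric[ord], genes[ord])
}

#' @describeIn ranked_list Ranked list from a DEG table, using log2fc.
#' @param table A [deg_table()].
#' @export
ranked_from_deg <- function(table) {
  ranked_list(table$gene, table$log2fc)
}

#' GSEA enrichment score
#'
#' Walks the ranked list accumulating `|metric|^weight / NR` at each gene-set
#' member (NR normalizes over in-set members) and `-1 / (N - |S|)` at each
#' non-member. The enrichment score is the running sum's extremum of largest
#' magnitude (positive on ties); the leading edge is the set members at or
#' before a positive extremum, or at or after a negative one.
#'
#' @param ranked A [ranked_list()] (named numeric, decreasing).
#' @param gene_set Character vector of member symbols.
#' @param weight Exponent on the metric for hit increments; 0 gives the
#'   classic unweighted Kolmogorov-Smirnov statistic, 1 (default) the
#'   standard weighted form.
#' @return A list with `es`, `leading_edge`, and the running sum (`profile`).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n <- length(genes)
  n_hit <- sum(hit)
  if (n_hit == 0) stop("undefined statistic: no gene-set member in ranked list")
  if (n_hit == n) stop("undefined statistic: gene set covers entire ranked list")
  w <- abs(ranked)^weight
  nr <- sum(w[hit])
  inc <- ifelse(hit, if (nr > 0) w / nr else 1 / n_hit, -1 / (n - n_hit))
  if (nr == 0) inc[!hit] <- -1 / (n - n_hit)  # degenerate all-zero metric
  prof <- cumsum(inc)
  i_max <- which.max(prof)
  i_min <- which.min(prof)
  es <- if (abs(prof[i_max]) >= abs(prof[i_min])) prof[i_max] else prof[i_min]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= i_max]
             else genes[hit & seq_len(n) >= i_min]
  list(es = es, leading_edge = leading, profile = prof)
}

# ES for many permutations at once, computed from sorted hit positions only.
# P: m x B matrix of sorted positions; w: per-position |metric|^weight.
.es_from_positions <- function(P, w, n) {
  m <- nrow(P)
  B <- ncol(P)
  Wm <- matrix(w[P], m, B)
  CW <- apply(Wm, 2, cumsum)
  if (m == 1) CW <- matrix(CW, 1, B)
  tot <- CW[m, ]
  hitfrac <- sweep(CW, 2, tot, "/")
  miss <- (P - seq_len(m)) / (n - m)
  pos_dev <- hitfrac - miss
  pre <- rbind(0, hitfrac[-m, , drop = FALSE])
  neg_dev <- pre - miss
  mx <- apply(pos_dev, 2, max)
  mn <- pmin(apply(neg_dev, 2, min), 0)
  ifelse(abs(mx) >= abs(mn), mx, mn)
}

#' GSEA with gene-permutation significance
#'
#' For each catalog set, computes the observed enrichment score, then a null
#' distribution by re-drawing the set's in-list members uniformly at random
#' from the ranked list (`n_perm` gene permutations, fixed seed). The
#' p-value uses an add-one pseudocount over same-sign nulls:
#' `p = (1 + #same-sign nulls with |ES_null| >= |ES|) / (1 + #same-sign
#' nulls)`; the normalized enrichment score is `ES / mean(|ES_null|)` over
#' same-sign nulls. BH correction runs across the tested sets.
#'
#' @param ranked A [ranked_list()].
#' @param sets A [gene_sets()] collection (or named list).
#' @param n_perm Number of permutations (>= 100); default 10000.
#' @param weight Running-sum weight, as in [gsea_es()].
#' @param seed Integer seed; required, so results are reproducible.
#' @param min_size,max_size Bounds on in-list set size; sets outside are
#'   skipped.
#' @return A `data.frame`: `set_id`, `size`, `es`, `nes`, `p_value`, `padj`,
#'   `n_same` (number of same-sign null scores, the p-value's effective
#'   denominator minus one), `leading_edge` (slash-separated), `n_perm`,
#'   `seed`. The smallest attainable p-value is `1 / (1 + n_same)`.
#' @export
gsea_significance <- function(ranked, sets, n_perm = 10000, weight = 1, seed,
                              min_size = 3, max_size = Inf) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- names(ranked)
  n <- length(genes)
  w <- abs(ranked)^weight
  keep <- names(sets)[vapply(sets, function(s) {
    m <- sum(genes %in% s)
    m >= max(1, min_size) && m <= min(max_size, n - 1)
  }, logical(1))]
  if (!length(keep)) {
    return(data.frame(set_id = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0), padj = numeric(0),
                      leading_edge = character(0), n_perm = integer(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  set.seed(seed)
  rows <- lapply(keep, function(id) {
    obs <- gsea_es(ranked, sets[[id]], weight)
    m <- sum(genes %in% sets[[id]])
    P <- matrix(0L, m, n_perm)
    for (b in seq_len(n_perm)) P[, b] <- sort.int(sample.int(n, m))
    null_es <- .es_from_positions(P, w, n)
    same <- null_es * obs$es > 0 | (obs$es == 0 & null_es == 0)
    n_same <- sum(same)
    if (n_same == 0) {
      rm_warn("no same-sign permutations for set ", id,
              "; p floored at 1/(1+n_perm)")
      p <- 1 / (1 + n_perm)
      nes <- NA_real_
    } else {
      p <- (1 + sum(abs(null_es[same]) >= abs(obs$es))) / (1 + n_same)
      nes <- obs$es / mean(abs(null_es[same]))
    }
    data.frame(set_id = id, size = m, es = obs$es, nes = nes, p_value = p,
               n_same = n_same,
               leading_edge = paste(obs$leading_edge, collapse = "/"),
               n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out[, c("set_id", "size", "es", "nes", "p_value", "padj", "n_same",
          "leading_edge", "n_perm", "seed")]
}
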