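# Over-representation analysis over GMT catalogs, redundancy simplification,
# cluster-marker enrichment and Fisher's exact test.

#' Over-representation analysis (hypergeometric)
#'
#' For each catalog term, intersects its members with the background to get
#' `K`, counts query hits `k`, and computes the one-sided hypergeometric
#' upper-tail p-value ([hypergeom_overlap_test()]). Terms with fewer than
#' `min_size` or more than `max_size` background members are dropped before
#' testing; BH correction runs across the retained terms only.
#'
#' @param query Character vector of query genes (subset of `background`).
#' @param background Character vector: the gene universe.
#' @param catalog A [gene_sets()] collection.
#' @param min_size,max_size Retained term size bounds after background
#'   intersection (defaults 10 and 500).
#' @return A `data.frame` with columns `term_id`, `description`, `k`, `K`,
#'   `n`, `N`, `expected`, `p_value`, `padj`, `hits` (slash-separated member
#'   hits), sorted by `padj` then `term_id`.
#' @export
ora <- function(query, background, catalog, min_size = 10, max_size = 500) {
  query <- unique(query)
  background <- unique(background)
  if (!length(catalog)) stop("catalog must be non-empty")
  if (!all(query %in% background)) {
    stop("domain error: query must be a subset of background")
  }
  desc <- attr(catalog, "descriptions")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(catalog), function(id) {
    members <- intersect(catalog[[id]], background)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    hits <- intersect(query, members)
    ov <- hypergeom_overlap_test(length(hits), K, n, N)
    data.frame(term_id = id,
               description = if (!is.null(desc)) desc[[id]] else "",
               k = ov$k, K = K, n = n, N = N, expected = ov$expected,
               p_value = ov$p_value, stringsAsFactors = FALSE,
               hits = paste(sort(hits), collapse = "/"))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), expected = numeric(0),
                      p_value = numeric(0), padj = numeric(0),
                      hits = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  out <- out[order(out$padj, out$term_id), ]
  rownames(out) <- NULL
  out[, c("term_id", "description", "k", "K", "n", "N", "expected",
          "p_value", "padj", "hits")]
}

#' Collapse redundant enriched terms
#'
#' Single-linkage clusters the supplied terms by Jaccard similarity of their
#' member sets at the given cutoff and keeps one representative per cluster:
#' the minimum-`padj` term, ties broken by the lexicographically smaller
#' term id. Uses set-membership similarity rather than ontology-graph
#' semantic similarity, so it needs nothing beyond the catalog itself.
#'
#' @param results An [ora()] result data frame (typically pre-filtered to
#'   significant terms).
#' @param catalog The [gene_sets()] collection the results were computed
#'   against.
#' @param cutoff Jaccard similarity threshold in (0, 1]; default 0.7.
#' @return The surviving rows of `results`, original order preserved.
#' @export
simplify_terms <- function(results, catalog, cutoff = 0.7) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("domain error: cutoff must be in (0, 1]")
  if (nrow(results) <= 1) return(results)
  ids <- results$term_id
  if (!all(ids %in% names(catalog))) {
    stop("results contain terms absent from catalog")
  }
  sets <- lapply(catalog[ids], unique)
  m <- length(ids)
  sim <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(sets[[i]]) + length(sets[[j]]) - inter
      sim[i, j] <- sim[j, i] <- if (uni > 0) inter / uni else 0
    }
  }
  tree <- hclust(as.dist(1 - sim), method = "single")
  cl <- cutree(tree, h = 1 - cutoff)
  keep <- logical(m)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    best <- idx[order(results$padj[idx], results$term_id[idx])][1]
    keep[best] <- TRUE
  }
  out <- results[keep, ]
  rownames(out) <- NULL
  out
}

#' Marker-based cluster enrichment
#'
#' Tests, per cell cluster, whether an upregulated gene set overlaps that
#' cluster's marker genes more than expected under a hypergeometric null with
#' all expressed genes as background, with BH correction across clusters.
#'
#' @param up_genes Character vector of (harmonized) upregulated query genes.
#' @param markers Named list: cluster id -> character vector of marker genes.
#' @param background Character vector of all expressed genes.
#' @return A `data.frame` with one row per cluster: `cluster`, `k`, `K`, `n`,
#'   `N`, `expected`, `p_value`, `padj`, `hits`.
#' @export
marker_cluster_enrichment <- function(up_genes, markers, background) {
  background <- unique(background)
  if (!length(background)) stop("domain error: empty background")
  up <- intersect(unique(up_genes), background)
  rows <- lapply(names(markers), function(cl) {
    mk <- intersect(unique(markers[[cl]]), background)
    hits <- intersect(up, mk)
    ov <- hypergeom_overlap_test(length(hits), length(mk), length(up),
                                 length(background))
    data.frame(cluster = cl, k = ov$k, K = ov$K, n = ov$n, N = ov$N,
               expected = ov$expected, p_value = ov$p_value,
               hits = paste(sort(hits), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out[, c("cluster", "k", "K", "n", "N", "expected", "p_value", "padj", "hits")]
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional exact two-sided p-value (sum of hypergeometric probabilities
#' of tables, with the observed margins, no more probable than the observed
#' one) and the sample odds ratio `a*d / (b*c)` (infinite when `b*c = 0` and
#' `a*d > 0`).
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, byrow=TRUE)`.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("domain error: negative count")
  if (sum(counts) == 0) stop("domain error: empty table")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p)
}
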