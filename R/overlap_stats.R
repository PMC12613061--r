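# Cross-dataset DEG comparison statistics: significance filtering, Venn
# partitioning, one-sided hypergeometric overlap tests with BH correction,
# direction concordance, and Spearman correlation of shared log2 fold changes.

#' Filter a DEG table to significant genes
#'
#' DEGs are defined by `padj < alpha` (strict); records with missing `padj`
#' never pass. Optionally restrict to one direction of regulation.
#'
#' @param table A [deg_table()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param direction `"any"`, `"up"` (`log2fc > 0`) or `"down"` (`log2fc < 0`).
#' @return A filtered [deg_table()] (possibly empty).
#' @export
filter_significant <- function(table, alpha = 0.05,
                               direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "deg_table"), alpha > 0, alpha < 1)
  keep <- !is.na(table$padj) & table$padj < alpha
  if (direction == "up") keep <- keep & table$log2fc > 0
  if (direction == "down") keep <- keep & table$log2fc < 0
  deg_table(table$gene[keep], table$log2fc[keep], table$padj[keep],
            attr(table, "dataset_id"), attr(table, "species"))
}

#' One-sided hypergeometric overlap test
#'
#' Tests whether the observed overlap `k` between a set of size `K` and a set
#' of size `n`, drawn from a background of `N` genes, is larger than expected
#' by chance. The p-value is the upper tail `P(X >= k)` (inclusive of the
#' observed count) for `X ~ Hypergeometric(N, K, n)`; the expectation is
#' `n * K / N`.
#'
#' @param k Observed overlap.
#' @param K Size of the first set (e.g. DEGs in dataset A).
#' @param n Size of the second set (the draw).
#' @param N Background size: the union of all analyzed genes.
#' @return A list of class `"overlap_result"` with fields `k`, `K`, `n`, `N`,
#'   `expected`, `p_value`.
#' @examples
#' hypergeom_overlap_test(5, 8, 6, 20)
#' @export
hypergeom_overlap_test <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (N <= 0 || K > N || n > N || k > min(K, n) || k < 0) {
    stop("domain error: need 0 <= k <= min(K, n) and K, n <= N, N > 0")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, K = K, n = n, N = N,
                 expected = n * K / N, p_value = p, padj = NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> k=%d (expected %.2f) K=%d n=%d N=%d p=%.3g\n",
              x$k, x$expected, x$K, x$n, x$N, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are returned in input
#' order, capped at 1 and monotone-repaired by the cumulative minimum from
#' the largest rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Venn partition of two or three gene sets
#'
#' @param sets Named list of 2 or 3 character vectors (harmonized symbols).
#' @return Named integer vector of disjoint region counts; for three sets the
#'   regions are `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC` (with the supplied set
#'   names substituted), covering the union exactly.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || !length(sets) %in% 2:3) {
    stop("venn_partition supports exactly 2 or 3 sets")
  }
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets))
  }
  labels <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_along(sets), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- table(factor(labels, levels = combos))
  out <- as.integer(counts)
  names(out) <- combos
  out
}

#' Direction concordance between two significance-filtered DEG tables
#'
#' Over the shared (harmonized) genes, counts those whose log2 fold change
#' has the same sign in both tables. Genes with a fold change of exactly zero
#' in either table are excluded from both numerator and denominator.
#'
#' @param a,b [deg_table()]s, already filtered to significant DEGs.
#' @return A list with `n_shared`, `n_concordant`, `fraction`.
#' @export
direction_concordance <- function(a, b) {
  shared <- intersect(a$gene, b$gene)
  la <- a$log2fc[match(shared, a$gene)]
  lb <- b$log2fc[match(shared, b$gene)]
  nz <- la != 0 & lb != 0
  la <- la[nz]; lb <- lb[nz]
  n_shared <- length(la)
  n_conc <- sum(sign(la) == sign(lb))
  list(n_shared = n_shared, n_concordant = n_conc,
       fraction = if (n_shared > 0) n_conc / n_shared else NA_real_)
}

#' Spearman correlation of shared log2 fold changes
#'
#' Computes Spearman's rho (Pearson correlation of average ranks, so ties are
#' mid-ranked) over the genes shared by two DEG tables, with a two-sided
#' p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param a,b [deg_table()]s.
#' @return A list with `rho`, `p_value`, `n_shared`, `shared_genes`.
#' @export
correlate_shared_lfc <- function(a, b) {
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 2) stop("insufficient data: fewer than 2 shared genes")
  la <- a$log2fc[match(shared, a$gene)]
  lb <- b$log2fc[match(shared, b$gene)]
  rho <- cor(rank(la), rank(lb))
  n <- length(shared)
  p <- if (n >= 3 && abs(rho) < 1) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else if (abs(rho) == 1 && n >= 3) 0 else NA_real_
  list(rho = rho, p_value = p, n_shared = n, shared_genes = shared)
}

#' Top n upregulated genes among a shared gene list
#'
#' Ranks the shared genes by descending log2 fold change in `a`, breaking
#' ties by smaller `padj` then lexicographic symbol, and returns the top `n`
#' (all, if fewer are available).
#'
#' @param a Reference [deg_table()] providing the ranking.
#' @param shared Character vector of candidate genes.
#' @param n Number of genes to return (default 10).
#' @return Character vector of at most `n` genes.
#' @export
top_n_upregulated <- function(a, shared, n = 10) {
  stopifnot(n >= 1)
  shared <- intersect(shared, a$gene)
  idx <- match(shared, a$gene)
  ord <- order(-a$log2fc[idx], a$padj[idx], a$gene[idx], na.last = TRUE)
  head(shared[ord], n)
}

#' Full pairwise DEG comparison
#'
#' Convenience wrapper running the overlap test, Venn partition, direction
#' concordance and Spearman correlation for one dataset pair, mirroring a
#' single panel of a cross-dataset comparison figure.
#'
#' @param a,b Unfiltered [deg_table()]s.
#' @param background_n Background size N (union of analyzed genes). Required:
#'   there is no silent default.
#' @param alpha DEG significance threshold.
#' @return A list with `overlap` (an `"overlap_result"`), `venn`,
#'   `concordance`, `correlation`, `sig_a`, `sig_b`.
#' @export
compare_deg_tables <- function(a, b, background_n, alpha = 0.05) {
  if (missing(background_n) || is.null(background_n)) {
    stop("background_n is required: supply the size of the union of analyzed genes")
  }
  sa <- filter_significant(a, alpha)
  sb <- filter_significant(b, alpha)
  k <- length(intersect(sa$gene, sb$gene))
  ov <- hypergeom_overlap_test(k, nrow(sa), nrow(sb), background_n)
  vp <- venn_partition(setNames(list(sa$gene, sb$gene),
                                make.unique(c(attr(a, "dataset_id"),
                                              attr(b, "dataset_id")))))
  conc <- direction_concordance(sa, sb)
  corr <- if (k >= 2) correlate_shared_lfc(sa, sb) else NULL
  list(overlap = ov, venn = vp, concordance = conc, correlation = corr,
       sig_a = sa, sig_b = sb)
}
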