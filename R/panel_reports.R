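# Cross-dataset fold-change matrix for a gene panel and direction-stratified
# top/bottom selection.

#' Log2 fold-change matrix for a gene panel
#'
#' Rows follow the panel order, columns the dataset order; a cell is missing
#' (`NA`) iff the gene is absent from that dataset's table. A parallel
#' logical matrix flags cells with `padj < 0.05` so downstream display can
#' mask non-significant values.
#'
#' @param panel Character vector of (harmonized) panel genes.
#' @param datasets List of [deg_table()]s.
#' @return A list of class `"fc_matrix"` with `lfc` (numeric matrix), `sig`
#'   (logical matrix), both `genes x datasets`.
#' @export
build_lfc_matrix <- function(panel, datasets) {
  if (!length(panel)) stop("domain error: empty panel")
  panel <- harmonize_symbol(panel)
  ids <- vapply(datasets, attr, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  lfc <- matrix(NA_real_, length(panel), length(datasets),
                dimnames = list(panel, ids))
  sig <- matrix(NA, length(panel), length(datasets),
                dimnames = list(panel, ids))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    i <- match(panel, d$gene)
    lfc[, j] <- d$log2fc[i]
    sig[, j] <- !is.na(d$padj[i]) & d$padj[i] < 0.05
    sig[is.na(i), j] <- NA
    if (all(is.na(i))) rm_warn("dataset ", ids[j], " contains no panel gene")
  }
  structure(list(lfc = lfc, sig = sig), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d genes x %d datasets (%d missing cells)\n",
              nrow(x$lfc), ncol(x$lfc), sum(is.na(x$lfc))))
  print(head(x$lfc))
  invisible(x)
}

#' Export / import a fold-change matrix as TSV
#'
#' One row per gene; per dataset a log2 fold-change column and a `__sig`
#' significance-flag column, missing cells written as `NA`. `import_matrix`
#' inverts `export_matrix` exactly.
#'
#' @param matrix A `"fc_matrix"`.
#' @param path Output path.
#' @return The path (`export_matrix`) or a `"fc_matrix"` (`import_matrix`).
#' @export
export_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "fc_matrix"))
  df <- data.frame(gene = rownames(matrix$lfc), matrix$lfc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sig <- matrix$sig
  colnames(sig) <- paste0(colnames(sig), "__sig")
  df <- cbind(df, as.data.frame(sig, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname export_matrix
#' @export
import_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sig_cols <- grep("__sig$", names(df), value = TRUE)
  ids <- sub("__sig$", "", sig_cols)
  lfc <- as.matrix(df[, ids, drop = FALSE])
  sig <- as.matrix(df[, sig_cols, drop = FALSE])
  colnames(sig) <- ids
  rownames(lfc) <- rownames(sig) <- df$gene
  structure(list(lfc = lfc, sig = matrix(as.logical(sig), nrow(sig),
                                         ncol(sig), dimnames = dimnames(sig))),
            class = "fc_matrix")
}

#' Direction-stratified top/bottom selection
#'
#' From an overlap gene list, picks the `n` most strongly upregulated
#' (largest positive log2 fold change) and the `n` most strongly
#' downregulated (most negative) genes in the reference table. Ties break by
#' smaller `padj`, then symbol; genes with a fold change of exactly zero are
#' in neither list.
#'
#' @param overlap Character vector of candidate genes (present in
#'   `reference`).
#' @param reference A [deg_table()] providing log2fc and padj.
#' @param n Maximum list length per direction (default 25).
#' @return A list with `up` and `down` character vectors, each sorted by
#'   decreasing `|log2fc|`.
#' @export
select_top_bottom <- function(overlap, reference, n = 25) {
  overlap <- intersect(overlap, reference$gene)
  i <- match(overlap, reference$gene)
  lfc <- reference$log2fc[i]
  padj <- reference$padj[i]
  pick <- function(sel) {
    ord <- order(-abs(lfc[sel]), padj[sel], overlap[sel], na.last = TRUE)
    head(overlap[sel][ord], n)
  }
  list(up = pick(lfc > 0), down = pick(lfc < 0))
}
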