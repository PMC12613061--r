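#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper p.adjust fisher.test rnorm runif rbinom cor pt
#'   setNames hclust cutree as.dist
#' @importFrom utils read.delim write.table head
NULL

# Leveled, timestamp-free logging. Messages go through message() so callers
# can suppress them; pipeline runs additionally capture them into run.log.
rm_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

rm_info <- function(...) rm_log("INFO", ...)
rm_warn <- function(...) rm_log("WARN", ...)

#' Harmonize gene symbols
#'
#' Trims surrounding whitespace and uppercases, so that mouse-cased symbols
#' (e.g. `"Spp1"`) and their human counterparts (`"SPP1"`) collapse to a
#' single identifier. All cross-dataset and cross-species matching in this
#' package happens in this harmonized space.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of harmonized symbols.
#' @examples
#' harmonize_symbol(c("Spp1", " Nexn ", "SRF"))
#' @export
harmonize_symbol <- function(x) {
  if (!is.character(x)) stop("gene symbols must be character")
  out <- toupper(trimws(x))
  if (any(is.na(x)) || any(!nzchar(out))) {
    stop("invalid gene symbol: empty or blank input")
  }
  out
}

# Stable writer used everywhere so outputs are byte-reproducible.
write_tsv <- function(df, path, na = "NA") {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = na, eol = "\n")
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
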