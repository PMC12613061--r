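# Readers and writers for the external formats the pipeline consumes.
# Internal convention: all genomic coordinates are 0-based half-open
# ([start, end)), i.e. the BED/narrowPeak convention. GTF input (1-based
# closed) is converted on ingestion and never stored.

#' Construct a DEG table
#'
#' A DEG table holds one dataset's differential-expression results: one row
#' per gene with a log2 fold change and a Benjamini-Hochberg adjusted p-value
#' (`padj`, possibly `NA`). Gene symbols are harmonized (trimmed, uppercased)
#' and must be unique after harmonization.
#'
#' @param gene Character vector of gene symbols.
#' @param log2fc Numeric log2 fold changes (finite).
#' @param padj Numeric adjusted p-values in `[0, 1]`, `NA` allowed.
#' @param dataset_id Non-empty dataset identifier.
#' @param species `"human"` or `"mouse"`.
#' @return A `data.frame` of class `"deg_table"` with columns `gene`,
#'   `log2fc`, `padj` and attributes `dataset_id` and `species`.
#' @export
deg_table <- function(gene, log2fc, padj, dataset_id, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!nzchar(dataset_id)) stop("dataset_id must be non-empty")
  gene <- if (length(gene)) harmonize_symbol(gene) else character(0)
  log2fc <- as.numeric(log2fc)
  padj <- as.numeric(padj)
  stopifnot(length(log2fc) == length(gene), length(padj) == length(gene))
  if (anyDuplicated(gene)) stop("duplicate gene symbols after harmonization")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  bad <- !is.na(padj) & (padj < 0 | padj > 1)
  if (any(bad)) stop("padj outside [0, 1]")
  out <- data.frame(gene = gene, log2fc = log2fc, padj = padj,
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "species") <- species
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("<deg_table> %s (%s): %d genes, %d significant at padj < 0.05\n",
              attr(x, "dataset_id"), attr(x, "species"), nrow(x),
              sum(!is.na(x$padj) & x$padj < 0.05)))
  print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a DEG table from TSV/CSV
#'
#' Symbols are harmonized on ingestion; rows that collapse to the same
#' harmonized symbol are deduplicated keeping the record with the smallest
#' `padj` (missing `padj` sorts last).
#'
#' @param path Path to a delimited file with a header row.
#' @param dataset_id Dataset identifier to attach.
#' @param species `"human"` or `"mouse"`.
#' @param column_map Named character vector mapping the required fields to
#'   column names in the file; names must be `gene`, `log2fc`, `padj`.
#' @param sep Field separator (default tab).
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path, dataset_id, species = c("human", "mouse"),
                           column_map = c(gene = "gene", log2fc = "log2fc",
                                          padj = "padj"),
                           sep = "\t") {
  species <- match.arg(species)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name columns for: ", paste(need, collapse = ", "))
  }
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(column_map[need]), names(df))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    rm_warn("empty DEG table: ", path)
    return(deg_table(character(0), numeric(0), numeric(0), dataset_id, species))
  }
  gene <- as.character(df[[column_map[["gene"]]]])
  lfc_raw <- df[[column_map[["log2fc"]]]]
  padj_raw <- df[[column_map[["padj"]]]]
  num_or_die <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop(sprintf("unparseable %s at data line %d of %s: '%s'",
                   what, bad[1], path, x[bad[1]]))
    }
    v
  }
  lfc <- num_or_die(lfc_raw, "log2fc")
  padj <- num_or_die(padj_raw, "padj")
  if (any(is.na(lfc))) {
    stop("missing log2fc at data line ", which(is.na(lfc))[1], " of ", path)
  }
  gene <- harmonize_symbol(gene)
  # keep the min-padj record per harmonized symbol; NA padj sorts last
  ord <- order(gene, is.na(padj), padj)
  keep <- !duplicated(gene[ord])
  idx <- ord[keep]
  idx <- sort(idx)
  n_dup <- length(gene) - length(idx)
  rm_info("read ", length(gene), " rows from ", path,
          if (n_dup > 0) paste0(" (", n_dup, " duplicate symbols collapsed)") else "")
  deg_table(gene[idx], lfc[idx], padj[idx], dataset_id, species)
}

#' Write a DEG table to TSV
#'
#' @param x A [deg_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_deg_table <- function(x, path) {
  stopifnot(inherits(x, "deg_table"))
  write_tsv(data.frame(gene = x$gene, log2fc = x$log2fc, padj = x$padj), path)
}

## ---- narrowPeak (ENCODE BED6+4) --------------------------------------------

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue (-log10, -1 if missing), qValue (-log10, -1 if missing), peak
#' (summit offset from start, -1 if missing). Coordinates stay 0-based
#' half-open; the -1 sentinels are preserved as-is.
#'
#' @param path Path to a narrowPeak file.
#' @return A `data.frame` of class `"narrowpeak"` with the ten ENCODE columns.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(narrowpeak_df())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 10)) {
    stop("narrowPeak format error in ", path, ": line ",
         which(ncols < 10)[1], " has ", ncols[which(ncols < 10)[1]],
         " columns (need 10)")
  }
  m <- do.call(rbind, fields)
  out <- narrowpeak_df(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = m[, 4],
    score = as.integer(round(as.numeric(m[, 5]))),
    strand = m[, 6],
    signalValue = as.numeric(m[, 7]),
    pValue = as.numeric(m[, 8]),
    qValue = as.numeric(m[, 9]),
    peak = as.integer(m[, 10])
  )
  bad <- which(!(out$end > out$start))
  if (length(bad)) {
    stop("narrowPeak record error in ", path, ": line ", bad[1],
         " has start >= end")
  }
  if (any(out$score < 0)) stop("narrowPeak record error: negative score")
  too_big <- out$peak >= 0 & out$peak >= (out$end - out$start)
  if (any(too_big)) {
    stop("narrowPeak record error in ", path, ": summit offset >= peak length")
  }
  out
}

narrowpeak_df <- function(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          score = integer(0), strand = character(0),
                          signalValue = numeric(0), pValue = numeric(0),
                          qValue = numeric(0), peak = integer(0)) {
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, strand = strand, signalValue = signalValue,
                    pValue = pValue, qValue = qValue, peak = peak,
                    stringsAsFactors = FALSE)
  class(out) <- c("narrowpeak", "data.frame")
  out
}

#' Write peaks in narrowPeak format
#'
#' @param peaks A `"narrowpeak"` data frame as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- as.data.frame(peaks)[, c("chrom", "start", "end", "name", "score",
                                 "strand", "signalValue", "pValue", "qValue",
                                 "peak")]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                       df$chrom, df$start, df$end, df$name, df$score,
                       df$strand,
                       format(df$signalValue, trim = TRUE, scientific = FALSE),
                       format(df$pValue, trim = TRUE, scientific = FALSE),
                       format(df$qValue, trim = TRUE, scientific = FALSE),
                       df$peak), con)
  }
  invisible(path)
}

## ---- BED intervals (blacklist etc.) ----------------------------------------

#' Read BED3/BED6 intervals
#'
#' @param path Path to a BED file (0-based half-open, as the format defines).
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) stop("BED format error: fewer than 3 columns")
  m <- do.call(rbind, lapply(fields, function(f) f[1:min(6, min(ncols))]))
  out <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), stringsAsFactors = FALSE)
  if (min(ncols) >= 6) {
    out$name <- m[, 4]
    out$score <- suppressWarnings(as.numeric(m[, 5]))
    out$strand <- m[, 6]
  }
  if (any(out$end <= out$start)) stop("BED record error: start >= end")
  out
}

write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df[cols])), sep = "\t")), con)
  }
  invisible(path)
}

## ---- TSS annotation --------------------------------------------------------

#' Read transcription start sites from GTF or BED6
#'
#' The TSS is the strand-aware 5' end reduced to a single 0-based position:
#' for `+` features the (0-based) start, for `-` features `end - 1`. GTF
#' `gene` features (1-based closed) are converted on ingestion; BED6 is
#' already 0-based half-open.
#'
#' @param path Annotation file.
#' @param format `"gtf"` or `"bed6"`.
#' @return A `data.frame` with columns `gene`, `chrom`, `strand`, `tss`
#'   (0-based), one row per distinct (gene, chrom, strand, tss).
#' @export
read_tss <- function(path, format = c("gtf", "bed6")) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      keep <- as.character(gr$type) == "gene"
      if (any(keep)) gr <- gr[keep]
    }
    sym <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) gr$gene_name else gr$gene_id
    if (is.null(sym)) stop("GTF record error: no gene_name/gene_id attribute")
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("TSS record error: feature without strand")
    # GRanges is 1-based closed; 0-based 5' end is start-1 (+) or end-1 (-)
    tss <- ifelse(strand == "+", BiocGenerics::start(gr) - 1L,
                  BiocGenerics::end(gr) - 1L)
    out <- data.frame(gene = harmonize_symbol(as.character(sym)),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  } else {
    bed <- read_bed(path)
    if (!all(c("name", "strand") %in% names(bed))) {
      stop("BED6 required for TSS input (need name and strand columns)")
    }
    if (any(!bed$strand %in% c("+", "-"))) {
      stop("TSS record error: feature without strand")
    }
    tss <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
    out <- data.frame(gene = harmonize_symbol(bed$name), chrom = bed$chrom,
                      strand = bed$strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  }
  if (any(out$tss < 0)) stop("TSS record error: negative TSS position")
  unique(out)
}

## ---- JASPAR PFMs -----------------------------------------------------------

#' Read position frequency matrices in JASPAR text format
#'
#' Expects records of the form `>ID NAME` followed by four lines
#' `A [ n1 n2 ... ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional).
#'
#' @param path Path to a JASPAR-format PFM file.
#' @return A list of `"pfm"` objects, each a list with `motif_id`, `name`,
#'   and `counts` (4 x width numeric matrix, rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("JASPAR format error: no '>' header found")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    h <- sub("^>", "", lines[starts[i]])
    parts <- strsplit(h, "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) >= 2) paste(parts[-1], collapse = " ") else {
      rm_warn("PFM header without name; using id ", motif_id)
      motif_id
    }
    body <- lines[(starts[i] + 1):(if (i < length(starts)) starts[i + 1] - 1 else length(lines))]
    if (length(body) < 4) stop("JASPAR format error: motif ", motif_id,
                               " has fewer than 4 count rows")
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      if (any(is.na(v))) stop("JASPAR format error: unparseable counts in ",
                              motif_id)
      v
    })
    base_letters <- toupper(substr(body[1:4], 1, 1))
    if (!identical(base_letters, c("A", "C", "G", "T"))) {
      # accept unlabeled rows in A,C,G,T order
      if (any(base_letters %in% c("A", "C", "G", "T"))) {
        names(rows) <- base_letters
        rows <- rows[c("A", "C", "G", "T")]
        if (any(vapply(rows, is.null, logical(1)))) {
          stop("JASPAR format error: rows must cover A, C, G, T")
        }
      }
    }
    w <- unique(lengths(rows))
    if (length(w) != 1) stop("JASPAR format error: rows of unequal width in ",
                             motif_id)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("JASPAR format error: negative count in ",
                              motif_id)
    if (any(colSums(counts) <= 0)) {
      stop("JASPAR format error: empty column in ", motif_id)
    }
    if (w < 4) stop("JASPAR format error: motif width < 4 in ", motif_id)
    out[[i]] <- structure(list(motif_id = motif_id, name = name,
                               counts = counts), class = "pfm")
  }
  out
}

#' Consensus sequence of a PFM (per-column argmax)
#' @param pfm A `"pfm"` object.
#' @return Single consensus string.
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

## ---- GMT gene-set catalogs -------------------------------------------------

#' Read a GMT gene-set catalog
#'
#' Each line: term id, description, then member symbols, tab-separated.
#' Members are harmonized and deduplicated; sets left empty are dropped with
#' a warning; duplicated term ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `"gene_sets"`) with a
#'   `"descriptions"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("GMT format error: duplicate term id ", ids[duplicated(ids)][1])
  }
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  members <- lapply(fields, function(f) {
    if (length(f) < 3) return(character(0))
    unique(harmonize_symbol(f[-(1:2)]))
  })
  empty <- lengths(members) == 0
  if (any(empty)) {
    rm_warn(sum(empty), " empty gene set(s) dropped from ", path)
  }
  gene_sets(setNames(members[!empty], ids[!empty]),
            descriptions = setNames(desc[!empty], ids[!empty]))
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors (harmonized symbols).
#' @param descriptions Optional named character vector of term descriptions.
#' @return A `"gene_sets"` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets)) stop("gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate term ids")
  if (any(lengths(sets) == 0)) stop("empty member sets not allowed")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = c("gene_sets", "list"))
}

#' Write a gene-set collection as GMT
#' @param sets A `"gene_sets"` object (or named list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sets)) {
    writeLines(paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), con)
  }
  invisible(path)
}

## ---- ortholog map ----------------------------------------------------------

#' Read a human-mouse ortholog map
#'
#' @param path TSV with columns `human_symbol` and `mouse_symbol`.
#' @return A `data.frame` with harmonized `human` and `mouse` columns,
#'   duplicate pairs removed. One-to-many relationships are kept and counted
#'   in the log.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("human_symbol", "mouse_symbol")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error in ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  out <- data.frame(human = harmonize_symbol(df$human_symbol),
                    mouse = harmonize_symbol(df$mouse_symbol),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  n_multi <- sum(duplicated(out$human)) + sum(duplicated(out$mouse))
  if (n_multi > 0) rm_info(n_multi, " one-to-many ortholog relationships in ",
                           path)
  out
}

write_ortholog_map <- function(map, path) {
  write_tsv(data.frame(human_symbol = map$human, mouse_symbol = map$mouse), path)
}

## ---- genome sequence -------------------------------------------------------

#' Read a genome FASTA into a sequence store
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# GRanges helpers: internal coordinates are 0-based half-open, GRanges is
# 1-based closed, so start+1 on the way in.
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}
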