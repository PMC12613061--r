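# Direct-target prediction funnel: blacklist removal, promoter-window peak
# assignment with five-tier score classification, cross-species YAP1 + TEAD
# promoter-occupancy consensus, TEAD motif filtering, and intersection with
# genes consistently downregulated at both knockout time points.

TIER_LEVELS <- c("blue", "cyan", "green", "yellow", "red")

#' Five-tier classification of peak scores
#'
#' Maps a narrowPeak score (-log10 q-value x 10) to the ordinal five-color
#' intensity scale: blue < 200, cyan 200-499, green 500-749, yellow 750-999,
#' red >= 1000.
#'
#' @param score Integer vector of non-negative scores.
#' @return Ordered factor with levels blue < cyan < green < yellow < red.
#' @examples
#' classify_tier(c(199, 200, 500, 999, 1000))
#' @export
classify_tier <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    stop("domain error: scores must be non-negative")
  }
  cut(score, breaks = c(-Inf, 200, 500, 750, 1000, Inf), right = FALSE,
      labels = TIER_LEVELS, ordered_result = TRUE)
}

#' Effective peak score
#'
#' The narrowPeak score column when positive; when an emitter zeroed the
#' column but provided a q-value, the score is repaired from its definition
#' as `round(-log10(q) * 10)`; otherwise 0 with a warning.
#'
#' @param peaks A `"narrowpeak"` data frame.
#' @return Integer vector of effective scores.
#' @export
effective_score <- function(peaks) {
  sc <- as.integer(peaks$score)
  zero <- sc <= 0
  has_q <- peaks$qValue >= 0
  repair <- zero & has_q
  if (any(repair)) {
    sc[repair] <- as.integer(round(peaks$qValue[repair] * 10))
    rm_info(sum(repair), " zero narrowPeak score(s) repaired from q-value")
  }
  none <- zero & !has_q
  if (any(none)) rm_warn(sum(none), " peak(s) with score 0 and no q-value")
  sc
}

#' Remove peaks overlapping a blacklist
#'
#' Drops any peak with at least 1 bp of intersection with a blacklist
#' interval (0-based half-open on both sides, so abutting intervals do not
#' overlap).
#'
#' @param peaks A `"narrowpeak"` data frame.
#' @param blacklist A `data.frame` with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @return The surviving peaks.
#' @export
remove_blacklisted <- function(peaks, blacklist) {
  if (!nrow(peaks) || is.null(blacklist) || !nrow(blacklist)) return(peaks)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(peaks$chrom, peaks$start, peaks$end),
    as_granges0(blacklist$chrom, blacklist$start, blacklist$end),
    minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) rm_info(length(drop), " blacklisted peak(s) removed")
  out <- peaks[setdiff(seq_len(nrow(peaks)), drop), ]
  rownames(out) <- NULL
  out
}

#' Promoter windows around transcription start sites
#'
#' A symmetric window `[tss - flank, tss + flank)` per TSS record, clipped at
#' the chromosome start; only the TSS position itself is strand-aware. Genes
#' with several TSSs get several windows.
#'
#' @param tss TSS table from [read_tss()].
#' @param flank Half-width in bp (default 2000, i.e. +/- 2 kb).
#' @return A `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @export
build_promoter_windows <- function(tss, flank = 2000) {
  stopifnot(flank > 0)
  data.frame(gene = tss$gene, chrom = tss$chrom,
             start = pmax(0L, as.integer(tss$tss - flank)),
             end = as.integer(tss$tss + flank), stringsAsFactors = FALSE)
}

#' Assign each gene its best promoter peak per factor
#'
#' A peak is promoter-bound for a gene iff it overlaps (>= 1 bp) any of that
#' gene's promoter windows. Per gene and factor, the peak with the maximal
#' [effective_score()] is retained; ties break by smaller start, then
#' lexicographic chromosome.
#'
#' @param peaks_by_factor Named list: factor name (e.g. `"YAP1"`,
#'   `"TEAD1"`) -> `"narrowpeak"` data frame, already blacklist-filtered.
#' @param windows Promoter windows from [build_promoter_windows()].
#' @param species `"human"` or `"mouse"`.
#' @return A `data.frame` of class `"promoter_occupancy"`: one row per
#'   (gene, factor) with a promoter peak, columns `species`, `gene`,
#'   `factor`, `chrom`, `start`, `end`, `name`, `score` (effective), `tier`.
#' @export
assign_promoter_peaks <- function(peaks_by_factor, windows,
                                  species = c("human", "mouse")) {
  species <- match.arg(species)
  win_gr <- as_granges0(windows$chrom, windows$start, windows$end)
  rows <- list()
  for (fac in names(peaks_by_factor)) {
    pk <- peaks_by_factor[[fac]]
    if (!nrow(pk)) next
    eff <- effective_score(pk)
    ov <- GenomicRanges::findOverlaps(
      as_granges0(pk$chrom, pk$start, pk$end), win_gr, minoverlap = 1L)
    if (!length(ov)) next
    pi <- S4Vectors::queryHits(ov)
    gene <- windows$gene[S4Vectors::subjectHits(ov)]
    cand <- data.frame(gene = gene, idx = pi, score = eff[pi],
                       start = pk$start[pi], chrom = pk$chrom[pi],
                       stringsAsFactors = FALSE)
    cand <- unique(cand)  # a peak overlapping two windows of one gene counts once
    ord <- order(cand$gene, -cand$score, cand$start, cand$chrom)
    best <- cand[ord, ][!duplicated(cand$gene[ord]), ]
    rows[[fac]] <- data.frame(
      species = species, gene = best$gene, factor = fac,
      chrom = pk$chrom[best$idx], start = pk$start[best$idx],
      end = pk$end[best$idx], name = pk$name[best$idx], score = best$score,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), gene = character(0),
               factor = character(0), chrom = character(0),
               start = integer(0), end = integer(0), name = character(0),
               score = integer(0), stringsAsFactors = FALSE)
  out$tier <- if (nrow(out)) as.character(classify_tier(out$score)) else character(0)
  out <- out[order(out$gene, out$factor), ]
  rownames(out) <- NULL
  class(out) <- c("promoter_occupancy", "data.frame")
  out
}

#' Genes occupied by YAP1 and at least one TEAD factor
#'
#' @param occ A `"promoter_occupancy"` table.
#' @param yap_factor Name of the YAP factor (default `"YAP1"`).
#' @param tead_factors Names of the TEAD factors (default `TEAD1`-`TEAD4`).
#' @return Character vector of qualifying genes.
#' @export
species_occupancy_filter <- function(occ, yap_factor = "YAP1",
                                     tead_factors = paste0("TEAD", 1:4)) {
  yap_genes <- unique(occ$gene[occ$factor == yap_factor])
  tead_genes <- unique(occ$gene[occ$factor %in% tead_factors])
  sort(intersect(yap_genes, tead_genes))
}

#' Cross-species promoter-occupancy consensus
#'
#' Keeps ortholog pairs whose human member passes the human occupancy filter
#' and whose mouse member passes the mouse one. A human gene with several
#' mouse orthologs qualifies if any pairing passes; one row per qualifying
#' human gene (first qualifying mouse ortholog in symbol order), with the
#' multiplicity logged.
#'
#' @param human_pass,mouse_pass Character vectors from
#'   [species_occupancy_filter()].
#' @param orthologs Ortholog map from [read_ortholog_map()].
#' @return A `data.frame` with `human` and `mouse` symbol columns, sorted by
#'   human symbol.
#' @export
cross_species_consensus <- function(human_pass, mouse_pass, orthologs) {
  ok <- orthologs$human %in% human_pass & orthologs$mouse %in% mouse_pass
  pairs <- orthologs[ok, , drop = FALSE]
  pairs <- pairs[order(pairs$human, pairs$mouse), ]
  multi <- sum(duplicated(pairs$human))
  if (multi > 0) rm_info(multi, " extra mouse ortholog pairing(s) collapsed")
  pairs <- pairs[!duplicated(pairs$human), ]
  rownames(pairs) <- NULL
  pairs
}

#' Assemble the final target panel
#'
#' Keeps consensus genes with (i) a TEAD motif hit in a promoter-bound peak
#' of either species, and (ii) `padj < 0.05` and `log2fc < 0` in both
#' knockout time-point DEG tables. Attaches each species' best tier (maximum
#' effective score across the five factors) and both fold changes.
#'
#' @param consensus Pairs from [cross_species_consensus()].
#' @param motif_genes Character vector of genes (human symbols) with at least
#'   one motif hit in a promoter-bound peak of either species.
#' @param deg_2wk,deg_8wk [deg_table()]s for the two time points (mouse
#'   knockout). Symbols are matched after harmonization, so either species'
#'   casing works.
#' @param occ_human,occ_mouse `"promoter_occupancy"` tables.
#' @param alpha Significance threshold (default 0.05).
#' @return A `data.frame`: `gene` (human symbol), `mouse_gene`,
#'   `human_score`, `human_tier`, `mouse_score`, `mouse_tier`, `tead_motif`,
#'   `log2fc_2wk`, `log2fc_8wk`, sorted by `gene`.
#' @export
build_target_panel <- function(consensus, motif_genes, deg_2wk, deg_8wk,
                               occ_human, occ_mouse, alpha = 0.05) {
  if (!nrow(consensus)) return(empty_panel())
  down2 <- filter_significant(deg_2wk, alpha, direction = "down")
  down8 <- filter_significant(deg_8wk, alpha, direction = "down")
  in_deg <- function(g_h, g_m, tab) g_h %in% tab$gene | g_m %in% tab$gene
  keep <- consensus$human %in% motif_genes &
    in_deg(consensus$human, consensus$mouse, down2) &
    in_deg(consensus$human, consensus$mouse, down8)
  sel <- consensus[keep, , drop = FALSE]
  if (!nrow(sel)) return(empty_panel())
  best_by_gene <- function(occ, genes) {
    vapply(genes, function(g) {
      sc <- occ$score[occ$gene == g]
      if (length(sc)) max(sc) else NA_integer_
    }, numeric(1))
  }
  hs <- best_by_gene(occ_human, sel$human)
  ms <- best_by_gene(occ_mouse, sel$mouse)
  lfc_of <- function(g_h, g_m, tab) {
    i <- ifelse(match(g_h, tab$gene, nomatch = 0L) > 0,
                match(g_h, tab$gene), match(g_m, tab$gene))
    tab$log2fc[i]
  }
  out <- data.frame(
    gene = sel$human, mouse_gene = sel$mouse,
    human_score = as.integer(hs),
    human_tier = as.character(classify_tier(hs)),
    mouse_score = as.integer(ms),
    mouse_tier = as.character(classify_tier(ms)),
    tead_motif = TRUE,
    log2fc_2wk = lfc_of(sel$human, sel$mouse, down2),
    log2fc_8wk = lfc_of(sel$human, sel$mouse, down8),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

empty_panel <- function() {
  data.frame(gene = character(0), mouse_gene = character(0),
             human_score = integer(0), human_tier = character(0),
             mouse_score = integer(0), mouse_tier = character(0),
             tead_motif = logical(0), log2fc_2wk = numeric(0),
             log2fc_8wk = numeric(0), stringsAsFactors = FALSE)
}

#' Run the full target-prediction funnel
#'
#' Per species: blacklist-filter the per-factor peaks, assign best promoter
#' peaks, and apply the YAP1 + >= 1 TEAD occupancy filter. Then: ortholog
#' consensus across species, TEAD motif filter over promoter-bound peaks of
#' either species, and intersection with genes consistently downregulated at
#' both time points.
#'
#' @param human,mouse Per-species input lists with elements `peaks` (named
#'   list factor -> `"narrowpeak"` data frame; several files per factor may
#'   be concatenated beforehand), `blacklist` (interval data frame or NULL),
#'   `tss` (from [read_tss()]), `genome` (a DNAStringSet).
#' @param pfms List of `"pfm"` objects (TEAD motifs).
#' @param orthologs Ortholog map.
#' @param deg_2wk,deg_8wk Knockout DEG tables.
#' @param flank Promoter half-width (default 2000).
#' @param p_cutoff Motif match p-value (default 5e-5).
#' @param background Motif background composition (default uniform).
#' @param alpha DEG significance threshold (default 0.05).
#' @param scan_windows If `TRUE`, scan motifs over the full promoter windows
#'   instead of only the promoter-bound peak intervals (default `FALSE`).
#' @return A list with `panel` (see [build_target_panel()]), `stage_counts`
#'   (named integer vector of genes surviving each funnel stage),
#'   `occupancy` (per species), `consensus`, `motif_genes`, and
#'   `elimination` (per input gene, the first stage at which it left the
#'   funnel, `"panel"` if it survived).
#' @export
run_funnel <- function(human, mouse, pfms, orthologs, deg_2wk, deg_8wk,
                       flank = 2000, p_cutoff = 5e-5,
                       background = rep(0.25, 4), alpha = 0.05,
                       scan_windows = FALSE) {
  per_species <- function(sp, inp) {
    pre <- inp$peaks
    post <- lapply(pre, remove_blacklisted, blacklist = inp$blacklist)
    windows <- build_promoter_windows(inp$tss, flank)
    occ <- assign_promoter_peaks(post, windows, sp)
    occ_pre <- assign_promoter_peaks(pre, windows, sp)
    list(occ = occ, occ_pre = occ_pre, windows = windows,
         pass = species_occupancy_filter(occ))
  }
  h <- per_species("human", human)
  m <- per_species("mouse", mouse)

  consensus <- cross_species_consensus(h$pass, m$pass, orthologs)

  # motif filter: any promoter-bound peak of any factor, either species
  motif_pass_h <- motif_genes_for(human$genome, h, pfms, background, p_cutoff,
                                  scan_windows)
  motif_pass_m <- motif_genes_for(mouse$genome, m, pfms, background, p_cutoff,
                                  scan_windows)
  mouse_to_human <- setNames(consensus$human, consensus$mouse)
  motif_genes <- union(intersect(consensus$human, motif_pass_h),
                       unname(mouse_to_human[intersect(consensus$mouse,
                                                       motif_pass_m)]))
  after_motif <- consensus[consensus$human %in% motif_genes, , drop = FALSE]

  panel <- build_target_panel(consensus, motif_genes, deg_2wk, deg_8wk,
                              h$occ, m$occ, alpha)

  stage_counts <- c(
    input_genes = length(union(unique(h$occ_pre$gene),
                               unique(orthologs$human))),
    human_occupancy = length(h$pass),
    mouse_occupancy = length(m$pass),
    consensus = nrow(consensus),
    motif = nrow(after_motif),
    panel = nrow(panel))

  elim <- classify_elimination(h, m, orthologs, consensus, motif_genes,
                               deg_2wk, deg_8wk, panel, alpha)

  list(panel = panel, stage_counts = stage_counts,
       occupancy = list(human = h$occ, mouse = m$occ),
       consensus = consensus, motif_genes = motif_genes, elimination = elim)
}

motif_genes_for <- function(genome, sp_state, pfms, background, p_cutoff,
                            scan_windows) {
  occ <- sp_state$occ
  if (!nrow(occ)) return(character(0))
  if (scan_windows) {
    w <- sp_state$windows[sp_state$windows$gene %in% unique(occ$gene), ]
    regions <- narrowpeak_df(chrom = w$chrom, start = w$start, end = w$end,
                             name = w$gene, score = rep(0L, nrow(w)),
                             strand = rep(".", nrow(w)),
                             signalValue = rep(0, nrow(w)),
                             pValue = rep(-1, nrow(w)),
                             qValue = rep(-1, nrow(w)),
                             peak = rep(-1L, nrow(w)))
    gene_of <- w$gene
  } else {
    regions <- narrowpeak_df(chrom = occ$chrom, start = occ$start,
                             end = occ$end, name = occ$name,
                             score = as.integer(occ$score),
                             strand = rep(".", nrow(occ)),
                             signalValue = rep(0, nrow(occ)),
                             pValue = rep(-1, nrow(occ)),
                             qValue = rep(1, nrow(occ)),
                             peak = rep(-1L, nrow(occ)))
    gene_of <- occ$gene
  }
  hits <- scan_motifs(genome, regions, pfms, background = background,
                      p_cutoff = p_cutoff)
  if (!nrow(hits)) return(character(0))
  hit_key <- paste(hits$chrom, hits$peak_start, hits$peak_end)
  reg_key <- paste(regions$chrom, regions$start, regions$end)
  sort(unique(gene_of[reg_key %in% hit_key]))
}

# First funnel stage at which each gene was eliminated (ground-truth
# bookkeeping for planted fixtures and run reports). Gates are evaluated in
# funnel order: blacklist -> YAP1 occupancy -> TEAD occupancy -> ortholog
# consensus -> motif -> downregulation at 2 then 8 weeks. Mouse-side gates
# are only assessable for genes with an ortholog entry; a gene passing the
# human gates without one exits at the consensus (no_ortholog) stage.
classify_elimination <- function(h, m, orthologs, consensus, motif_genes,
                                 deg_2wk, deg_8wk, panel, alpha) {
  all_genes <- sort(unique(c(h$occ_pre$gene, orthologs$human)))
  down2 <- filter_significant(deg_2wk, alpha, direction = "down")
  down8 <- filter_significant(deg_8wk, alpha, direction = "down")
  teads <- paste0("TEAD", 1:4)
  h_yap <- unique(h$occ$gene[h$occ$factor == "YAP1"])
  h_tead <- unique(h$occ$gene[h$occ$factor %in% teads])
  m_yap <- unique(m$occ$gene[m$occ$factor == "YAP1"])
  m_tead <- unique(m$occ$gene[m$occ$factor %in% teads])
  pre_h <- unique(h$occ_pre$gene); post_h <- unique(h$occ$gene)
  pre_m <- unique(m$occ_pre$gene); post_m <- unique(m$occ$gene)
  mouse_of <- split(orthologs$mouse, orthologs$human)
  vapply(all_genes, function(g) {
    gm <- mouse_of[[g]]
    has_m <- length(gm) > 0
    if ((g %in% pre_h && !(g %in% post_h)) ||
        (has_m && any(gm %in% pre_m) && !any(gm %in% post_m))) {
      return("blacklist")
    }
    if (!(g %in% h_yap) || (has_m && !any(gm %in% m_yap))) return("no_yap1")
    if (!(g %in% h_tead) || (has_m && !any(gm %in% m_tead))) return("no_tead")
    if (!(g %in% consensus$human)) return("no_ortholog")
    if (!(g %in% motif_genes)) return("no_motif")
    if (!(g %in% down2$gene || any(gm %in% down2$gene))) return("not_down_2wk")
    if (!(g %in% down8$gene || any(gm %in% down8$gene))) return("not_down_8wk")
    "panel"
  }, character(1))
}
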