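# Synthetic-data generators: every pipeline input with known ground truth.
# All generators are pure functions of their parameters and seed, so the
# emitted files are byte-reproducible.

#' Generate a pair of DEG tables with controlled overlap and concordance
#'
#' Builds two DEG tables over a shared gene universe such that exactly
#' `round(overlap_target * n_deg_b)` genes are significant in both, the
#' shared genes agree in sign with probability `concordance_target`, and
#' shared fold-change magnitudes are positively coupled (so Spearman
#' correlation rises with concordance). Significant genes draw
#' `padj < 0.05`, all others `>= 0.05`; fold-change magnitudes are
#' `|N(0, lfc_sd)| + 0.25` so no gene sits at zero.
#'
#' @param n_genes Universe size.
#' @param n_deg_a,n_deg_b Number of significant genes per table.
#' @param overlap_target Fraction of table B's DEGs shared with A, in `[0, 1]`.
#' @param concordance_target Probability of sign agreement on shared DEGs.
#' @param lfc_sd Fold-change spread (log2 units), default 1.
#' @param seed Integer seed.
#' @return A list with `a`, `b` ([deg_table()]s) and `truth` (shared genes,
#'   realized concordance, parameters).
#' @export
gen_deg_pair <- function(n_genes, n_deg_a, n_deg_b, overlap_target,
                         concordance_target, lfc_sd = 1, seed) {
  stopifnot(overlap_target >= 0, overlap_target <= 1,
            concordance_target >= 0, concordance_target <= 1, lfc_sd > 0)
  n_shared <- round(overlap_target * n_deg_b)
  if (n_shared > min(n_deg_a, n_deg_b) ||
      n_deg_a + n_deg_b - n_shared > n_genes) {
    stop("spec error: infeasible overlap for the given sizes")
  }
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  perm <- sample(genes)
  shared <- perm[seq_len(n_shared)]
  a_extra <- perm[n_shared + seq_len(n_deg_a - n_shared)]
  b_extra <- perm[n_deg_a + seq_len(n_deg_b - n_shared)]
  sig_a <- c(shared, a_extra)
  sig_b <- c(shared, b_extra)

  mag <- function(n) abs(rnorm(n, 0, lfc_sd)) + 0.25
  lfc_a <- setNames(sample(c(-1, 1), n_genes, TRUE) * mag(n_genes), genes)
  padj_a <- setNames(runif(n_genes, 0.051, 1), genes)
  padj_a[sig_a] <- runif(length(sig_a), 1e-4, 0.049)

  lfc_b <- setNames(sample(c(-1, 1), n_genes, TRUE) * mag(n_genes), genes)
  padj_b <- setNames(runif(n_genes, 0.051, 1), genes)
  padj_b[sig_b] <- runif(length(sig_b), 1e-4, 0.049)
  agree <- rbinom(n_shared, 1, concordance_target) == 1
  sgn <- sign(lfc_a[shared]) * ifelse(agree, 1, -1)
  coupled <- 0.25 + abs(0.8 * (abs(lfc_a[shared]) - 0.25) +
                          rnorm(n_shared, 0, 0.3 * lfc_sd))
  lfc_b[shared] <- sgn * coupled

  list(a = deg_table(genes, unname(lfc_a), unname(padj_a), "synthetic_a", "mouse"),
       b = deg_table(genes, unname(lfc_b), unname(padj_b), "synthetic_b", "mouse"),
       truth = list(shared = sort(shared), n_shared = n_shared,
                    realized_concordance = if (n_shared) mean(agree) else NA,
                    overlap_target = overlap_target,
                    concordance_target = concordance_target, seed = seed))
}

#' Generate a gene-set catalog with planted enrichment
#'
#' Planted sets sample their members with elevated odds from a designated
#' query list, so over-representation analysis should rank them first;
#' unplanted sets are uniform draws from the background.
#'
#' @param background Character vector: gene universe.
#' @param query Character vector: the query list planted sets favor.
#' @param n_sets Total number of sets (>= 1), including the planted ones.
#' @param planted Named numeric vector: set name -> enrichment odds
#'   (sampling-weight multiplier for query genes); may be empty.
#' @param set_size Length-2 integer range of set sizes (default 10-40).
#' @param seed Integer seed.
#' @return A list with `catalog` (a [gene_sets()]) and `truth`.
#' @export
gen_gene_sets <- function(background, query, n_sets, planted = numeric(0),
                          set_size = c(10, 40), seed) {
  stopifnot(n_sets >= 1, length(planted) <= n_sets,
            all(query %in% background))
  set.seed(seed)
  sizes <- sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
  w_planted <- function(odds) {
    ifelse(background %in% query, odds, 1)
  }
  n_null <- n_sets - length(planted)
  ids <- c(names(planted),
           if (n_null > 0) sprintf("NULL_SET_%03d", seq_len(n_null)))
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    sets[[i]] <- if (i <= length(planted)) {
      sort(sample(background, sizes[i], prob = w_planted(planted[i])))
    } else {
      sort(sample(background, sizes[i]))
    }
  }
  names(sets) <- ids
  list(catalog = gene_sets(sets), truth = list(planted = names(planted),
                                               odds = planted, seed = seed))
}

## ---- full regulatory fixture -----------------------------------------------

FUNNEL_STAGES <- c("blacklist", "no_yap1", "no_tead", "no_ortholog",
                   "no_motif", "not_down_2wk", "not_down_8wk")

# TEAD-like PFM: weakly informative flanks around a strong GGAATG core.
# The flanks keep the exact score distribution wide enough that a match
# p-value of 5e-5 is attainable at width 10.
tead_fixture_pfm <- function() {
  core <- c("G", "G", "A", "A", "T", "G")
  cols <- list(c(A = 40, C = 20, G = 20, T = 20),
               c(A = 20, C = 40, G = 20, T = 20))
  counts <- matrix(0, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[, 1] <- cols[[1]]; counts[, 2] <- cols[[2]]
  for (j in seq_along(core)) {
    v <- c(A = 1, C = 1, G = 1, T = 1); v[core[j]] <- 97
    counts[, 2 + j] <- v
  }
  counts[, 9] <- cols[[2]]; counts[, 10] <- cols[[1]]
  structure(list(motif_id = "SYN0001", name = "TEAD_SYNTH", counts = counts),
            class = "pfm")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# TRUE if any window of `s` (either strand) scores >= thr under M.
.has_hit <- function(s, M, thr) {
  f <- .scan_scores(.encode_seq(s), M)
  r <- .scan_scores(.encode_seq(.revcomp(s)), M)
  (length(f) && max(f) >= thr) || (length(r) && max(r) >= thr)
}

#' Generate the full regulatory fixture with planted funnel targets
#'
#' Writes, for a pseudo-human and a pseudo-mouse genome: FASTA (random
#' sequence with TEAD consensus motifs planted inside target promoter
#' peaks), TSS BED6, per-factor narrowPeak files (YAP1, TEAD1-4), a
#' blacklist BED, an ortholog TSV, two knockout-time-point DEG tables, and
#' the TEAD PFM in JASPAR format. Planted target genes pass every funnel
#' gate; each decoy is constructed to violate exactly one gate (its peaks
#' blacklisted; no YAP1 peak; no TEAD peak; missing ortholog; no motif, with
#' a one-mismatch near-miss planted instead; or not downregulated at one
#' time point). Promoter-peak sequence is rejection-sampled to be free of
#' threshold-level motif matches before planting, so motif presence is
#' exactly the planted truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_targets Number of planted target genes (default 19).
#' @param decoys_per_stage Decoys per violated gate (default 3).
#' @param n_background Extra genes with no ChIP evidence (default 10).
#' @param seed Integer seed.
#' @param p_cutoff Motif-match p-value the fixture is calibrated against
#'   (default 5e-5).
#' @return A `FixtureTruth` list: `planted_targets`, `decoys` (named vector
#'   gene -> violated stage), `background_genes`, `params`, `seed`; also
#'   written to `truth.json` in `out_dir`.
#' @export
gen_regulatory_fixture <- function(out_dir, n_targets = 19,
                                   decoys_per_stage = 3, n_background = 10,
                                   seed, p_cutoff = 5e-5) {
  n_genes <- n_targets + length(FUNNEL_STAGES) * decoys_per_stage + n_background
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "human"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "mouse"), showWarnings = FALSE)

  pfm <- tead_fixture_pfm()
  M <- pwm_matrix(pfm)
  thr <- pwm_threshold(pfm, p_cutoff = p_cutoff)
  cons <- pfm_consensus(pfm)
  near_miss <- cons
  substr(near_miss, 6, 6) <- "C"  # one core mismatch, far below threshold
  stopifnot(is.finite(thr))

  human_sym <- sprintf("GENE%03d", seq_len(n_genes))
  mouse_sym <- sprintf("Musg%03d", seq_len(n_genes))
  roles <- c(rep("target", n_targets),
             rep(FUNNEL_STAGES, each = decoys_per_stage),
             rep("background", n_background))

  factors <- c("YAP1", paste0("TEAD", 1:4))
  block <- 6000L
  tier_pool <- c(100L, 350L, 620L, 870L, 1200L)

  gene_factors <- lapply(seq_len(n_genes), function(i) {
    switch(roles[i],
           background = character(0),
           no_yap1 = c("TEAD1", sample(paste0("TEAD", 2:4), 1)),
           no_tead = "YAP1",
           c("YAP1", sample(paste0("TEAD", 1:4), sample(1:2, 1))))
  })

  build_species <- function(sp, syms) {
    chrom <- paste0(sp, "_chr1")
    glen <- n_genes * block
    genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    tss <- (seq_len(n_genes) - 1L) * block + 3000L
    strand <- rep(c("+", "-"), length.out = n_genes)

    peaks <- list()
    blacklist <- list()
    for (i in seq_len(n_genes)) {
      facs <- gene_factors[[i]]
      if (!length(facs)) next
      p_start <- tss[i] - 100L - (match(facs, factors) - 1L) * 10L
      p_end <- p_start + 200L
      score <- sample(tier_pool, length(facs), replace = TRUE) +
        sample(-40:40, length(facs), replace = TRUE)
      zero_score <- runif(length(facs)) < 0.2
      for (j in seq_along(facs)) {
        peaks[[length(peaks) + 1]] <- data.frame(
          factor = facs[j], chrom = chrom, start = p_start[j], end = p_end[j],
          name = sprintf("%s_%s_%s", sp, syms[i], facs[j]),
          score = if (zero_score[j]) 0L else score[j],
          qValue = score[j] / 10, gene_i = i, stringsAsFactors = FALSE)
      }
      if (roles[i] == "blacklist") {
        blacklist[[length(blacklist) + 1]] <- data.frame(
          chrom = chrom, start = min(p_start) - 50L, end = max(p_end) + 50L,
          stringsAsFactors = FALSE)
      }

      # Motif control inside the peak-bearing interval. Genes meant to pass
      # the motif gate get the full PWM consensus planted in their first
      # peak (it scores the attainable maximum, so it always matches).
      # no_motif decoys get their interval rejection-sampled until it holds
      # no threshold-level match on either strand, then a one-mismatch
      # near-miss of the consensus is planted to stress the threshold.
      anchor <- p_start[1] + 95L  # 0-based plant offset, inside first peak
      if (roles[i] == "no_motif") {
        scrub_lo <- min(p_start) - 9L
        scrub_hi <- max(p_end) + 9L
        repeat {
          s <- paste(genome_chars[(scrub_lo + 1):scrub_hi], collapse = "")
          at <- anchor - scrub_lo + 1L  # 1-based within region
          substr(s, at, at + nchar(near_miss) - 1L) <- near_miss
          if (!.has_hit(s, M, thr)) {
            genome_chars[(scrub_lo + 1):scrub_hi] <-
              strsplit(s, "", fixed = TRUE)[[1]]
            break
          }
          genome_chars[(scrub_lo + 1):scrub_hi] <-
            sample(c("A", "C", "G", "T"), scrub_hi - scrub_lo, replace = TRUE)
        }
      } else {
        genome_chars[(anchor + 1):(anchor + nchar(cons))] <-
          strsplit(cons, "", fixed = TRUE)[[1]]
      }
    }

    peak_df <- do.call(rbind, peaks)
    genome <- Biostrings::DNAStringSet(setNames(paste(genome_chars, collapse = ""),
                                                chrom))
    bl <- if (length(blacklist)) do.call(rbind, blacklist) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))

    # TSS as BED6: the strand-aware 5' end must land on `tss`
    bed <- data.frame(chrom = chrom,
                      start = ifelse(strand == "+", tss, tss - 199L),
                      end = ifelse(strand == "+", tss + 200L, tss + 1L),
                      name = syms, score = 0L, strand = strand,
                      stringsAsFactors = FALSE)
    list(chrom = chrom, genome = genome, peaks = peak_df, blacklist = bl,
         tss_bed = bed)
  }

  hs <- build_species("hs", human_sym)
  mm <- build_species("mm", mouse_sym)

  write_species <- function(sp_dir, st) {
    Biostrings::writeXStringSet(st$genome, file.path(sp_dir, "genome.fa"))
    write_bed(st$tss_bed, file.path(sp_dir, "tss.bed"))
    write_bed(st$blacklist, file.path(sp_dir, "blacklist.bed"))
    for (fac in factors) {
      pk <- st$peaks[st$peaks$factor == fac, , drop = FALSE]
      np <- narrowpeak_df(chrom = pk$chrom, start = pk$start, end = pk$end,
                          name = pk$name, score = pk$score,
                          strand = rep(".", nrow(pk)),
                          signalValue = round(pk$qValue / 3, 2),
                          pValue = pk$qValue + 2,
                          qValue = pk$qValue,
                          peak = rep(100L, nrow(pk)))
      write_narrowpeak(np, file.path(sp_dir, paste0(fac, ".narrowPeak")))
    }
  }
  write_species(file.path(out_dir, "human"), hs)
  write_species(file.path(out_dir, "mouse"), mm)

  keep_orth <- roles != "no_ortholog"
  write_ortholog_map(data.frame(human = human_sym[keep_orth],
                                mouse = mouse_sym[keep_orth]),
                     file.path(out_dir, "orthologs.tsv"))

  make_deg <- function(which_wk) {
    lfc <- numeric(n_genes); padj <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      down <- roles[i] %in% c("target", setdiff(FUNNEL_STAGES,
                                                paste0("not_down_", which_wk)))
      flipped <- roles[i] == paste0("not_down_", which_wk)
      if (down) {
        lfc[i] <- -(abs(rnorm(1)) + 0.3); padj[i] <- runif(1, 1e-4, 0.049)
      } else if (flipped) {
        lfc[i] <- abs(rnorm(1)) + 0.3; padj[i] <- runif(1, 1e-4, 0.049)
      } else {
        lfc[i] <- rnorm(1); padj[i] <- runif(1, 0.051, 1)
      }
    }
    deg_table(mouse_sym, lfc, padj, paste0("yt_", which_wk), "mouse")
  }
  deg2 <- make_deg("2wk")
  deg8 <- make_deg("8wk")
  write_deg_table(deg2, file.path(out_dir, "deg_2wk.tsv"))
  write_deg_table(deg8, file.path(out_dir, "deg_8wk.tsv"))
  write_jaspar_pfm(list(pfm), file.path(out_dir, "tead_motif.jaspar"))

  decoy_idx <- roles %in% FUNNEL_STAGES
  truth <- list(
    planted_targets = human_sym[roles == "target"],
    decoys = setNames(roles[decoy_idx], human_sym[decoy_idx]),
    background_genes = human_sym[roles == "background"],
    params = list(n_targets = n_targets, decoys_per_stage = decoys_per_stage,
                  n_background = n_background, p_cutoff = p_cutoff,
                  flank = 2000, threshold = thr),
    seed = seed)
  write_json_file(truth, file.path(out_dir, "truth.json"))
  invisible(truth)
}

#' Load a generated fixture directory into funnel-ready inputs
#'
#' @param dir A directory written by [gen_regulatory_fixture()].
#' @return A list with `human`, `mouse` (each: `peaks`, `blacklist`, `tss`,
#'   `genome`), `pfms`, `orthologs`, `deg_2wk`, `deg_8wk`, `truth`.
#' @export
load_fixture <- function(dir) {
  factors <- c("YAP1", paste0("TEAD", 1:4))
  load_sp <- function(sp) {
    sp_dir <- file.path(dir, sp)
    peaks <- lapply(setNames(factors, factors), function(f) {
      read_narrowpeak(file.path(sp_dir, paste0(f, ".narrowPeak")))
    })
    list(peaks = peaks,
         blacklist = read_bed(file.path(sp_dir, "blacklist.bed")),
         tss = read_tss(file.path(sp_dir, "tss.bed"), format = "bed6"),
         genome = read_genome(file.path(sp_dir, "genome.fa")))
  }
  list(human = load_sp("human"), mouse = load_sp("mouse"),
       pfms = read_jaspar_pfm(file.path(dir, "tead_motif.jaspar")),
       orthologs = read_ortholog_map(file.path(dir, "orthologs.tsv")),
       deg_2wk = read_deg_table(file.path(dir, "deg_2wk.tsv"), "yt_2wk", "mouse"),
       deg_8wk = read_deg_table(file.path(dir, "deg_8wk.tsv"), "yt_8wk", "mouse"),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
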