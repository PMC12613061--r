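# Small in-code fixture builders shared across test files.

make_deg <- function(genes, lfc, padj = rep(0.01, length(genes)),
                     id = "test", species = "mouse") {
  deg_table(genes, lfc, padj, id, species)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One narrowPeak row with sane defaults.
np_row <- function(chrom, start, end, name = "pk", score = 500L,
                   qValue = 50, peak = -1L) {
  regumirror:::narrowpeak_df(chrom = chrom, start = as.integer(start),
                             end = as.integer(end), name = name,
                             score = as.integer(score), strand = ".",
                             signalValue = 1, pValue = -1, qValue = qValue,
                             peak = as.integer(peak))
}

np_bind <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("narrowpeak", "data.frame")
  out
}

# Genome from named character sequences.
genome_of <- function(...) {
  Biostrings::DNAStringSet(unlist(list(...)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Pipeline-scale fixture: a full config over generated inputs.
pipeline_config <- function(fix, gmt, da, db) {
  sp_cfg <- function(sp) {
    facs <- c("YAP1", paste0("TEAD", 1:4))
    list(genome = file.path(fix, sp, "genome.fa"),
         tss = file.path(fix, sp, "tss.bed"),
         blacklist = file.path(fix, sp, "blacklist.bed"),
         peaks = lapply(setNames(facs, facs), function(f) {
           list(file.path(fix, sp, paste0(f, ".narrowPeak")))
         }))
  }
  list(
    alpha = 0.05,
    datasets = list(
      list(id = "pair_a", path = da, species = "mouse"),
      list(id = "pair_b", path = db, species = "mouse"),
      list(id = "yt_2wk", path = file.path(fix, "deg_2wk.tsv"),
           species = "mouse", role = "yt_2wk"),
      list(id = "yt_8wk", path = file.path(fix, "deg_8wk.tsv"),
           species = "mouse", role = "yt_8wk")),
    compare = list(list(a = "pair_a", b = "pair_b", background = 2000)),
    enrich = list(gmt = gmt, query = list(dataset = "pair_a",
                                          direction = "up"),
                  background = list("pair_a"), min_size = 5,
                  max_size = 500),
    gsea = list(gmt = gmt, ranked = "pair_a", n_perm = 200, seed = 11),
    funnel = list(human = sp_cfg("human"), mouse = sp_cfg("mouse"),
                  pfm = file.path(fix, "tead_motif.jaspar"),
                  orthologs = file.path(fix, "orthologs.tsv"),
                  deg_2wk = "yt_2wk", deg_8wk = "yt_8wk"),
    panel = list(genes = "from_funnel",
                 datasets = list("yt_2wk", "yt_8wk", "pair_a")))
}

build_pipeline_inputs <- function(seed = 11) {
  fix <- tempfile("fix")
  truth <- gen_regulatory_fixture(fix, n_targets = 4, decoys_per_stage = 1,
                                  n_background = 2, seed = seed)
  gp <- gen_deg_pair(2000, 500, 500, 0.6, 0.9, seed = seed + 1)
  da <- file.path(fix, "pair_a.tsv"); write_deg_table(gp$a, da)
  db <- file.path(fix, "pair_b.tsv"); write_deg_table(gp$b, db)
  gs <- gen_gene_sets(gp$a$gene,
                      filter_significant(gp$a, direction = "up")$gene,
                      n_sets = 8, planted = c(PLANTED = 15), seed = seed + 2)
  gmt <- file.path(fix, "sets.gmt"); write_gmt(gs$catalog, gmt)
  list(fix = fix, truth = truth,
       config = pipeline_config(fix, gmt, da, db))
}
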