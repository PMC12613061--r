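test_that("symbol harmonization trims, uppercases, and rejects blanks", {
  expect_equal(harmonize_symbol(c("Spp1", "SRF", " Nexn ")),
               c("SPP1", "SRF", "NEXN"))
  expect_error(harmonize_symbol(""), "invalid")
  expect_error(harmonize_symbol("   "), "invalid")
})

test_that("DEG reader harmonizes, keeps min-padj duplicate, preserves NA padj", {
  path <- write_lines_tmp(c("gene\tlog2fc\tpadj",
                            "Spp1\t1.2\t0.01",
                            "SRF\t-0.5\t0.2",
                            "SPP1\t0.9\t0.04",
                            "Nexn\t0.3\tNA"), ".tsv")
  tab <- suppressMessages(read_deg_table(path, "d1", "mouse"))
  expect_s3_class(tab, "deg_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$padj[tab$gene == "SPP1"], 0.01)
  expect_true(is.na(tab$padj[tab$gene == "NEXN"]))
  expect_identical(attr(tab, "dataset_id"), "d1")
})

test_that("DEG reader flags schema and numeric errors with location", {
  bad_schema <- write_lines_tmp(c("symbol\tlfc\tq", "A\t1\t0.1"), ".tsv")
  expect_error(suppressMessages(read_deg_table(bad_schema, "x", "mouse")),
               "missing column")
  bad_num <- write_lines_tmp(c("gene\tlog2fc\tpadj", "A\t1\t0.1",
                               "B\toops\t0.2"), ".tsv")
  expect_error(suppressMessages(read_deg_table(bad_num, "x", "mouse")),
               "line 2")
  empty <- write_lines_tmp("gene\tlog2fc\tpadj", ".tsv")
  expect_warning(
    withCallingHandlers(
      tab <- read_deg_table(empty, "x", "mouse"),
      message = function(m) {
        if (grepl("empty", conditionMessage(m))) warning("empty logged")
        invokeRestart("muffleMessage")
      }),
    "empty logged")
  expect_equal(nrow(tab), 0)
})

test_that("narrowPeak parsing keeps BED semantics and -1 sentinels", {
  path <- write_lines_tmp(
    c("chr1\t100\t600\tp1\t300\t.\t8.5\t40.0\t30.0\t250",
      "chr2\t10\t60\tp2\t0\t.\t1.0\t-1\t-1\t-1"))
  pk <- read_narrowpeak(path)
  expect_equal(pk$start[1], 100)
  expect_equal(pk$end[1], 600)
  expect_equal(pk$score[1], 300)
  expect_equal(pk$qValue[1], 30)
  expect_equal(pk$peak[1], 250)
  expect_equal(pk$qValue[2], -1)
  expect_equal(pk$peak[2], -1)
})

test_that("narrowPeak reader rejects malformed records", {
  expect_error(read_narrowpeak(write_lines_tmp("chr1\t1\t2\tx\t0\t.\t1\t1\t1")),
               "columns")
  expect_error(read_narrowpeak(
    write_lines_tmp("chr1\t600\t100\tp\t1\t.\t1\t-1\t-1\t-1")),
    "start >= end")
  expect_error(read_narrowpeak(
    write_lines_tmp("chr1\t100\t110\tp\t1\t.\t1\t-1\t-1\t50")),
    "summit")
})

test_that("narrowPeak and GMT survive write-read round trips", {
  set.seed(4)
  pk <- np_bind(np_row("chr1", 100, 600, "a", 300, 30),
                np_row("chr2", 5, 105, "b", 0, -1),
                np_row("chr10", 7, 8, "c", 1200, 120.5))
  p <- tempfile()
  write_narrowpeak(pk, p)
  expect_equal(read_narrowpeak(p), pk)

  gs <- gene_sets(list(S1 = c("A", "B", "C"), S2 = c("B", "D")),
                  descriptions = c(S1 = "first", S2 = "second"))
  g <- tempfile(fileext = ".gmt")
  write_gmt(gs, g)
  back <- read_gmt(g)
  expect_equal(unclass(back)[names(gs)], unclass(gs)[names(gs)],
               ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions"), attr(gs, "descriptions"))

  tab <- make_deg(c("AAA", "BBB"), c(1.5, -2), c(0.01, NA))
  t2 <- tempfile(fileext = ".tsv")
  write_deg_table(tab, t2)
  back2 <- suppressMessages(read_deg_table(t2, "test", "mouse"))
  expect_equal(as.data.frame(back2), as.data.frame(tab))
})

test_that("GMT reader harmonizes members and rejects duplicate terms", {
  g <- write_lines_tmp(c("S1\tdesc\tSox9\tSOX9\tFoo",
                         "S2\tdesc\tBar"), ".gmt")
  sets <- read_gmt(g)
  expect_equal(sets$S1, c("SOX9", "FOO"))
  dup <- write_lines_tmp(c("S1\td\tA", "S1\td\tB"), ".gmt")
  expect_error(read_gmt(dup), "duplicate term")
})

test_that("TSS extraction is strand-aware in both GTF and BED6", {
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "g1"; gene_name "GeneA";',
    'chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tgene_id "g2"; gene_name "GeneB";'),
    ".gtf")
  tss <- read_tss(gtf, "gtf")
  expect_equal(tss$tss[tss$gene == "GENEA"], 1000)
  expect_equal(tss$tss[tss$gene == "GENEB"], 1999)

  bed <- write_lines_tmp(c("chr2\t500\t900\tgeneX\t0\t-",
                           "chr2\t100\t400\tgeneY\t0\t+"), ".bed")
  tss2 <- read_tss(bed, "bed6")
  expect_equal(tss2$tss[tss2$gene == "GENEX"], 899)
  expect_equal(tss2$tss[tss2$gene == "GENEY"], 100)
  expect_error(read_tss(write_lines_tmp("chr1\t1\t2\tg\t0\t."), "bed6"),
               "strand")
})

test_that("GTF -> internal -> BED6 -> internal is idempotent", {
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t5001\t6000\t.\t+\t.\tgene_id "ga";',
    'chr3\tsrc\tgene\t101\t900\t.\t-\t.\tgene_id "gb";'), ".gtf")
  tss <- read_tss(gtf, "gtf")
  # write as BED6 single-base features at the TSS
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", tss$chrom,
                     ifelse(tss$strand == "+", tss$tss, tss$tss),
                     tss$tss + 1L, tss$gene, tss$strand), bed)
  tss2 <- read_tss(bed, "bed6")
  expect_equal(tss2[order(tss2$gene), ], tss[order(tss$gene), ],
               ignore_attr = TRUE)
})

test_that("JASPAR PFM parsing recovers consensus, multiple motifs, defaults", {
  path <- write_lines_tmp(c(
    ">M1 TEADish",
    "A  [  1  1 90  2  1  1 ]",
    "C  [  2  1  2  1  1  2 ]",
    "G  [ 90 90  4  1  1 90 ]",
    "T  [  2  3  1 91 92  2 ]",
    ">M2",
    "A [ 5 5 5 5 ]", "C [ 1 1 1 1 ]", "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"))
  pfms <- suppressMessages(read_jaspar_pfm(path))
  expect_length(pfms, 2)
  expect_equal(pfm_consensus(pfms[[1]]), "GGATTG")
  expect_equal(pfms[[2]]$name, pfms[[2]]$motif_id)
  expect_equal(ncol(pfms[[1]]$counts), 6)

  uneven <- write_lines_tmp(c(">M3", "A [ 1 2 3 4 ]", "C [ 1 2 3 ]",
                              "G [ 1 2 3 4 ]", "T [ 1 2 3 4 ]"))
  expect_error(read_jaspar_pfm(uneven), "unequal width")
  negative <- write_lines_tmp(c(">M4", "A [ 1 2 3 -4 ]", "C [ 1 2 3 4 ]",
                                "G [ 1 2 3 4 ]", "T [ 1 2 3 4 ]"))
  expect_error(read_jaspar_pfm(negative), "negative")
})

test_that("ortholog map deduplicates and keeps one-to-many pairs", {
  path <- write_lines_tmp(c("human_symbol\tmouse_symbol",
                            "SRF\tSrf", "NEXN\tNexn", "SRF\tSrf",
                            "FGFR2\tFgfr2", "FGFR2\tFgfr2b"), ".tsv")
  om <- suppressMessages(read_ortholog_map(path))
  expect_equal(nrow(om), 4)
  expect_equal(sum(om$human == "FGFR2"), 2)
  expect_error(read_ortholog_map(write_lines_tmp("a\tb\nX\tY", ".tsv")),
               "missing column")
})

test_that("readers reject randomly mutated fixture lines", {
  set.seed(99)
  good_np <- "chr1\t100\t600\tp1\t300\t.\t8.5\t40.0\t30.0\t250"
  # dropping any field breaks the 10-column contract
  for (drop in sample(1:10, 5)) {
    f <- strsplit(good_np, "\t")[[1]][-drop]
    expect_error(read_narrowpeak(write_lines_tmp(paste(f, collapse = "\t"))))
  }
})
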