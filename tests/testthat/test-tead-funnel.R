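test_that("tier classification reproduces every boundary", {
  expect_equal(as.character(classify_tier(c(0, 199, 200, 499, 500, 749,
                                            750, 999, 1000, 5000))),
               c("blue", "blue", "cyan", "cyan", "green", "green",
                 "yellow", "yellow", "red", "red"))
  expect_true(is.ordered(classify_tier(0L)))
  # total and stepwise non-decreasing over a dense score sweep
  sweep_tiers <- classify_tier(0:1500)
  expect_false(any(is.na(sweep_tiers)))
  expect_true(all(diff(as.integer(sweep_tiers)) >= 0))
  expect_error(classify_tier(-1), "non-negative")
})

test_that("effective score repairs zeroed columns from the q-value", {
  pk <- np_bind(np_row("c1", 0, 100, score = 300, qValue = 12),
                np_row("c1", 0, 100, score = 0, qValue = 30),
                np_row("c1", 0, 100, score = 0, qValue = -1))
  sc <- suppressMessages(effective_score(pk))
  expect_equal(sc, c(300L, 300L, 0L))
})

test_that("blacklist removal uses half-open 1 bp overlap semantics", {
  pk <- np_bind(np_row("c1", 100, 600, "a"), np_row("c1", 100, 600, "b"))
  bl_hit <- data.frame(chrom = "c1", start = 599, end = 700)
  bl_abut <- data.frame(chrom = "c1", start = 600, end = 700)
  expect_equal(nrow(suppressMessages(remove_blacklisted(pk, bl_hit))), 0)
  expect_equal(nrow(remove_blacklisted(pk, bl_abut)), 2)
  expect_equal(remove_blacklisted(pk, bl_abut[0, ]), pk)
})

test_that("promoter windows are symmetric, clipped, and per-TSS", {
  tss <- data.frame(gene = c("A", "B", "B"), chrom = "c1",
                    strand = c("+", "-", "-"), tss = c(5000L, 1500L, 9000L))
  w <- build_promoter_windows(tss)
  expect_equal(w$start[1], 3000)
  expect_equal(w$end[1], 7000)
  expect_equal(w$start[2], 0)   # left clip
  expect_equal(w$end[2], 3500)
  expect_equal(sum(w$gene == "B"), 2)
})

test_that("best promoter peak per gene-factor follows score then position", {
  windows <- build_promoter_windows(
    data.frame(gene = c("A", "B"), chrom = "c1", strand = "+",
               tss = c(5000L, 20000L)))
  pk <- np_bind(np_row("c1", 4000, 4200, "low", 300, 30),
                np_row("c1", 4500, 4700, "high", 800, 80),
                np_row("c1", 6999, 7200, "edge", 100, 10),
                np_row("c1", 50000, 50100, "far", 900, 90))
  occ <- assign_promoter_peaks(list(YAP1 = pk), windows, "human")
  a <- occ[occ$gene == "A", ]
  expect_equal(a$name, "high")
  expect_equal(a$tier, "yellow")
  expect_false("B" %in% occ$gene)
  # peak overlapping two genes' windows contributes to both
  win2 <- build_promoter_windows(
    data.frame(gene = c("X", "Y"), chrom = "c1", strand = "+",
               tss = c(5000L, 7000L)))
  both <- assign_promoter_peaks(list(YAP1 = np_row("c1", 5500, 5600, "mid",
                                                   500, 50)), win2, "human")
  expect_setequal(both$gene, c("X", "Y"))
  # equal scores: smaller start wins
  tie <- np_bind(np_row("c1", 4100, 4300, "second", 500, 50),
                 np_row("c1", 4000, 4200, "first", 500, 50))
  occ_tie <- assign_promoter_peaks(list(YAP1 = tie), windows, "human")
  expect_equal(occ_tie$name[occ_tie$gene == "A"], "first")
})

test_that("occupancy filter demands YAP1 plus at least one TEAD", {
  occ <- data.frame(
    species = "human",
    gene = c("A", "A", "B", "C", "C", "C", "C"),
    factor = c("YAP1", "TEAD1", "YAP1", paste0("TEAD", 1:4)),
    stringsAsFactors = FALSE)
  expect_equal(species_occupancy_filter(occ), "A")
})

test_that("cross-species consensus keeps any passing ortholog pairing", {
  om <- data.frame(human = c("SRF", "NEXN", "FGFR2", "FGFR2"),
                   mouse = c("SRF", "NEXN", "FGFR2", "FGFR2B"),
                   stringsAsFactors = FALSE)
  cons <- suppressMessages(cross_species_consensus(
    c("SRF", "FGFR2", "ORPHAN"), c("SRF", "FGFR2B"), om))
  expect_equal(cons$human, c("FGFR2", "SRF"))
  expect_equal(cons$mouse[cons$human == "FGFR2"], "FGFR2B")
  # human passing but mouse failing is dropped; unmapped human dropped
  expect_false("NEXN" %in% cons$human)
  expect_false("ORPHAN" %in% cons$human)
})

test_that("target panel gates on motif and consistent downregulation", {
  cons <- data.frame(human = c("AAA", "BBB", "CCC"),
                     mouse = c("MAA", "MBB", "MCC"), stringsAsFactors = FALSE)
  occ_h <- data.frame(gene = c("AAA", "BBB", "CCC"), factor = "YAP1",
                      score = c(600L, 1100L, 300L), stringsAsFactors = FALSE)
  occ_m <- data.frame(gene = c("MAA", "MBB", "MCC"), factor = "TEAD1",
                      score = c(800L, 250L, 999L), stringsAsFactors = FALSE)
  deg2 <- make_deg(c("MAA", "MBB", "MCC"), c(-1, -2, 1),
                   c(0.01, 0.01, 0.01), "yt_2wk")
  deg8 <- make_deg(c("MAA", "MBB", "MCC"), c(-0.5, -1, -1),
                   c(0.01, 0.04, 0.01), "yt_8wk")
  panel <- build_target_panel(cons, motif_genes = c("AAA", "BBB"),
                              deg_2wk = deg2, deg_8wk = deg8,
                              occ_human = occ_h, occ_mouse = occ_m)
  # CCC: up at 2wk; AAA+BBB pass all gates
  expect_equal(panel$gene, c("AAA", "BBB"))
  expect_equal(panel$human_tier, c("green", "red"))
  expect_equal(panel$mouse_tier, c("yellow", "cyan"))
  expect_equal(panel$log2fc_2wk, c(-1, -2))
  expect_true(all(panel$tead_motif))
  none <- build_target_panel(cons[0, ], character(0), deg2, deg8,
                             occ_h, occ_m)
  expect_equal(nrow(none), 0)
})
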