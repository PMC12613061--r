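test_that("DEG pair generator hits the overlap count exactly", {
  gp <- gen_deg_pair(3000, 800, 400, overlap_target = 0.5,
                     concordance_target = 1, seed = 2)
  sa <- filter_significant(gp$a)
  sb <- filter_significant(gp$b)
  expect_equal(length(intersect(sa$gene, sb$gene)), 200)
  expect_equal(nrow(sa), 800)
  expect_equal(nrow(sb), 400)
  expect_equal(direction_concordance(sa, sb)$fraction, 1)
  expect_error(gen_deg_pair(100, 50, 90, 1, 0.9, seed = 1), "infeasible")
  expect_error(gen_deg_pair(100, 90, 90, 0, 0.9, seed = 1), "infeasible")
})

test_that("DEG pair generator is seed-deterministic", {
  g1 <- gen_deg_pair(500, 100, 100, 0.6, 0.8, seed = 9)
  g2 <- gen_deg_pair(500, 100, 100, 0.6, 0.8, seed = 9)
  expect_identical(g1, g2)
  g3 <- gen_deg_pair(500, 100, 100, 0.6, 0.8, seed = 10)
  expect_false(identical(g1$a$log2fc, g3$a$log2fc))
})

test_that("planted gene sets rank first in ORA; null catalogs stay calm", {
  set.seed(79)
  bg <- sprintf("G%04d", 1:800)
  query <- sample(bg, 80)
  wins <- 0
  for (s in 1:20) {
    gs <- gen_gene_sets(bg, query, n_sets = 21, planted = c(PL = 25),
                        seed = s)
    res <- ora(query, bg, gs$catalog, min_size = 5, max_size = 200)
    if (nrow(res) && res$term_id[1] == "PL") wins <- wins + 1
  }
  expect_gte(wins, 19)  # >= 95% success over seeds
  # all-null catalog: average BH-significant count is tiny
  n_sig <- vapply(1:20, function(s) {
    gs <- gen_gene_sets(bg, query, n_sets = 20, seed = 100 + s)
    res <- ora(query, bg, gs$catalog, min_size = 5, max_size = 200)
    sum(res$padj < 0.05)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.05 * 20)
})

test_that("regulatory fixture recovers planted truth through the funnel", {
  dir <- tempfile("fix")
  truth <- gen_regulatory_fixture(dir, n_targets = 6, decoys_per_stage = 1,
                                  n_background = 4, seed = 83)
  fx <- suppressMessages(load_fixture(dir))
  res <- suppressMessages(run_funnel(fx$human, fx$mouse, fx$pfms,
                                     fx$orthologs, fx$deg_2wk, fx$deg_8wk))
  expect_setequal(res$panel$gene, truth$planted_targets)
  elim <- res$elimination[names(truth$decoys)]
  expect_equal(unname(elim), unname(truth$decoys))
  # funnel stage counts are monotone past the per-species stages
  chain <- res$stage_counts[c("consensus", "motif", "panel")]
  expect_true(all(diff(chain) <= 0))
})

test_that("no-motif decoys survive until, and die at, the motif gate", {
  dir <- tempfile("fix")
  truth <- gen_regulatory_fixture(dir, n_targets = 4, decoys_per_stage = 2,
                                  n_background = 2, seed = 89)
  fx <- suppressMessages(load_fixture(dir))
  res <- suppressMessages(run_funnel(fx$human, fx$mouse, fx$pfms,
                                     fx$orthologs, fx$deg_2wk, fx$deg_8wk))
  nm <- names(truth$decoys)[truth$decoys == "no_motif"]
  expect_true(all(nm %in% res$consensus$human))
  expect_false(any(nm %in% res$motif_genes))
})

test_that("every decoy passes all gates except its own", {
  # disabling a single gate must admit exactly that gate's decoys
  dir <- tempfile("fix")
  truth <- gen_regulatory_fixture(dir, n_targets = 4, decoys_per_stage = 1,
                                  n_background = 2, seed = 97)
  fx <- suppressMessages(load_fixture(dir))
  base <- suppressMessages(run_funnel(fx$human, fx$mouse, fx$pfms,
                                      fx$orthologs, fx$deg_2wk, fx$deg_8wk))
  # blacklist gate off
  h2 <- fx$human; h2$blacklist <- NULL
  m2 <- fx$mouse; m2$blacklist <- NULL
  no_bl <- suppressMessages(run_funnel(h2, m2, fx$pfms, fx$orthologs,
                                       fx$deg_2wk, fx$deg_8wk))
  bl_genes <- names(truth$decoys)[truth$decoys == "blacklist"]
  expect_setequal(no_bl$panel$gene, c(truth$planted_targets, bl_genes))
  # downregulation gate at 8 weeks off (reuse the 2wk table for both)
  no_8wk <- suppressMessages(run_funnel(fx$human, fx$mouse, fx$pfms,
                                        fx$orthologs, fx$deg_2wk, fx$deg_2wk))
  nd8 <- names(truth$decoys)[truth$decoys == "not_down_8wk"]
  expect_setequal(no_8wk$panel$gene, c(truth$planted_targets, nd8))
})

test_that("fixture files are byte-identical across runs with one seed", {
  d1 <- tempfile(); d2 <- tempfile()
  gen_regulatory_fixture(d1, n_targets = 3, decoys_per_stage = 1,
                         n_background = 2, seed = 101)
  gen_regulatory_fixture(d2, n_targets = 3, decoys_per_stage = 1,
                         n_background = 2, seed = 101)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("shared-gene Spearman rho rises with the concordance target", {
  rho_at <- function(ct) {
    mean(vapply(1:8, function(s) {
      gp <- gen_deg_pair(2000, 700, 700, 0.7, ct, seed = 1000 * s + ct * 100)
      suppressMessages(correlate_shared_lfc(filter_significant(gp$a),
                                            filter_significant(gp$b))$rho)
    }, numeric(1)))
  }
  rhos <- vapply(c(0.5, 0.7, 0.9, 1.0), rho_at, numeric(1))
  expect_true(all(diff(rhos) > 0))
})
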