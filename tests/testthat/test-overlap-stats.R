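test_that("significance filter is strict and direction-aware", {
  tab <- make_deg(c("A", "B", "C", "D"), c(-1, 1, 2, -2),
                  c(0.04, 0.05, 0.06, NA))
  expect_equal(filter_significant(tab)$gene, "A")
  both <- make_deg(c("U", "D"), c(1, -1), c(0.01, 0.01))
  expect_equal(filter_significant(both, direction = "down")$gene, "D")
  expect_equal(filter_significant(both, direction = "up")$gene, "U")
  all_na <- make_deg(c("A", "B"), c(1, 2), c(NA, NA))
  expect_equal(nrow(filter_significant(all_na)), 0)
})

test_that("hypergeometric upper tail matches hand enumeration and edge cases", {
  expect_equal(hypergeom_overlap_test(5, 8, 6, 20)$p_value, 700 / 38760,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_test(0, 8, 6, 20)$p_value, 1)
  expect_equal(hypergeom_overlap_test(6, 6, 6, 6)$p_value, 1)
  expect_equal(hypergeom_overlap_test(5, 8, 6, 20)$expected, 6 * 8 / 20)
  expect_error(hypergeom_overlap_test(7, 8, 6, 20), "domain")
  expect_error(hypergeom_overlap_test(2, 30, 6, 20), "domain")
})

test_that("hypergeometric test equals the big-integer oracle on random draws", {
  set.seed(11)
  for (i in 1:100) {
    N <- sample(2:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeom_overlap_test(k, K, n, N)$p_value,
                 oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle and its hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # monotone in the raw-p order, and the monotone repair (cumulative
    # minimum from the largest rank) is idempotent on the adjusted values
    sorted_adj <- adj[order(p)]
    expect_true(all(diff(sorted_adj) >= -1e-15))
    expect_equal(rev(cummin(rev(sorted_adj))), sorted_adj)
  }
})

test_that("venn partition covers the union with disjoint regions", {
  v <- venn_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                           C = c("c", "d", "e")))
  expect_equal(unname(v[c("A", "B", "C", "A&B", "A&C", "B&C", "A&B&C")]),
               c(1, 0, 1, 1, 0, 1, 1))
  same <- venn_partition(list(A = c("x", "y"), B = c("x", "y"),
                              C = c("x", "y")))
  expect_equal(unname(same["A&B&C"]), 2)
  expect_equal(sum(same), 2)
  disj <- venn_partition(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(disj[c("A", "B", "C")]), c(1, 1, 1))
  expect_equal(sum(disj), 3)
  expect_error(venn_partition(list(a = "1", b = "2", c = "3", d = "4")),
               "2 or 3")
  # property: counts always sum to |union|
  set.seed(31)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(1:20, 1)))
    expect_equal(sum(venn_partition(sets)),
                 length(unique(unlist(sets))))
  }
})

test_that("direction concordance counts sign agreement, excluding zeros", {
  a <- make_deg(c("A", "B", "C", "D"), c(1, -1, 1, 2))
  b <- make_deg(c("A", "B", "C", "D"), c(2, -3, -1, 4))
  cc <- direction_concordance(a, b)
  expect_equal(cc$n_shared, 4)
  expect_equal(cc$fraction, 0.75)
  expect_equal(direction_concordance(a, a)$fraction, 1)
  z <- make_deg(c("A", "B"), c(0, 1))
  expect_equal(direction_concordance(z, make_deg(c("A", "B"), c(1, 1)))$n_shared,
               1)
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  a <- make_deg(paste0("G", 1:4), c(1, 2, 2, 3))
  b <- make_deg(paste0("G", 1:4), c(1, 2, 3, 4))
  r <- correlate_shared_lfc(a, b)
  expect_equal(r$rho, 4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_equal(r$n_shared, 4)
  # monotone invariance
  b2 <- make_deg(paste0("G", 1:4), exp(c(1, 2, 3, 4)))
  expect_equal(correlate_shared_lfc(a, b2)$rho, r$rho)
  rev_b <- make_deg(paste0("G", 1:5), -(1:5))
  fwd_a <- make_deg(paste0("G", 1:5), 1:5)
  expect_equal(correlate_shared_lfc(fwd_a, rev_b)$rho, -1)
  expect_equal(correlate_shared_lfc(fwd_a, fwd_a)$rho, 1)
  expect_error(correlate_shared_lfc(make_deg("A", 1), make_deg("A", 1)),
               "insufficient")
  # cross-check p-value against cor.test's t approximation
  set.seed(41)
  x <- make_deg(paste0("G", 1:30), rnorm(30))
  y <- make_deg(paste0("G", 1:30), rnorm(30))
  got <- correlate_shared_lfc(x, y)
  ref <- suppressWarnings(cor.test(x$log2fc, y$log2fc, method = "spearman",
                                   exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("top-n upregulated selection orders by lfc, padj, then symbol", {
  tab <- make_deg(paste0("G", 1:12), c(12:3, 2, 2),
                  c(rep(0.02, 10), 0.03, 0.01))
  top <- top_n_upregulated(tab, tab$gene, 10)
  expect_length(top, 10)
  expect_equal(top[1], "G1")
  few <- top_n_upregulated(tab, paste0("G", 1:4), 10)
  expect_length(few, 4)
  tie <- make_deg(c("AAA", "BBB"), c(1, 1), c(0.03, 0.01))
  expect_equal(top_n_upregulated(tie, tie$gene, 1), "BBB")
})

test_that("pairwise comparison wrapper requires an explicit background", {
  a <- make_deg(c("A", "B", "C"), c(1, 2, 3), c(0.01, 0.01, 0.2))
  b <- make_deg(c("A", "B", "D"), c(1, -2, 1), c(0.01, 0.01, 0.01))
  expect_error(compare_deg_tables(a, b), "background")
  res <- compare_deg_tables(a, b, background_n = 10)
  expect_equal(res$overlap$k, 2)
  expect_equal(res$concordance$fraction, 0.5)
})
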