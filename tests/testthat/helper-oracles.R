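# Independent oracles used across the suite. Big integers are little-endian
# base-10000 limb vectors, so binomial coefficients up to C(60, 30) and
# their products are computed exactly, independently of R's phyper/choose.

big_from_int <- function(x) {
  v <- integer(0)
  while (x > 0) {
    v <- c(v, as.integer(x %% 10000))
    x <- x %/% 10000
  }
  if (!length(v)) v <- 0L
  v
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0L, n - length(a)))
  b <- c(b, rep(0L, n - length(b)))
  r <- a + b
  carry <- 0L
  for (i in seq_len(n)) {
    r[i] <- r[i] + carry
    carry <- r[i] %/% 10000L
    r[i] <- r[i] %% 10000L
  }
  if (carry > 0L) r <- c(r, carry)
  r
}

big_mul <- function(a, b) {
  # partial sums stay below length(a) * 9999^2 < 2^53, so doubles are exact
  r <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    r[idx] <- r[idx] + a[i] * b
  }
  carry <- 0
  for (i in seq_along(r)) {
    r[i] <- r[i] + carry
    carry <- floor(r[i] / 10000)
    r[i] <- r[i] - carry * 10000
  }
  while (carry > 0) {
    r <- c(r, carry %% 10000)
    carry <- carry %/% 10000
  }
  while (length(r) > 1 && r[length(r)] == 0) r <- r[-length(r)]
  r
}

big_to_double <- function(v) {
  sum(v * 10000^(seq_along(v) - 1))
}

# Pascal's triangle of exact big-integer binomial coefficients, additive only.
big_choose_table <- function(n_max) {
  tab <- vector("list", n_max + 1)
  tab[[1]] <- list(big_from_int(1))
  for (n in seq_len(n_max)) {
    row <- vector("list", n + 1)
    row[[1]] <- big_from_int(1)
    row[[n + 1]] <- big_from_int(1)
    if (n >= 2) {
      prev <- tab[[n]]
      for (k in 2:n) row[[k]] <- big_add(prev[[k - 1]], prev[[k]])
    }
    tab[[n + 1]] <- row
  }
  tab
}

BIG_CHOOSE <- big_choose_table(60)

big_choose <- function(n, k) {
  if (k < 0 || k > n) return(big_from_int(0))
  BIG_CHOOSE[[n + 1]][[k + 1]]
}

# Exact upper-tail hypergeometric P(X >= k) by big-integer enumeration.
oracle_hyper_upper <- function(k, K, n, N) {
  num <- big_from_int(0)
  for (x in seq(k, min(K, n))) {
    num <- big_add(num, big_mul(big_choose(K, x), big_choose(N - K, n - x)))
  }
  big_to_double(num) / big_to_double(big_choose(N, n))
}

# Literal step-up BH: sort ascending, multiply by m/rank, cumulative minimum
# from the largest rank, cap at 1, return in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, scaled[i])
    adj[i] <- running
  }
  pmin(adj, 1)[order(ord)]
}

# Two-sided Fisher p by full enumeration over tables with fixed margins;
# totals <= 40 keep choose() exact in doubles.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  denom <- choose(n, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / denom
  xs <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(a)
  sum(vapply(xs, prob, 1)[vapply(xs, prob, 1) <= p_obs * (1 + 1e-7)])
}

# Step-by-step running-sum GSEA enrichment score.
oracle_gsea_es <- function(ranked, set, weight) {
  genes <- names(ranked)
  hit <- genes %in% set
  n <- length(genes)
  w <- abs(ranked)^weight
  nr <- sum(w[hit])
  run <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / nr else -1 / (n - sum(hit))
    if (run > best_pos) best_pos <- run
    if (run < best_neg) best_neg <- run
  }
  unname(if (abs(best_pos) >= abs(best_neg)) best_pos else best_neg)
}

# Per-offset brute-force PWM scan of one sequence string (one strand).
oracle_scan <- function(s, M) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  w <- ncol(M)
  L <- length(v)
  if (L < w) return(numeric(0))
  vapply(seq_len(L - w + 1), function(o) {
    win <- v[o:(o + w - 1)]
    if (any(is.na(win))) return(-Inf)
    sum(M[cbind(win, seq_len(w))])
  }, numeric(1))
}

# Exhaustive 4^w threshold oracle: smallest attained score whose upper-tail
# probability under the background is <= p_cutoff (Inf if none).
oracle_pwm_threshold <- function(pfm, background = rep(0.25, 4),
                                 p_cutoff = 5e-5, pseudocount = 1) {
  M <- pwm_matrix(pfm, background, pseudocount)
  w <- ncol(M)
  grids <- do.call(expand.grid, rep(list(1:4), w))
  sc <- numeric(nrow(grids))
  pr <- rep(1, nrow(grids))
  for (j in seq_len(w)) {
    sc <- sc + M[cbind(grids[[j]], j)]
    pr <- pr * background[grids[[j]]]
  }
  # aggregate probability mass over (numerically) equal scores before the
  # tail cumsum, otherwise duplicated scores split their mass
  key <- round(sc, 9)
  mass <- tapply(pr, key, sum)
  uniq <- as.numeric(names(mass))
  ord <- order(uniq)
  uniq <- uniq[ord]; mass <- as.numeric(mass)[ord]
  tail_p <- rev(cumsum(rev(mass)))
  ok <- which(tail_p <= p_cutoff)
  if (!length(ok)) return(Inf)
  uniq[ok[1]]
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

# Random PFM with tunable information content.
random_pfm <- function(width, sharp = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) {
    v <- rep(1, 4)
    v[sample(4, 1)] <- sharp
    counts[, j] <- v + sample(0:3, 4, replace = TRUE)
  }
  structure(list(motif_id = sprintf("RND%02d", width), name = "random",
                 counts = counts), class = "pfm")
}

# The convolution discretizes per-column scores to `bin`-width cells, so a
# sequence whose exact score lies within w*bin of the cutoff boundary may
# land on either side. Equality with the 4^w enumeration therefore means:
# the threshold is never above the enumerated one by more than the band,
# and the true probability mass it admits beyond the band stays within
# p_cutoff.
expect_threshold_matches_enumeration <- function(pfm, p_cutoff, bin = 0.001) {
  w <- ncol(pfm$counts)
  band <- w * bin
  dp <- pwm_threshold(pfm, p_cutoff = p_cutoff, bin = bin)
  oracle <- oracle_pwm_threshold(pfm, p_cutoff = p_cutoff)
  if (is.infinite(oracle)) {
    expect_true(is.infinite(dp))
    return(invisible(NULL))
  }
  expect_lte(dp, oracle + band)
  M <- pwm_matrix(pfm)
  grids <- do.call(expand.grid, rep(list(1:4), w))
  sc <- numeric(nrow(grids))
  for (j in seq_len(w)) sc <- sc + M[cbind(grids[[j]], j)]
  expect_lte(mean(sc >= dp + band), p_cutoff)
}
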