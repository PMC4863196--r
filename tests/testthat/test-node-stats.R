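test_that("degree counts unique partners, not weights", {
  # star: center linked to 4 leaves
  m <- matrix(0, 5, 5)
  m[1, 2:5] <- c(7, 1, 2, 3)
  D <- dyad_matrix(m + t(m), node_ids = paste0("n", 1:5), symmetric = TRUE)
  deg <- degree_vector(D)
  expect_equal(unname(deg), c(4, 1, 1, 1, 1))
  # one heavy edge is still one partner
  m2 <- matrix(0, 3, 3); m2[1, 2] <- 7
  D2 <- dyad_matrix(m2, node_ids = c("a", "b", "c"))
  expect_equal(unname(degree_vector(D2, "out")), c(1, 0, 0))
  expect_equal(unname(degree_vector(D2, "in")), c(0, 1, 0))
  expect_equal(unname(degree_vector(D2, "all")), c(1, 1, 0))
})

test_that("degree and strength match brute-force scans on synthetic matrices", {
  D <- rand_dir_dm(15, 111, values = function(k) rpois(k, 0.5))
  m <- unclass(D)
  out_deg <- vapply(1:15, function(i) sum(m[i, ] > 0), numeric(1))
  in_deg <- vapply(1:15, function(i) sum(m[, i] > 0), numeric(1))
  all_deg <- vapply(1:15, function(i) sum(m[i, ] > 0 | m[, i] > 0), numeric(1))
  expect_equal(unname(degree_vector(D, "out")), out_deg)
  expect_equal(unname(degree_vector(D, "in")), in_deg)
  expect_equal(unname(degree_vector(D, "all")), all_deg)
  expect_equal(unname(strength_vector(D)),
               vapply(1:15, function(i) sum(m[i, ]), numeric(1)))
})

test_that("strength requires the directed network", {
  S <- rand_sym_dm(5, 112)
  expect_error(strength_vector(S), "directed")
  m <- matrix(0, 3, 3); m[1, 2] <- 2; m[1, 3] <- 3
  D <- dyad_matrix(m, node_ids = c("a", "b", "c"))
  expect_equal(strength_vector(D)[["a"]], 5)
  expect_equal(strength_vector(D)[["c"]], 0)
})

test_that("bipartite degree covers both modes", {
  M <- bipartite_matrix(rbind(c(2, 1, 0), c(0, 0, 3)),
                        row_ids = c("m1", "m2"), col_ids = c("f1", "f2", "f3"))
  deg <- degree_vector(M)
  expect_equal(deg[["m1"]], 2)
  expect_equal(deg[["m2"]], 1)
  expect_equal(deg[["f3"]], 1)
  expect_equal(length(deg), 5)
})

test_that("signed-rank test is exact under ties and matches wilcox.test without", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)
  expect_error(paired_signed_rank(x, x), "zero")
  # all differences -1: exact p from the 2^6 enumeration is 2/64
  res <- paired_signed_rank(x, x + 1)
  expect_equal(res$W, 0)
  expect_equal(res$n, 6)
  expect_equal(res$p, 2 / 64)
  # enumeration oracle with distinct magnitudes and mixed signs
  set.seed(120)
  d <- c(0.3, -1.2, 2.5, -0.7, 1.9, -3.1, 0.9)
  y <- setNames(rnorm(7), letters[1:7])
  res2 <- paired_signed_rank(y + d, y)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 7))
  W_all <- as.matrix(signs) %*% r
  p_le <- mean(W_all <= W_obs); p_ge <- mean(W_all >= W_obs)
  expect_equal(res2$W, W_obs)
  expect_equal(res2$p, min(1, 2 * min(p_le, p_ge)))
  # agreement with the standard exact test when there are no ties
  ref <- wilcox.test(y + d, y, paired = TRUE, exact = TRUE)
  expect_equal(res2$p, ref$p.value)
  expect_equal(res2$W, unname(ref$statistic))
})

test_that("large-sample signed-rank path gives sensible two-sided p-values", {
  set.seed(121)
  x <- setNames(rnorm(40), paste0("n", 1:40))
  y <- x + rnorm(40, mean = 0.8)
  res <- paired_signed_rank(x, y)
  ref <- wilcox.test(as.numeric(x), as.numeric(y), paired = TRUE,
                     exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$method, "normal approximation")
})

test_that("rank correlation respects monotone transforms and ties", {
  x <- setNames(c(3, 1, 4, 1.5, 9, 2.6), paste0("n", 1:6))
  expect_equal(rank_correlation(x, exp(x))$r_s, 1)
  expect_equal(rank_correlation(x, -x^3)$r_s, -1)
  # tied-heavy data: equals rank-then-Pearson oracle
  a <- setNames(c(1, 1, 2, 2, 3, 3, 4), paste0("n", 1:7))
  b <- setNames(c(2, 1, 1, 3, 3, 2, 4), paste0("n", 1:7))
  expect_equal(rank_correlation(a, b)$r_s, cor(rank(a), rank(b)))
  expect_error(rank_correlation(a, setNames(rep(1, 7), names(a))), "degenerate")
  # optional permutation p is reproducible
  r1 <- rank_correlation(a, b, n_perm = 199, seed = 3)
  r2 <- rank_correlation(a, b, n_perm = 199, seed = 3)
  expect_identical(r1$p_permutation, r2$p_permutation)
})

test_that("bipartite degree correlation matches hand-built oracles", {
  # two disjoint complete blocks: 1x1 and 3x3
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1
  m[2:4, 2:4] <- 1
  M <- bipartite_matrix(m, row_ids = paste0("m", 1:4), col_ids = paste0("f", 1:4))
  res <- bipartite_degree_correlation(M)
  edges <- which(m > 0, arr.ind = TRUE)
  oracle <- cor(rowSums(m > 0)[edges[, 1]], colSums(m > 0)[edges[, 2]],
                method = "spearman")
  expect_equal(res$r_s, oracle)
  expect_gt(res$r_s, 0)
  expect_equal(res$n_edges, 10)
  # star plus monogamous pairs: negative by oracle
  s <- matrix(0, 4, 6)
  s[1, 1:3] <- 1          # one male with three females
  s[2, 4] <- 1; s[3, 5] <- 1; s[4, 6] <- 1
  Ms <- bipartite_matrix(s, row_ids = paste0("m", 1:4), col_ids = paste0("f", 1:6))
  edges_s <- which(s > 0, arr.ind = TRUE)
  oracle_s <- suppressWarnings(
    cor(rowSums(s > 0)[edges_s[, 1]], colSums(s > 0)[edges_s[, 2]],
        method = "spearman"))
  if (is.na(oracle_s)) {
    expect_error(bipartite_degree_correlation(Ms), "degenerate")
  } else {
    expect_equal(bipartite_degree_correlation(Ms)$r_s, oracle_s)
    expect_lt(bipartite_degree_correlation(Ms)$r_s, 0)
  }
  # perfect monogamy: no variation in either endpoint degree
  mono <- bipartite_matrix(diag(4), row_ids = paste0("m", 1:4),
                           col_ids = paste0("f", 1:4))
  expect_error(bipartite_degree_correlation(mono), "degenerate")
})

test_that("the constrained null subsamples the possibility set at matched density", {
  set.seed(130)
  poss <- matrix(rbinom(15 * 12, 1, 0.6), 15, 12)
  obs <- poss * matrix(rbinom(15 * 12, 1, 0.5), 15, 12)
  # ensure enough structure
  obs[1, poss[1, ] > 0] <- 1
  M <- bipartite_matrix(obs, row_ids = paste0("m", 1:15),
                        col_ids = paste0("f", 1:12))
  P <- bipartite_matrix(poss, row_ids = paste0("m", 1:15),
                        col_ids = paste0("f", 1:12))
  res <- degree_correlation_null(M, P, n_sim = 500, seed = 5)
  expect_equal(res$edge_rate, sum(obs > 0) / sum(poss > 0))
  expect_true(res$p > 0 && res$p <= 1)
  # mean simulated edge count matches the observed count within 3 SE
  e_obs <- sum(obs > 0)
  se <- sqrt(sum(poss > 0) * res$edge_rate * (1 - res$edge_rate) / 500)
  expect_lt(abs(mean(res$simulated_edges) - e_obs), 3 * se)
  # reproducibility
  res2 <- degree_correlation_null(M, P, n_sim = 500, seed = 5)
  expect_identical(res$simulated, res2$simulated)
  expect_identical(res$p, res2$p)
  # observed edges outside the possibility set are reported
  P2 <- P; P2[1, 1] <- 0
  if (obs[1, 1] > 0) {
    expect_warning(degree_correlation_null(M, bipartite_matrix(P2),
                                           n_sim = 99, seed = 1), "possibility")
  }
  # when the possibility set equals the observed edges, every simulated
  # network is a subsample of true edges and the observed r has support
  resS <- degree_correlation_null(M, M, n_sim = 199, seed = 6)
  expect_true(min(resS$simulated) <= resS$observed + 1e-9)
  expect_equal(resS$edge_rate, 1)
})

test_that("two-sided tail doubles the smaller tail and caps at one", {
  set.seed(131)
  poss <- matrix(1, 10, 10)
  obs <- matrix(rbinom(100, 1, 0.4), 10, 10)
  obs[1, ] <- 1
  M <- bipartite_matrix(obs, row_ids = paste0("m", 1:10),
                        col_ids = paste0("f", 1:10))
  P <- bipartite_matrix(poss, row_ids = paste0("m", 1:10),
                        col_ids = paste0("f", 1:10))
  up <- degree_correlation_null(M, P, n_sim = 199, seed = 2, tail = "upper")
  two <- degree_correlation_null(M, P, n_sim = 199, seed = 2, tail = "two")
  lower <- (sum(up$simulated <= up$observed + 1e-12) + 1) / 200
  expect_equal(two$p, min(1, 2 * min(up$p, lower)))
})
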