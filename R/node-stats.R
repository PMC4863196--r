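#' Degree: number of unique partners
#'
#' Degree counts distinct partners linked by a positive weight,
#' regardless of the weight's size.  For a directed dyadic matrix,
#' `direction` selects partners the node acts on (`"out"`), is acted on
#' by (`"in"`), or either (`"all"`); for a symmetric matrix all three
#' coincide.  For a bipartite matrix, degree is the number of
#' opposite-mode partners and a value is returned for every node of both
#' modes.
#'
#' @param D a [dyad_matrix()] or [bipartite_matrix()].
#' @param direction `"all"` (default), `"out"` or `"in"`; ignored for
#'   bipartite input.
#' @return Named integer vector of degrees.
#' @export
degree_vector <- function(D, direction = c("all", "out", "in")) {
  direction <- match.arg(direction)
  if (inherits(D, "bipartite_matrix")) {
    m <- D > 0
    return(c(rowSums(m), colSums(m)))
  }
  stopifnot(inherits(D, "dyad_matrix"))
  m <- unclass_matrix(D) > 0
  switch(direction,
         out = rowSums(m),
         `in` = colSums(m),
         all = rowSums(m | t(m)))
}

#' Strength: total interaction weight instigated
#'
#' The row sums of a directed interaction matrix — the total number of
#' interactions a node instigated, regardless of partner identity.
#' Defined on the original directed networks; a symmetric matrix is
#' rejected because symmetrization discards who instigated.
#'
#' @param D a directed [dyad_matrix()].
#' @return Named numeric vector of out-strengths.
#' @export
strength_vector <- function(D) {
  stopifnot(inherits(D, "dyad_matrix"))
  if (is_symmetric(D)) {
    stop("strength is defined on the directed network; got a symmetric matrix")
  }
  rowSums(unclass_matrix(D))
}

#' Paired Wilcoxon signed-rank comparison of two node statistics
#'
#' Two-sided signed-rank test on per-node differences `x - y` (e.g. each
#' male's degree in the fighting vs the sperm-competition network).
#' Zero differences are dropped; tied absolute differences get average
#' ranks.  For `n <= 14` retained differences the null distribution of
#' the positive-rank sum `W` is enumerated exactly over all `2^n` sign
#' assignments (exact even under ties); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors named by node id, over the same node set.
#' @return A list of class `signed_rank_result`: `W` (positive-rank
#'   sum), `p`, `n` (non-zero differences), `method`.
#' @export
paired_signed_rank <- function(x, y) {
  xy <- align_node_stats(x, y)
  if (length(xy$x) < 5) stop("need at least 5 paired observations")
  d <- xy$x - xy$y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate comparison: all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 14) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4  # tie correction is implicit in the averaged ranks
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(W = W, p = p, n = n, method = method),
            class = "signed_rank_result")
}

# Exact two-sided p for the positive-rank sum given the (possibly tied,
# averaged) ranks: enumerate the distribution of W over all 2^n sign
# assignments by convolution on doubled ranks (which are integers).
signed_rank_exact_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1)  # dist[s + 1] = #assignments with 2W = s
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, N = %d, p = %.4g (%s)\n",
              x$W, x$n, x$p, x$method))
  invisible(x)
}

#' Spearman rank correlation between two node statistics
#'
#' Spearman's r_s with average ranks for ties.  The analytic p-value
#' comes from the large-sample approximation of [stats::cor.test()]; an
#' optional permutation p-value (permuting `y` against `x`, add-one
#' convention) is computed when `n_perm` is given.
#'
#' @inheritParams paired_signed_rank
#' @param n_perm optional number of permutations for a permutation
#'   p-value.
#' @param seed seed for the permutation stream.
#' @return A list of class `rank_correlation_result`: `r_s`, `p`, `n`,
#'   and `p_permutation` when requested.
#' @export
rank_correlation <- function(x, y, n_perm = NULL, seed = 1) {
  xy <- align_node_stats(x, y)
  if (length(xy$x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(xy$x) == 0 || stats::sd(xy$y) == 0) {
    stop("degenerate correlation: a vector is constant")
  }
  ct <- suppressWarnings(
    stats::cor.test(xy$x, xy$y, method = "spearman", exact = FALSE))
  out <- list(r_s = unname(ct$estimate), p = ct$p.value, n = length(xy$x))
  if (!is.null(n_perm)) {
    set.seed(seed)
    rx <- rank(xy$x)
    ry <- rank(xy$y)
    r_obs <- stats::cor(rx, ry)
    b <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(stats::cor(rx, sample(ry))) >= abs(r_obs) - 1e-12) b <- b + 1L
    }
    out$p_permutation <- (b + 1) / (n_perm + 1)
    out$n_perm <- n_perm
  }
  structure(out, class = "rank_correlation_result")
}

#' @export
print.rank_correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r_s = %.4f, N = %d, p = %.4g\n",
              x$r_s, x$n, x$p))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_permutation, x$n_perm))
  }
  invisible(x)
}

align_node_stats <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y))) {
    if (length(x) != length(y)) stop("vectors differ in length and are unnamed")
    return(list(x = as.numeric(x), y = as.numeric(y)))
  }
  if (!setequal(names(x), names(y))) {
    stop("node statistic vectors are over different node sets")
  }
  ids <- sort(names(x))
  list(x = as.numeric(x[ids]), y = as.numeric(y[ids]))
}

#' Degree correlation over the edges of a bipartite network
#'
#' For every unique linked pair (positive entry) the degrees of the two
#' endpoints are collected, and Spearman's correlation is computed over
#' edges.  A positive value means well-connected nodes link to
#' well-connected partners (assortativity by promiscuity in a mating
#' network).
#'
#' @param M a [bipartite_matrix()]; weights matter only through edge
#'   existence.
#' @return A list of class `degree_correlation_result`: `r_s`,
#'   `n_edges`, and the per-edge degree table `edges`.
#' @export
bipartite_degree_correlation <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  edges <- which(unclass(M) > 0, arr.ind = TRUE)
  if (nrow(edges) < 3) {
    stop("degenerate network: fewer than 3 edges")
  }
  rdeg <- rowSums(M > 0)
  cdeg <- colSums(M > 0)
  dm <- rdeg[edges[, 1]]
  df_ <- cdeg[edges[, 2]]
  if (stats::sd(dm) == 0 || stats::sd(df_) == 0) {
    stop("degenerate network: endpoint degrees constant on one side")
  }
  r_s <- stats::cor(dm, df_, method = "spearman")
  structure(list(
    r_s = r_s,
    n_edges = nrow(edges),
    edges = data.frame(row_id = rownames(M)[edges[, 1]],
                       col_id = colnames(M)[edges[, 2]],
                       row_degree = as.numeric(dm),
                       col_degree = as.numeric(df_))
  ), class = "degree_correlation_result")
}

#' @export
print.degree_correlation_result <- function(x, ...) {
  cat(sprintf("Bipartite degree correlation: r_s = %.4f over %d edges\n",
              x$r_s, x$n_edges))
  invisible(x)
}

#' Constrained null model for the mating-network degree correlation
#'
#' Compares the observed degree correlation of the mating network with
#' the distribution over random networks drawn from the space-time
#' possibility set: each pair that overlapped in both space and time is
#' included as an edge independently with probability
#' `E_obs / E_poss`, so simulated networks have, on average, the same
#' density as the observed one while respecting spatial and temporal
#' structure.  Degenerate draws (fewer than 3 edges or no degree
#' variation) are redrawn, up to `50 * n_sim` total draws.
#'
#' @param M observed [bipartite_matrix()] of matings.
#' @param possibility [bipartite_matrix()] with the same row/column ids;
#'   positive entries mark pairs that could have mated (see
#'   [mating_possibility()]).  Observed edges outside the possibility
#'   set trigger a warning and are added to it.
#' @param n_sim number of simulated networks (minimum 99).
#' @param seed integer seed; results are bit-reproducible.
#' @param tail `"upper"` (default; counts simulated correlations at
#'   least as large as observed) or `"two"`.
#' @return A list of class `null_distribution_result`: `observed`,
#'   `simulated` (length `n_sim`), `simulated_edges` (edge count of each
#'   simulated network), `edge_counts` (per-pair inclusion counts over
#'   the retained simulations), `p`, `n_sim`, `seed`, `tail`,
#'   `edge_rate`, `n_redraws`, `density_matched`.
#' @export
degree_correlation_null <- function(M, possibility, n_sim = 1000, seed = 1,
                                    tail = c("upper", "two")) {
  stopifnot(inherits(M, "bipartite_matrix"),
            inherits(possibility, "bipartite_matrix"))
  tail <- match.arg(tail)
  if (n_sim < 99) stop("'n_sim' must be at least 99")
  if (!identical(rownames(M), rownames(possibility)) ||
      !identical(colnames(M), colnames(possibility))) {
    stop("observed and possibility matrices must share row and column ids")
  }
  poss <- unclass(possibility) > 0
  obs_edges <- unclass(M) > 0
  outside <- obs_edges & !poss
  if (any(outside)) {
    warning(sum(outside), " observed edge(s) lie outside the possibility set;",
            " they were added to it", call. = FALSE)
    poss <- poss | outside
  }
  e_obs <- sum(obs_edges)
  e_poss <- sum(poss)
  if (e_poss == 0) stop("empty possibility set")
  rate <- e_obs / e_poss
  observed <- bipartite_degree_correlation(M)$r_s

  poss_idx <- which(poss)
  template <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  set.seed(seed)
  simulated <- numeric(n_sim)
  simulated_edges <- integer(n_sim)
  edge_counts <- matrix(0L, nrow(M), ncol(M), dimnames = dimnames(M))
  n_redraws <- 0L
  max_draws <- 50L * n_sim
  draws <- 0L
  i <- 1L
  while (i <= n_sim) {
    if (draws >= max_draws) {
      stop("degenerate redraw limit exceeded (", max_draws, " draws); ",
           "the possibility set is too sparse for the observed density")
    }
    draws <- draws + 1L
    keep <- poss_idx[stats::runif(length(poss_idx)) < rate]
    sim <- template
    sim[keep] <- 1
    r <- tryCatch(
      bipartite_degree_correlation(bipartite_matrix(sim))$r_s,
      error = function(e) NA_real_)
    if (is.na(r)) {
      n_redraws <- n_redraws + 1L
      next
    }
    simulated[i] <- r
    simulated_edges[i] <- length(keep)
    edge_counts[keep] <- edge_counts[keep] + 1L
    i <- i + 1L
  }
  p_upper <- (sum(simulated >= observed - 1e-12) + 1) / (n_sim + 1)
  p_lower <- (sum(simulated <= observed + 1e-12) + 1) / (n_sim + 1)
  p <- if (tail == "upper") p_upper else min(1, 2 * min(p_upper, p_lower))
  structure(list(
    observed = observed, simulated = simulated,
    simulated_edges = simulated_edges, edge_counts = edge_counts,
    p = p, n_sim = n_sim,
    seed = seed, tail = tail, edge_rate = rate, n_possible = e_poss,
    n_observed_edges = e_obs, n_redraws = n_redraws, density_matched = TRUE
  ), class = "null_distribution_result")
}

#' @export
print.null_distribution_result <- function(x, ...) {
  cat(sprintf(
    "Degree-correlation null model: observed r_s = %.4f, p = %.4g (%s tail)\n",
    x$observed, x$p, x$tail))
  cat(sprintf(
    "  %d simulated networks (edge rate %.3f over %d possible pairs, %d redraws)\n",
    x$n_sim, x$edge_rate, x$n_possible, x$n_redraws))
  invisible(x)
}
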