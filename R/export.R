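#' Export a dyadic or bipartite matrix as labelled CSV
#'
#' @param M a [dyad_matrix()] or [bipartite_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_adjacency_csv <- function(M, path) {
  stopifnot(inherits(M, "dyad_matrix") || inherits(M, "bipartite_matrix"))
  m <- M
  attr(m, "symmetric") <- NULL
  class(m) <- NULL
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Export a dyadic matrix as GraphML
#'
#' Writes a weighted graph (directed unless the matrix is flagged
#' symmetric) with a `weight` edge attribute and, optionally, a `sex`
#' node attribute.
#'
#' @param D a [dyad_matrix()].
#' @param path output file path.
#' @param sex optional named character vector of node sexes.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(D, path, sex = NULL) {
  stopifnot(inherits(D, "dyad_matrix"))
  mode <- if (is_symmetric(D)) "undirected" else "directed"
  m <- unclass_matrix(D)
  g <- igraph::graph_from_adjacency_matrix(m, mode = mode, weighted = TRUE)
  if (!is.null(sex)) {
    igraph::V(g)$sex <- unname(sex[node_ids(D)])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Quantile plot of a degree-correlation null distribution
#'
#' Shows the simulated degree correlations (median, 50% and 95%
#' quantile bands) with the observed value marked, in the style used to
#' compare observed mating-network assortativity against its
#' constrained null.
#'
#' @param x a `null_distribution_result`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.null_distribution_result <- function(x, ...) {
  q <- stats::quantile(x$simulated, c(0.025, 0.25, 0.5, 0.75, 0.975))
  graphics::plot(1, type = "n", xlim = c(0.5, 1.5),
                 ylim = range(c(x$simulated, x$observed)),
                 xaxt = "n", xlab = "", ylab = "degree correlation (r_s)",
                 ...)
  graphics::segments(0.8, q[c(1, 5)], 1.2, q[c(1, 5)], lty = 1)
  graphics::segments(0.85, q[c(2, 4)], 1.15, q[c(2, 4)], lty = 2)
  graphics::points(1, q[3], pch = 16)
  graphics::points(1, x$observed, pch = 8, cex = 1.5)
  graphics::legend("topright", pch = c(16, 8),
                   legend = c("simulated median", "observed"), bty = "n")
  invisible(x)
}
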