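#' Labelled dyadic interaction matrix
#'
#' A `dyad_matrix` is a square numeric matrix of pairwise interaction
#' strengths between labelled nodes, with a structurally zero diagonal
#' (no self-ties).  Directed matrices hold one value per ordered pair;
#' symmetric matrices (flagged with `symmetric = TRUE`) hold identical
#' reciprocal values and are treated as one value per unordered dyad by
#' all downstream statistics.
#'
#' @param values square numeric matrix; the diagonal is forced to zero.
#' @param node_ids character vector of unique node labels; defaults to the
#'   row names of `values`.
#' @param symmetric logical; if `TRUE` the matrix must be symmetric (it is
#'   made exactly so by copying the upper triangle onto the lower).
#' @return A matrix of class `dyad_matrix` with a `symmetric` attribute.
#' @examples
#' m <- rbind(c(0, 2, 0), c(1, 0, 3), c(0, 0, 0))
#' dyad_matrix(m, node_ids = c("a", "b", "c"))
#' @export
dyad_matrix <- function(values, node_ids = rownames(values), symmetric = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("'values' must be square, got ", nrow(values), " x ", ncol(values))
  }
  if (is.null(node_ids)) {
    node_ids <- paste0("n", seq_len(nrow(values)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(values)) {
    stop("'node_ids' length does not match matrix dimension")
  }
  if (anyDuplicated(node_ids)) {
    stop("node ids must be unique; duplicated: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(node_ids, node_ids)
  diag(values) <- 0
  if (symmetric) {
    if (max(abs(values - t(values))) > 1e-8 * (1 + max(abs(values)))) {
      stop("matrix flagged symmetric is not symmetric")
    }
    values[lower.tri(values)] <- t(values)[lower.tri(values)]
  }
  structure(values, class = c("dyad_matrix", "matrix"),
            symmetric = isTRUE(symmetric))
}

#' @export
print.dyad_matrix <- function(x, ...) {
  kind <- if (is_symmetric(x)) "symmetric" else "directed"
  cat(sprintf("<dyad_matrix: %d nodes, %s, %d nonzero off-diagonal entries>\n",
              nrow(x), kind, sum(x != 0)))
  print(unclass_matrix(x), ...)
  invisible(x)
}

#' @rdname dyad_matrix
#' @param x object to test or query.
#' @export
is_symmetric <- function(x) isTRUE(attr(x, "symmetric"))

#' @rdname dyad_matrix
#' @export
node_ids <- function(x) rownames(x)

unclass_matrix <- function(x) {
  attr(x, "symmetric") <- NULL
  class(x) <- NULL
  x
}

#' Labelled bipartite count matrix
#'
#' Rectangular nonnegative matrix linking two disjoint node sets, e.g.
#' males (rows) to females (columns) by mating counts, or individuals to
#' burrows by time observed.
#'
#' @param values numeric matrix with nonnegative entries.
#' @param row_ids,col_ids unique labels for the two modes; the two label
#'   sets must be disjoint.
#' @return A matrix of class `bipartite_matrix`.
#' @export
bipartite_matrix <- function(values, row_ids = rownames(values),
                             col_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("row and column ids are required")
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    stop("row and column ids must each be unique")
  }
  shared <- intersect(row_ids, col_ids)
  if (length(shared) > 0) {
    stop("row and column id sets must be disjoint; shared: ",
         paste(shared, collapse = ", "))
  }
  if (any(values < 0)) stop("bipartite matrix entries must be nonnegative")
  storage.mode(values) <- "double"
  dimnames(values) <- list(row_ids, col_ids)
  structure(values, class = c("bipartite_matrix", "matrix"))
}

#' @export
print.bipartite_matrix <- function(x, ...) {
  cat(sprintf("<bipartite_matrix: %d x %d, %d nonzero entries>\n",
              nrow(x), ncol(x), sum(x != 0)))
  y <- x
  class(y) <- NULL
  print(y, ...)
  invisible(x)
}

#' Vectorize the dyads of a dyadic matrix
#'
#' Extracts the off-diagonal values used by dyad-level statistics.  For
#' the unordered dyad set each pair contributes one value (the upper
#' triangle); for the ordered set every directed off-diagonal cell
#' contributes.
#'
#' @param D a [dyad_matrix()].
#' @param dyad_set `"unordered"` (default for symmetric matrices) or
#'   `"ordered"` (default for directed matrices).
#' @return Numeric vector of dyad values, in a fixed column-major order.
#' @export
dyad_values <- function(D, dyad_set = NULL) {
  m <- unclass_matrix(D)
  if (is.null(dyad_set)) {
    dyad_set <- if (is_symmetric(D)) "unordered" else "ordered"
  }
  dyad_set <- match.arg(dyad_set, c("unordered", "ordered"))
  if (dyad_set == "unordered") m[upper.tri(m)] else m[row(m) != col(m)]
}

# Rebuild a matrix from a vector in dyad_values() order.
matrix_from_dyads <- function(v, n, ids, dyad_set) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (dyad_set == "unordered") {
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dyad_matrix(m, symmetric = TRUE)
  } else {
    m[row(m) != col(m)] <- v
    dyad_matrix(m)
  }
}

check_same_nodes <- function(A, B, what = "matrices") {
  if (!identical(node_ids(A), node_ids(B))) {
    stop(what, " must share the same node ids in the same order")
  }
  invisible(TRUE)
}
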