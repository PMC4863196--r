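#' Directed fighting network
#'
#' Edge weight w(i -> j) counts the fights in which male `i` arrived at a
#' burrow and fought resident male `j`.  Every male in `males` appears as
#' a node even if he never fought (zero row and column).
#'
#' @param obs an [observation_set()].
#' @param males character vector of male ids to use as the node set;
#'   defaults to every male in the roster.  For the competitive analyses
#'   this is usually the set retained by [filter_isolates()].
#' @return A directed [dyad_matrix()] over `males`.
#' @export
build_fighting_network <- function(obs, males = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  males <- resolve_males(obs, males)
  n <- length(males)
  m <- matrix(0, n, n, dimnames = list(males, males))
  f <- obs$fights
  f <- f[f$arriving_male_id %in% males & f$resident_male_id %in% males, ,
         drop = FALSE]
  if (nrow(f) > 0) {
    tab <- table(factor(f$arriving_male_id, levels = males),
                 factor(f$resident_male_id, levels = males))
    m <- m + unclass(tab)
  }
  dyad_matrix(m)
}

#' Male-by-female mating matrix
#'
#' Counts matings with a successful spermatophore transfer; unsuccessful
#' mounts are excluded here (and only here).
#'
#' @inheritParams build_fighting_network
#' @param females female ids to use as columns; defaults to all females.
#' @return A [bipartite_matrix()] of transfer counts, males x females.
#' @export
build_mating_bipartite <- function(obs, males = NULL, females = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  males <- resolve_males(obs, males)
  if (is.null(females)) females <- obs$roster$id[obs$roster$sex == "female"]
  mt <- obs$matings
  mt <- mt[mt$spermatophore_transferred & mt$male_id %in% males &
             mt$female_id %in% females, , drop = FALSE]
  m <- matrix(0, length(males), length(females),
              dimnames = list(males, females))
  if (nrow(mt) > 0) {
    tab <- table(factor(mt$male_id, levels = males),
                 factor(mt$female_id, levels = females))
    m <- m + unclass(tab)
  }
  bipartite_matrix(m)
}

#' Sperm-competition network: one-mode projection of the mating matrix
#'
#' Two males are in sperm competition when they mated the same female.
#' The directed weight from `i` to `j` is the total number of times `i`
#' mated with any female also mated by `j`: each spermatophore is a unit
#' of investment competing for a share of a shared female's eggs, so a
#' male investing once in each of two shared females competes exactly as
#' strongly as one investing twice in a single shared female.
#'
#' @param M a male x female [bipartite_matrix()] of mating counts.
#' @return A directed [dyad_matrix()] over the males, where
#'   `w[i, j] = sum over females f mated by j of M[i, f]`.
#' @export
project_sperm_competition <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  counts <- unclass(M)
  class(counts) <- NULL
  shared <- counts %*% t(counts > 0)  # w(i->j) = sum_f M[i,f] * 1[M[j,f] > 0]
  dyad_matrix(shared, node_ids = rownames(M))
}

#' Temporal overlap: shared days of adult life
#'
#' The number of days each pair of adults was alive at the same time,
#' counting days inclusively: two individuals alive on the same single
#' day overlap by 1 day.
#'
#' @param obs an [observation_set()].
#' @param ids node ids (any mix of sexes); defaults to all males.
#' @return A symmetric [dyad_matrix()].
#' @export
build_temporal_overlap <- function(obs, ids = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  ids <- resolve_males(obs, ids)
  r <- obs$roster[match(ids, obs$roster$id), ]
  lo <- outer(r$emergence_day, r$emergence_day, pmax)
  hi <- outer(r$death_day, r$death_day, pmin)
  m <- pmax(hi - lo + 1L, 0L)
  dimnames(m) <- list(ids, ids)
  dyad_matrix(m, symmetric = TRUE)
}

# Directed spatial intermediate: w(i -> j) = i's total time at burrows
# both i and j were observed to use.  Exposed for the isolate filter and
# for callers wanting the asymmetric form.
spatial_intermediate <- function(obs, ids) {
  occ <- obs$occupancy
  occ <- occ[occ$individual_id %in% ids & occ$duration > 0, , drop = FALSE]
  burrows <- sort(unique(occ$burrow_id))
  tmat <- matrix(0, length(ids), length(burrows),
                 dimnames = list(ids, burrows))
  if (nrow(occ) > 0) {
    agg <- stats::aggregate(duration ~ individual_id + burrow_id, occ, sum)
    tmat[cbind(agg$individual_id, agg$burrow_id)] <- agg$duration
  }
  # sum over shared burrows of i's own time there
  w <- (tmat %*% t(tmat > 0))
  diag(w) <- 0
  w
}

#' Spatial overlap via shared burrow use
#'
#' Each individual's tie to a burrow is the total time observed there.
#' The directed pair weight w(i -> j) sums i's time over the burrows both
#' i and j used; the matrix is then symmetrized by the geometric mean of
#' the two directed weights, down-weighting unbalanced pairs.
#'
#' @inheritParams build_temporal_overlap
#' @return A symmetric [dyad_matrix()].
#' @export
build_spatial_overlap <- function(obs, ids = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  ids <- resolve_males(obs, ids)
  w <- spatial_intermediate(obs, ids)
  symmetrize_geometric(dyad_matrix(w))
}

#' Geometric-mean symmetrization of a directed network
#'
#' Replaces each pair of reciprocal weights by the square root of their
#' product, giving a single per-pair strength that weights balanced pairs
#' more heavily than unbalanced ones: reciprocal weights (5, 5) give 5
#' while (1, 9) give 3, although both pairs have arithmetic mean 5; a
#' pair with one zero weight gives 0.
#'
#' @param D a directed, nonnegative [dyad_matrix()].
#' @return A symmetric [dyad_matrix()] with entries
#'   `sqrt(D[i, j] * D[j, i])`.
#' @export
symmetrize_geometric <- function(D) {
  stopifnot(inherits(D, "dyad_matrix"))
  m <- unclass_matrix(D)
  if (any(m < 0)) stop("geometric-mean symmetrization requires nonnegative weights")
  out <- sqrt(m * t(m))
  dyad_matrix(out, symmetric = TRUE)
}

#' Center and scale the off-diagonal dyad values
#'
#' Subtracts the mean pairwise interaction strength and divides by the
#' standard deviation of all pairwise strengths, putting every predictor
#' on a common scale (standard deviations above/below the mean).  For a
#' symmetric matrix the statistics are taken over the unordered dyad set
#' (each pair once); for a directed matrix over all ordered off-diagonal
#' cells.  The population (divide-by-n) standard deviation is used.  The
#' diagonal stays zero and is excluded throughout.
#'
#' @param D a [dyad_matrix()] with at least two distinct off-diagonal
#'   values.
#' @return A [dyad_matrix()] whose dyad values have mean 0 and standard
#'   deviation 1.
#' @export
standardize_offdiag <- function(D) {
  stopifnot(inherits(D, "dyad_matrix"))
  v <- dyad_values(D)
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) {
    stop("degenerate scale: all off-diagonal values are equal (", v[1], ")")
  }
  m <- unclass_matrix(D)
  offdiag <- row(m) != col(m)
  m[offdiag] <- (m[offdiag] - mean(v)) / s
  dyad_matrix(m, symmetric = is_symmetric(D))
}

#' Males retained for the competitive analyses
#'
#' Males that never used the same burrow as another male are spatial
#' isolates: they cannot fight and are unlikely to enter sperm
#' competition, so they are dropped before network construction.  A male
#' is retained when he shares at least one burrow (positive observed
#' time) with at least one other male, at any time.
#'
#' @param obs an [observation_set()].
#' @return Character vector of retained male ids (sorted).
#' @export
filter_isolates <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  males <- obs$roster$id[obs$roster$sex == "male"]
  if (length(males) == 0) return(character())
  w <- spatial_intermediate(obs, males)
  keep <- rowSums(w > 0) > 0 | colSums(w > 0) > 0
  sort(males[keep])
}

#' Entrywise product of two aligned dyadic matrices
#'
#' Used to combine the spatial and temporal overlap matrices into a
#' possibility matrix that is nonzero only for pairs that both overlapped
#' in time and shared a burrow.
#'
#' @param A,B [dyad_matrix()] objects over the same node ids in the same
#'   order.
#' @return A [dyad_matrix()] with `out[i, j] = A[i, j] * B[i, j]`,
#'   symmetric when both inputs are.
#' @export
elementwise_product <- function(A, B) {
  stopifnot(inherits(A, "dyad_matrix"), inherits(B, "dyad_matrix"))
  check_same_nodes(A, B)
  dyad_matrix(unclass_matrix(A) * unclass_matrix(B),
              symmetric = is_symmetric(A) && is_symmetric(B))
}

resolve_males <- function(obs, ids) {
  if (is.null(ids)) {
    ids <- obs$roster$id[obs$roster$sex == "male"]
  } else {
    ids <- as.character(ids)
    missing <- setdiff(ids, obs$roster$id)
    if (length(missing) > 0) {
      stop("ids absent from roster: ", paste(missing, collapse = ", "))
    }
  }
  sort(ids)
}

#' Possibility matrix for male-female mating pairs
#'
#' Entry (m, f) is the product of the pair's spatial overlap (geometric
#' mean of shared-burrow times) and temporal overlap (shared adult days).
#' A pair can only have mated if both are positive, so the support of
#' this matrix is the candidate edge set for the constrained
#' degree-correlation null model.
#'
#' @param obs an [observation_set()].
#' @param males,females node ids; default to all males and all females.
#' @return A [bipartite_matrix()], males x females.
#' @export
mating_possibility <- function(obs, males = NULL, females = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  males <- resolve_males(obs, males)
  if (is.null(females)) females <- sort(obs$roster$id[obs$roster$sex == "female"])
  ids <- c(males, females)
  sp <- build_spatial_overlap(obs, ids)
  tm <- build_temporal_overlap(obs, ids)
  both <- elementwise_product(sp, tm)
  bipartite_matrix(unclass_matrix(both)[males, females, drop = FALSE])
}
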