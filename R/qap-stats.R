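#' Apply a node permutation to a dyadic matrix
#'
#' The quadratic assignment primitive: rows and columns are permuted
#' simultaneously, so `out[i, j] = D[perm[i], perm[j]]`.  This preserves
#' the dependence structure of the network (the multiset of dyad values,
#' degree sequences up to relabelling) while breaking any alignment with
#' a second matrix.  Node ids keep their original order: the permutation
#' moves values, not labels.
#'
#' @param D a [dyad_matrix()].
#' @param perm integer vector, a bijection on `1:nrow(D)`.
#' @return A [dyad_matrix()] with permuted values.
#' @export
permute_matrix <- function(D, perm) {
  stopifnot(inherits(D, "dyad_matrix"))
  n <- nrow(D)
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n))) {
    stop("'perm' must be a permutation of 1:", n)
  }
  m <- unclass_matrix(D)[perm, perm, drop = FALSE]
  dimnames(m) <- list(node_ids(D), node_ids(D))
  dyad_matrix(m, symmetric = is_symmetric(D))
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation between the dyad values of two matrices, with
#' significance from simultaneous row/column permutation of the second
#' matrix.  The two-sided p-value uses the add-one convention
#' `(b + 1) / (n_perm + 1)` where `b` counts permutations with
#' `|r*| >= |r|`; with `exact = TRUE` all `n!` permutations are
#' enumerated instead and `p` is the exact fraction (the identity
#' permutation guarantees `p > 0`).
#'
#' @param A,B [dyad_matrix()] objects over the same node set.  The
#'   unordered dyad set is used when both are symmetric, the ordered set
#'   otherwise.
#' @param n_perm number of sampled permutations (ignored when `exact`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations (requires <= 8 nodes).
#' @return A list of class `mantel_result` with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 2000, seed = 1, exact = FALSE) {
  stopifnot(inherits(A, "dyad_matrix"), inherits(B, "dyad_matrix"))
  check_same_nodes(A, B)
  dyad_set <- if (is_symmetric(A) && is_symmetric(B)) "unordered" else "ordered"
  va <- dyad_values(A, dyad_set)
  if (stats::sd(va) == 0) stop("degenerate correlation: matrix A is constant")
  if (stats::sd(dyad_values(B, dyad_set)) == 0) {
    stop("degenerate correlation: matrix B is constant")
  }
  corr_with <- function(Bm) {
    stats::cor(va, dyad_values(Bm, dyad_set))
  }
  r_obs <- corr_with(B)
  n <- nrow(A)
  if (exact) {
    perms <- all_permutations(n)
    r_star <- vapply(perms, function(p) corr_with(permute_matrix(B, p)),
                     numeric(1))
    p <- mean(abs(r_star) >= abs(r_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    if (n_perm < 1) stop("'n_perm' must be at least 1")
    set.seed(seed)
    b <- 0L
    for (i in seq_len(n_perm)) {
      r_star <- corr_with(permute_matrix(B, sample.int(n)))
      if (abs(r_star) >= abs(r_obs) - 1e-12) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel matrix correlation: r = %.4f, p = %.4g (%s)\n",
              x$r, x$p,
              if (x$exact) sprintf("exact, %d permutations", x$n_perm)
              else sprintf("%d sampled permutations", x$n_perm)))
  invisible(x)
}

# All n! permutations of 1:n as a list (guarded: meant for exact tests).
all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to 8 nodes (", n, " requested)")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Least-squares core used by every network regression: X already has an
# intercept column.  Returns coefficients, t-values and fit statistics.
ols_core <- function(X, y, names_) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop(collinearity_message(X, names_))
  }
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tss <- sum((y - mean(y))^2)
  list(coefficients = stats::setNames(as.numeric(coefs), names_),
       t_values = stats::setNames(as.numeric(coefs) / se, names_),
       residuals = res,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       residual_standard_error = sqrt(sigma2),
       degrees_of_freedom = df)
}

collinearity_message <- function(X, names_) {
  pred <- X[, -1, drop = FALSE]
  msg <- "rank-deficient design: predictors are collinear"
  if (ncol(pred) >= 2) {
    cc <- suppressWarnings(stats::cor(pred))
    diag(cc) <- 0
    cc[is.na(cc)] <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    msg <- paste0(msg, "; most correlated pair: ",
                  names_[-1][worst[1]], " and ", names_[-1][worst[2]],
                  sprintf(" (r = %.3f)", cc[worst[1], worst[2]]))
  }
  msg
}

#' Ordinary least squares network regression
#'
#' Regresses the dyad values of a response matrix on those of one or more
#' predictor matrices, with an intercept.  For symmetric inputs each
#' unordered dyad contributes one observation; degrees of freedom are
#' `n_dyads - n_predictors - 1`.
#'
#' @param y response [dyad_matrix()].
#' @param xs named list of predictor [dyad_matrix()] objects on the same
#'   node set.
#' @param dyad_set `"unordered"` (default when every matrix is symmetric)
#'   or `"ordered"`.
#' @return A list with `coefficients` (intercept first), `t_values`,
#'   `r_squared`, `residual_standard_error`, `degrees_of_freedom`,
#'   `n_dyads`.
#' @export
ols_network_fit <- function(y, xs, dyad_set = NULL) {
  prep <- prepare_dyadic_regression(y, xs, dyad_set)
  fit <- ols_core(prep$X, prep$yv, prep$names)
  fit$residuals <- NULL
  fit$n_dyads <- length(prep$yv)
  fit$dyad_set <- prep$dyad_set
  fit
}

prepare_dyadic_regression <- function(y, xs, dyad_set = NULL) {
  stopifnot(inherits(y, "dyad_matrix"))
  if (inherits(xs, "dyad_matrix")) xs <- list(xs)
  if (length(xs) == 0) stop("at least one predictor matrix is required")
  if (is.null(names(xs)) || any(names(xs) == "")) {
    names(xs) <- paste0("x", seq_along(xs))
  }
  for (x in xs) {
    stopifnot(inherits(x, "dyad_matrix"))
    check_same_nodes(y, x)
  }
  if (is.null(dyad_set)) {
    all_sym <- is_symmetric(y) && all(vapply(xs, is_symmetric, logical(1)))
    dyad_set <- if (all_sym) "unordered" else "ordered"
  }
  dyad_set <- match.arg(dyad_set, c("unordered", "ordered"))
  yv <- dyad_values(y, dyad_set)
  Xp <- vapply(xs, dyad_values, numeric(length(yv)), dyad_set = dyad_set)
  X <- cbind(`(Intercept)` = 1, Xp)
  if (length(yv) <= length(xs) + 1) {
    stop("too few dyads (", length(yv), ") for ", length(xs),
         " predictors plus intercept")
  }
  list(X = X, yv = yv, names = c("(Intercept)", names(xs)),
       dyad_set = dyad_set, n = nrow(y), ids = node_ids(y))
}

#' MRQAP network regression with Dekker double-semipartialling
#'
#' Fits the OLS network regression of [ols_network_fit()] and obtains
#' per-predictor permutation p-values robust to correlated predictors.
#' For each predictor `k`, its dyad values are residualized on the
#' remaining predictors (plus intercept); the residual matrix is
#' permuted by simultaneous row/column permutation; the response is
#' refit on the other predictors plus the permuted residuals; and the
#' pivotal statistic of the permuted term (its t-value by default) is
#' compared with the observed one.  Two-sided p-values use the add-one
#' convention `(b + 1) / (n_perm + 1)`; with `exact = TRUE` all `n!`
#' permutations are enumerated and `p` is the exact fraction.
#'
#' Coefficients and fit statistics are identical to [ols_network_fit()];
#' the permutation scheme affects only the p-values.
#'
#' @inheritParams ols_network_fit
#' @param n_perm number of sampled permutations (minimum 99).
#' @param seed integer seed; results are bit-reproducible given
#'   `(seed, n_perm)`.
#' @param statistic pivotal statistic inside the permutation loop:
#'   `"t"` (default, recommended for semipartialling) or `"coef"`.
#' @param exact enumerate all permutations (<= 8 nodes); `n_perm` is
#'   ignored.
#' @return An object of class `mrqap_result`: `predictor_names`,
#'   `coefficients` (with intercept), `permutation_p` (per predictor),
#'   `r_squared`, `residual_standard_error`, `degrees_of_freedom`,
#'   `n_dyads`, `n_permutations`, `seed`, `method`, `statistic`.
#' @export
mrqap_dsp <- function(y, xs, n_perm = 2000, seed = 1,
                      statistic = c("t", "coef"), dyad_set = NULL,
                      exact = FALSE) {
  statistic <- match.arg(statistic)
  prep <- prepare_dyadic_regression(y, xs, dyad_set)
  full <- ols_core(prep$X, prep$yv, prep$names)
  if (!exact && n_perm < 99) stop("'n_perm' must be at least 99")
  k_pred <- ncol(prep$X) - 1L
  pvals <- numeric(k_pred)
  perms <- if (exact) all_permutations(prep$n) else NULL

  for (k in seq_len(k_pred)) {
    col_k <- k + 1L
    others <- prep$X[, -col_k, drop = FALSE]
    qo <- qr(others)
    ek <- qr.resid(qo, prep$X[, col_k])
    Ek <- matrix_from_dyads(ek, prep$n, prep$ids, prep$dyad_set)
    obs_stat <- pivotal_stat(full, col_k, statistic)
    refit_stat <- function(perm) {
      ek_p <- dyad_values(permute_matrix(Ek, perm), prep$dyad_set)
      Xp <- cbind(others, ek_p)
      f <- ols_core(Xp, prep$yv, c(prep$names[-col_k], "perm"))
      pivotal_stat(f, ncol(Xp), statistic)
    }
    if (exact) {
      stat_star <- vapply(perms, refit_stat, numeric(1))
      pvals[k] <- mean(abs(stat_star) >= abs(obs_stat) - 1e-12)
    } else {
      set.seed(seed + k)
      b <- 0L
      for (i in seq_len(n_perm)) {
        if (abs(refit_stat(sample.int(prep$n))) >= abs(obs_stat) - 1e-12) {
          b <- b + 1L
        }
      }
      pvals[k] <- (b + 1) / (n_perm + 1)
    }
  }
  new_mrqap_result(full, prep, pvals,
                   n_perm = if (exact) factorial(prep$n) else n_perm,
                   seed = seed, method = "dsp", statistic = statistic,
                   exact = exact)
}

#' MRQAP with naive response permutation
#'
#' The classical QAP regression test: the response matrix itself is
#' permuted and the full model refit.  Valid when predictors are mutually
#' uncorrelated; with correlated predictors its p-values are distorted,
#' which is the motivation for the semipartialling scheme of
#' [mrqap_dsp()].  Provided as an independent cross-check.
#'
#' @inheritParams mrqap_dsp
#' @return An object of class `mrqap_result` (see [mrqap_dsp()]).
#' @export
mrqap_y_permute <- function(y, xs, n_perm = 2000, seed = 1,
                            statistic = c("t", "coef"), dyad_set = NULL,
                            exact = FALSE) {
  statistic <- match.arg(statistic)
  prep <- prepare_dyadic_regression(y, xs, dyad_set)
  full <- ols_core(prep$X, prep$yv, prep$names)
  if (!exact && n_perm < 99) stop("'n_perm' must be at least 99")
  k_pred <- ncol(prep$X) - 1L
  Y <- matrix_from_dyads(prep$yv, prep$n, prep$ids, prep$dyad_set)
  obs_stats <- vapply(seq_len(k_pred) + 1L, pivotal_stat, numeric(1),
                      fit = full, statistic = statistic)
  stat_for <- function(perm) {
    yv_p <- dyad_values(permute_matrix(Y, perm), prep$dyad_set)
    f <- ols_core(prep$X, yv_p, prep$names)
    vapply(seq_len(k_pred) + 1L, pivotal_stat, numeric(1),
           fit = f, statistic = statistic)
  }
  if (exact) {
    perms <- all_permutations(prep$n)
    stars <- vapply(perms, stat_for, numeric(k_pred))
    stars <- matrix(stars, nrow = k_pred)
    pvals <- rowMeans(abs(stars) >= abs(obs_stats) - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    b <- integer(k_pred)
    for (i in seq_len(n_perm)) {
      s <- stat_for(sample.int(prep$n))
      b <- b + as.integer(abs(s) >= abs(obs_stats) - 1e-12)
    }
    pvals <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  new_mrqap_result(full, prep, pvals, n_perm = n_used, seed = seed,
                   method = "y-permute", statistic = statistic, exact = exact)
}

pivotal_stat <- function(fit, col, statistic) {
  if (statistic == "t") fit$t_values[col] else fit$coefficients[col]
}

new_mrqap_result <- function(full, prep, pvals, n_perm, seed, method,
                             statistic, exact) {
  pred_names <- prep$names[-1]
  structure(list(
    predictor_names = pred_names,
    coefficients = full$coefficients,
    permutation_p = stats::setNames(pvals, pred_names),
    r_squared = full$r_squared,
    residual_standard_error = full$residual_standard_error,
    degrees_of_freedom = full$degrees_of_freedom,
    n_dyads = length(prep$yv),
    n_permutations = n_perm,
    seed = seed,
    method = method,
    statistic = statistic,
    exact = exact,
    dyad_set = prep$dyad_set
  ), class = "mrqap_result")
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MRQAP network regression (%s permutations, %s statistic)\n",
              x$method, x$statistic))
  tab <- data.frame(
    coefficient = x$coefficients[x$predictor_names],
    p = x$permutation_p[x$predictor_names])
  print(round(tab, 4))
  cat(sprintf(
    "R^2 = %.3f, residual SE = %.3f, df = %d, dyads = %d, %d permutations, seed = %d\n",
    x$r_squared, x$residual_standard_error, x$degrees_of_freedom,
    x$n_dyads, x$n_permutations, x$seed))
  invisible(x)
}

#' Tabulate an MRQAP result
#'
#' One row per predictor plus the model-level statistics, in the shape of
#' a standard network-regression results table.
#'
#' @param x an `mrqap_result`.
#' @param label optional label (e.g. a season identifier) repeated in the
#'   first column.
#' @return A data frame with columns `label`, `predictor`, `coefficient`,
#'   `p`, `residual_standard_error`, `degrees_of_freedom`, `r_squared`.
#' @export
mrqap_table <- function(x, label = "") {
  stopifnot(inherits(x, "mrqap_result"))
  data.frame(
    label = label,
    predictor = x$predictor_names,
    coefficient = as.numeric(x$coefficients[x$predictor_names]),
    p = as.numeric(x$permutation_p[x$predictor_names]),
    residual_standard_error = x$residual_standard_error,
    degrees_of_freedom = x$degrees_of_freedom,
    r_squared = x$r_squared,
    row.names = NULL
  )
}
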