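#' Run the full competition-network analysis
#'
#' Executes the three-prediction workflow on one season of observations:
#'
#' 1. Spatial isolates (males that never shared a burrow with another
#'    male) are removed; all male-male networks are built over the
#'    retained males.
#' 2. The directed fighting network, the male-female mating matrix and
#'    its sperm-competition projection, and the spatial and temporal
#'    overlap matrices are constructed.
#' 3. Mantel tests among the three predictors (fighting, space, time)
#'    are reported as a covariate pre-check — correlated covariates are
#'    the reason the regression uses semipartialling permutations.
#' 4. Fighting and sperm-competition networks are symmetrized by the
#'    geometric mean of reciprocal weights; each predictor is centered
#'    and scaled over its dyads; and [mrqap_dsp()] regresses
#'    sperm competition on fighting with space and time as covariates.
#' 5. Each male's degree in the fighting vs sperm-competition network is
#'    compared by a paired signed-rank test, and within-individual
#'    Spearman correlations are computed for degree (and for strength on
#'    the original directed networks).
#' 6. The mating network's degree correlation is tested against the
#'    space-time constrained edge-subsampling null of
#'    [degree_correlation_null()].
#'
#' All randomness flows from `seed` through fixed per-stage offsets, so
#' sub-analyses are independently reproducible and the whole report is
#' byte-identical across runs with identical inputs.
#'
#' @param obs an [observation_set()].
#' @param n_perm permutations for the MRQAP and Mantel tests.
#' @param n_sim simulated networks for the degree-correlation null.
#' @param seed top-level integer seed.
#' @param tail tail convention for the degree-correlation null
#'   (`"upper"` or `"two"`).
#' @param statistic pivotal statistic for the MRQAP permutations
#'   (`"t"` or `"coef"`).
#' @param verbose print stage-by-stage progress with counts.
#' @return A list of class `analysis_report` with elements `mrqap`,
#'   `mantel_checks`, `degree_comparison`, `within_individual`,
#'   `degree_correlation`, `counts`, and `provenance`.
#' @export
run_full_analysis <- function(obs, n_perm = 2000, n_sim = 1000, seed = 1,
                              tail = c("upper", "two"),
                              statistic = c("t", "coef"),
                              verbose = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  say <- function(...) if (verbose) message(sprintf(...))

  all_males <- obs$roster$id[obs$roster$sex == "male"]
  retained <- filter_isolates(obs)
  say("isolate filtering: %d of %d males retained",
      length(retained), length(all_males))
  if (length(retained) < 5) {
    stop("stage 'isolate filtering': only ", length(retained),
         " males retained; too few for the dyadic analyses")
  }

  fighting <- build_fighting_network(obs, males = retained)
  mating <- build_mating_bipartite(obs, males = retained)
  sperm <- project_sperm_competition(mating)
  space <- build_spatial_overlap(obs, ids = retained)
  time_ov <- build_temporal_overlap(obs, ids = retained)
  n_dyads <- choose(length(retained), 2)
  say("networks built over %d males (%d unordered dyads): %d fights, %d transfers",
      length(retained), n_dyads, sum(fighting), sum(mating))

  fighting_sym <- symmetrize_geometric(fighting)
  sperm_sym <- symmetrize_geometric(sperm)

  mantel_checks <- run_stage("Mantel covariate checks", {
    pairs <- list(
      fighting_space = list(fighting_sym, space),
      fighting_time = list(fighting_sym, time_ov),
      space_time = list(space, time_ov))
    out <- lapply(seq_along(pairs), function(i) {
      mantel_test(pairs[[i]][[1]], pairs[[i]][[2]], n_perm = n_perm,
                  seed = seed + 100 + i)
    })
    names(out) <- names(pairs)
    out
  })

  mrqap <- run_stage("MRQAP regression", {
    xs <- list(Fighting = standardize_offdiag(fighting_sym),
               Space = standardize_offdiag(space),
               Time = standardize_offdiag(time_ov))
    mrqap_dsp(sperm_sym, xs, n_perm = n_perm, seed = seed + 200,
              statistic = statistic)
  })
  say("MRQAP: R^2 = %.3f over %d dyads", mrqap$r_squared, mrqap$n_dyads)

  deg_fight <- degree_vector(fighting)
  deg_sperm <- degree_vector(sperm)
  degree_comparison <- run_stage("degree comparison", {
    w <- paired_signed_rank(deg_fight, deg_sperm)
    list(W = w$W, p = w$p, n = w$n, method = w$method,
         median_fighting_degree = stats::median(deg_fight),
         median_sperm_degree = stats::median(deg_sperm))
  })

  within_individual <- run_stage("within-individual correlations", {
    list(degree = rank_correlation(deg_fight, deg_sperm),
         strength = rank_correlation(strength_vector(fighting),
                                     strength_vector(sperm)))
  })

  degree_correlation <- run_stage("degree-correlation null model", {
    possibility <- mating_possibility(obs, males = retained)
    degree_correlation_null(mating, possibility, n_sim = n_sim,
                            seed = seed + 300, tail = tail)
  })
  say("degree correlation: observed r_s = %.3f, p = %.3g",
      degree_correlation$observed, degree_correlation$p)

  report <- list(
    mrqap = mrqap,
    mantel_checks = mantel_checks,
    degree_comparison = degree_comparison,
    within_individual = within_individual,
    degree_correlation = degree_correlation,
    counts = list(n_males = length(all_males),
                  n_retained = length(retained),
                  n_isolates = length(all_males) - length(retained),
                  n_dyads = n_dyads,
                  n_fights = nrow(obs$fights),
                  n_transferred = sum(obs$matings$spermatophore_transferred),
                  n_mating_edges = sum(mating > 0)),
    provenance = list(seed = seed, n_perm = n_perm, n_sim = n_sim,
                      tail = tail, statistic = statistic,
                      package_version = as.character(
                        utils::packageVersion("cricketnets")))
  )
  class(report) <- "analysis_report"
  report
}

run_stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", label, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Competition-network analysis report ==\n")
  cat(sprintf("%d males (%d retained after isolate filtering), %d dyads\n\n",
              x$counts$n_males, x$counts$n_retained, x$counts$n_dyads))
  cat("-- Mantel covariate checks --\n")
  for (nm in names(x$mantel_checks)) {
    m <- x$mantel_checks[[nm]]
    cat(sprintf("  %s: r = %.3f, p = %.4g\n", nm, m$r, m$p))
  }
  cat("\n-- Within-pair: MRQAP (sperm competition ~ fighting + space + time) --\n")
  print(x$mrqap)
  cat("\n-- Within-individual --\n")
  dc <- x$degree_comparison
  cat(sprintf("  degree comparison: medians %g (fighting) vs %g (sperm), W = %g, N = %d, p = %.4g\n",
              dc$median_fighting_degree, dc$median_sperm_degree,
              dc$W, dc$n, dc$p))
  cat(sprintf("  degree correlation: r_s = %.3f, p = %.4g\n",
              x$within_individual$degree$r_s, x$within_individual$degree$p))
  cat(sprintf("  strength correlation: r_s = %.3f, p = %.4g\n",
              x$within_individual$strength$r_s, x$within_individual$strength$p))
  cat("\n-- Mating-network degree correlation --\n")
  print(x$degree_correlation)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (the full report, excluding the bulky simulated
#' null draws), `mrqap_table.csv` (the network-regression results
#' table) and `null_distribution.csv` (one simulated degree correlation
#' per row, for quantile plots).  Output is byte-stable for identical
#' reports.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @param label optional label for the regression table rows.
#' @return Invisibly, the paths written.
#' @export
write_analysis_report <- function(report, dir, label = "") {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tab_path <- file.path(dir, "mrqap_table.csv")
  null_path <- file.path(dir, "null_distribution.csv")

  json <- list(
    mrqap = report$mrqap[c("predictor_names", "coefficients",
                           "permutation_p", "r_squared",
                           "residual_standard_error", "degrees_of_freedom",
                           "n_dyads", "n_permutations", "seed", "method",
                           "statistic")],
    mantel_checks = lapply(report$mantel_checks,
                           function(m) m[c("r", "p", "n_perm")]),
    degree_comparison = report$degree_comparison,
    within_individual = lapply(report$within_individual,
                               function(r) r[c("r_s", "p", "n")]),
    degree_correlation = report$degree_correlation[
      c("observed", "p", "n_sim", "seed", "tail", "edge_rate",
        "n_possible", "n_observed_edges", "n_redraws")],
    counts = report$counts,
    provenance = report$provenance
  )
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(mrqap_table(report$mrqap, label = label), tab_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(simulated_r = report$degree_correlation$simulated),
    null_path, row.names = FALSE, quote = FALSE)
  invisible(c(json = json_path, table = tab_path, null = null_path))
}
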