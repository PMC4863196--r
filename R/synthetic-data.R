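#' Configuration for the burrow-structured mating-system simulator
#'
#' The simulator emulates a season of observations of a burrow-dwelling
#' cricket population: adults emerge on staggered days, live for a
#' geometrically distributed number of days (truncated at season end),
#' and each day occupy one burrow drawn mostly from a home cluster of
#' burrows.  Males are sedentary residents; females rove in search of
#' singing males.  A male arriving at a burrow where another male sits
#' may fight him (fights happen on arrival, settled cohabitants do not
#' re-fight daily).  A female mates at most one male per burrow visit
#' (her phonotaxis target when he is present), with a spermatophore
#' transferred with fixed probability.  Two optional planted effects
#' are built from multipliers that equal 1 at strength 0, so null
#' configurations are exactly null:
#'
#' * `beta_fight_sperm` couples fighting and sperm competition within
#'   male pairs, in both causal directions: a female is preferentially
#'   attracted (weight `exp(beta)`) to males that fought one of her
#'   previous mates, and mates them more readily once there; and a male
#'   occasionally pays a brief aggressive visit to a sperm-competition
#'   rival (a male who inseminated one of his own mates) and fights him
#'   without displacing either resident.
#' * `assortativity_strength` plants a positive degree correlation
#'   (assortativity by promiscuity) in the mating network.  Promiscuity
#'   propensity is individual quality expressed as adult longevity,
#'   rank-scaled to (-1, 1).  At strength `a > 0`, promiscuous females
#'   move (and hence sample males) more often; a female's mate-seeking
#'   draw prefers males whose current partner count matches her own and
#'   whose quality is similar to hers; and a pair's mating probability
#'   is reinforced by the pair's joint partner counts.  All three
#'   multipliers are 1 at `a = 0`.
#'
#' Defaults describe a mid-sized population (40 males, 40 females, 40
#' burrows over a 90-day season with ~14-day adult lifespans); see
#' [synthetic_preset()] for population regimes calibrated to low- and
#' high-density field seasons and [planted_effect_defaults()] for the
#' documented planted-effect magnitudes used in power studies.
#'
#' @param n_males,n_females,n_burrows population and habitat sizes.
#' @param season_length days in the season.
#' @param emergence_spread adult emergence day is uniform on
#'   `1:emergence_spread` (must not exceed `season_length`).
#' @param mean_adult_lifespan mean adult lifespan in days (minimum 1
#'   day, truncated at season end).
#' @param lifespan_dispersion negative-binomial size parameter for the
#'   lifespan distribution: 1 (default) gives the geometric lifespans
#'   typical of wild insect adults (standard deviation roughly equal to
#'   the mean); large values give nearly equal lifespans, which makes
#'   pairwise exposure close to exchangeable — the regime used for
#'   permutation-test calibration studies.
#' @param burrow_cluster_count number of spatial clusters the burrows
#'   are partitioned into.
#' @param cluster_popularity exponent of the power-law weights used to
#'   assign individuals a home cluster: cluster `k` gets weight
#'   `k^-cluster_popularity`.  0 (default) assigns clusters uniformly;
#'   positive values concentrate the population in a few popular
#'   clusters (uneven habitat quality), which produces both frequent
#'   fighting among the concentrated males and a large fraction of
#'   spatially isolated males elsewhere — the low-density field regime.
#' @param cluster_tightness probability that a male's burrow draw stays
#'   within his home cluster.
#' @param moves_per_day daily probability that a male moves to a newly
#'   drawn burrow (otherwise he stays put).  Males are sedentary burrow
#'   residents.
#' @param female_moves_per_day,female_cluster_tightness the same two
#'   movement parameters for females, who rove more widely in search of
#'   mates; roving is what brings the sexes together at burrows.
#' @param female_attraction probability that a female's burrow draw
#'   targets a burrow currently occupied by a living male (phonotaxis
#'   towards singing males, uniform over occupied burrows); otherwise
#'   she draws by cluster like males do.
#' @param fight_prob_on_male_encounter probability that two males
#'   co-located on a day fight.
#' @param refight_prob probability that a fight is followed by a return
#'   bout the same day with the roles reversed.  Contests between
#'   closely matched males recur with either male initiating, which is
#'   what gives the directed fighting network reciprocal weights.
#' @param mating_rate_scale baseline daily mating rate for a co-located
#'   male-female pair; the mating probability is
#'   `1 - exp(-rate * multiplier)`.
#' @param spermatophore_success_prob probability a mating transfers a
#'   spermatophore.
#' @param beta_fight_sperm,assortativity_strength planted effects, see
#'   above; both 0 by default (null configuration).
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_males = 40, n_females = 40, n_burrows = 40,
                             season_length = 90, emergence_spread = 40,
                             mean_adult_lifespan = 14,
                             lifespan_dispersion = 1,
                             burrow_cluster_count = 16,
                             cluster_popularity = 0,
                             cluster_tightness = 0.95,
                             moves_per_day = 0.3,
                             female_moves_per_day = 0.5,
                             female_cluster_tightness = 0,
                             female_attraction = 0.4,
                             fight_prob_on_male_encounter = 0.8,
                             refight_prob = 0.5,
                             mating_rate_scale = 0.35,
                             spermatophore_success_prob = 0.8,
                             beta_fight_sperm = 0,
                             assortativity_strength = 0,
                             seed = 1) {
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              n_burrows = as.integer(n_burrows),
              season_length = as.integer(season_length),
              emergence_spread = as.integer(emergence_spread),
              mean_adult_lifespan = as.numeric(mean_adult_lifespan),
              lifespan_dispersion = as.numeric(lifespan_dispersion),
              burrow_cluster_count = as.integer(burrow_cluster_count),
              cluster_popularity = as.numeric(cluster_popularity),
              cluster_tightness = as.numeric(cluster_tightness),
              moves_per_day = as.numeric(moves_per_day),
              female_moves_per_day = as.numeric(female_moves_per_day),
              female_cluster_tightness = as.numeric(female_cluster_tightness),
              female_attraction = as.numeric(female_attraction),
              fight_prob_on_male_encounter = as.numeric(fight_prob_on_male_encounter),
              refight_prob = as.numeric(refight_prob),
              mating_rate_scale = as.numeric(mating_rate_scale),
              spermatophore_success_prob = as.numeric(spermatophore_success_prob),
              beta_fight_sperm = as.numeric(beta_fight_sperm),
              assortativity_strength = as.numeric(assortativity_strength),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_males > 0, n_females > 0, n_burrows > 0, season_length > 0,
              emergence_spread >= 1, emergence_spread <= season_length,
              mean_adult_lifespan >= 1, lifespan_dispersion > 0,
              burrow_cluster_count >= 1,
              burrow_cluster_count <= n_burrows, cluster_popularity >= 0,
              cluster_tightness >= 0, cluster_tightness <= 1,
              moves_per_day >= 0, moves_per_day <= 1,
              female_moves_per_day >= 0, female_moves_per_day <= 1,
              female_cluster_tightness >= 0, female_cluster_tightness <= 1,
              female_attraction >= 0, female_attraction <= 1,
              fight_prob_on_male_encounter >= 0,
              fight_prob_on_male_encounter <= 1,
              refight_prob >= 0, refight_prob <= 1,
              mating_rate_scale >= 0,
              spermatophore_success_prob >= 0, spermatophore_success_prob <= 1,
              beta_fight_sperm >= 0)
  })
  structure(cfg, class = "synthetic_config")
}

#' Preset simulator configurations
#'
#' Two field-season regimes scaled to the reported magnitudes of the
#' study system, plus a calibration regime:
#'
#' * `"y2006-like"`: a low-density season — 74 males among 151 adults,
#'   adults observed ~12 days on average, with a large fraction of
#'   males (roughly 4 in 10) never sharing a burrow with another male.
#' * `"y2013-like"`: a high-density season — 119 males among 239
#'   adults, ~14 observed days, with only ~1 in 7 males spatially
#'   isolated.  Density is controlled by burrows per individual and
#'   cluster structure, so the low-density preset yields a clearly
#'   higher isolate fraction than the high-density one.
#' * `"cohort"`: a synchronized cohort with homogeneous survival
#'   (narrow emergence window, low lifespan dispersion).  Under this
#'   regime pairwise exposure is close to exchangeable, which is the
#'   assumption behind the matrix-permutation tests; the package's
#'   type-I calibration and power studies therefore run here.  Field
#'   phenology (the other two presets, with geometric lifespans and a
#'   long emergence window) makes any two event networks share
#'   per-individual exposure, which genuinely inflates permutation
#'   tests — see the methods vignette.
#'
#' @param name `"y2006-like"`, `"y2013-like"` or `"cohort"`.
#' @param ... overrides passed to [synthetic_config()] (e.g. `seed`,
#'   planted effects).
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("y2006-like", "y2013-like", "cohort"),
                             ...) {
  name <- match.arg(name)
  base <- switch(name,
    "cohort" = list(lifespan_dispersion = 20, emergence_spread = 10),
    "y2006-like" = list(n_males = 74, n_females = 77, n_burrows = 140,
                        season_length = 90, emergence_spread = 45,
                        mean_adult_lifespan = 12, burrow_cluster_count = 70,
                        cluster_popularity = 0.8,
                        cluster_tightness = 0.97, moves_per_day = 0.2,
                        female_moves_per_day = 0.5,
                        female_cluster_tightness = 0,
                        fight_prob_on_male_encounter = 0.8,
                        mating_rate_scale = 0.35,
                        spermatophore_success_prob = 0.8),
    "y2013-like" = list(n_males = 119, n_females = 120, n_burrows = 120,
                        season_length = 90, emergence_spread = 45,
                        mean_adult_lifespan = 14, burrow_cluster_count = 60,
                        cluster_tightness = 0.95, moves_per_day = 0.3,
                        female_moves_per_day = 0.5,
                        female_cluster_tightness = 0,
                        fight_prob_on_male_encounter = 0.8,
                        mating_rate_scale = 0.35,
                        spermatophore_success_prob = 0.8))
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

#' Documented planted-effect magnitudes for calibration studies
#'
#' The magnitudes used by the package's own power analyses: strong
#' enough that the pipeline recovers each effect reliably at the preset
#' population sizes, while leaving null configurations untouched
#' (planted multipliers are exactly 1 at 0).
#'
#' @return Named list with `beta_fight_sperm` and
#'   `assortativity_strength`.
#' @export
planted_effect_defaults <- function() {
  list(beta_fight_sperm = 1.5, assortativity_strength = 2)
}

#' Generate a synthetic observation set
#'
#' Runs the daily movement / fighting / mating process described in
#' [synthetic_config()] and returns a fully validated
#' [observation_set()].  Occupancy duration is measured in days at a
#' burrow.  Identical configurations (including `seed`) give identical
#' observation sets, down to the bytes of the written CSV files.
#'
#' @param config a [synthetic_config()].
#' @return An [observation_set()].
#' @export
generate_observations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_m <- config$n_males
  n_f <- config$n_females
  n <- n_m + n_f
  male_ids <- sprintf("M%03d", seq_len(n_m))
  female_ids <- sprintf("F%03d", seq_len(n_f))
  ids <- c(male_ids, female_ids)
  burrow_ids <- sprintf("B%03d", seq_len(config$n_burrows))

  emergence <- sample.int(config$emergence_spread, n, replace = TRUE)
  lifespan <- 1L + stats::rnbinom(n, size = config$lifespan_dispersion,
                                  mu = config$mean_adult_lifespan - 1)
  death <- pmin(emergence + lifespan - 1L, config$season_length)

  cluster_of_burrow <- rep_len(seq_len(config$burrow_cluster_count),
                               config$n_burrows)
  home <- if (config$cluster_popularity == 0) {
    sample.int(config$burrow_cluster_count, n, replace = TRUE)
  } else {
    w <- seq_len(config$burrow_cluster_count)^-config$cluster_popularity
    sample.int(config$burrow_cluster_count, n, replace = TRUE,
               prob = w / sum(w))
  }
  cluster_burrows <- split(seq_len(config$n_burrows), cluster_of_burrow)

  tightness <- rep(c(config$cluster_tightness, config$female_cluster_tightness),
                   c(n_m, n_f))
  move_prob <- rep(c(config$moves_per_day, config$female_moves_per_day),
                   c(n_m, n_f))
  draw_cluster <- function(i) {
    if (stats::runif(1) < tightness[i]) {
      bs <- cluster_burrows[[home[i]]]
      bs[sample.int(length(bs), 1)]
    } else {
      sample.int(config$n_burrows, 1)
    }
  }

  loc <- matrix(NA_integer_, n, config$season_length)
  # promiscuity propensity = individual quality expressed as adult
  # longevity, rank-scaled to (-1, 1); inert at assortativity_strength = 0.
  # Longevity is what gives an individual mating opportunities, so
  # matching on it is what makes promiscuous individuals pair up.
  a_s <- config$assortativity_strength
  life_obs <- death - emergence + 1L
  s_m <- 2 * rank(life_obs[seq_len(n_m)], ties.method = "average") / (n_m + 1) - 1
  s_f <- 2 * rank(life_obs[seq(n_m + 1L, n)], ties.method = "average") / (n_f + 1) - 1
  males_alive <- lapply(seq_len(config$season_length), function(d) {
    which(emergence[seq_len(n_m)] <= d & death[seq_len(n_m)] >= d)
  })
  # fights happen on arrival; settled cohabitants do not re-fight daily
  arrived <- matrix(FALSE, n_m, config$season_length)

  fought <- matrix(FALSE, n_m, n_m)
  inseminated <- matrix(0L, n_m, n_f)

  # A female's attraction draw targets a singing male: uniformly when no
  # assortment is planted, otherwise weighted by exp(a * s_f * s_m)
  # (high-promiscuity females seek out high-promiscuity males) with
  # already-inseminated partners down-weighted by exp(-a) (novelty
  # seeking), which spreads a promiscuous female's matings over
  # distinct, similarly promiscuous partners.
  attract_prob <- rep(config$female_attraction, n_f)
  female_move_prob <- pmin(1, config$female_moves_per_day * exp(a_s * s_f))
  b_fs <- config$beta_fight_sperm
  draw_female <- function(i, d) {
    ma <- males_alive[[d]]
    fi <- i - n_m
    if (length(ma) > 0 && stats::runif(1) < attract_prob[fi]) {
      if (a_s == 0 && b_fs == 0) {
        j <- ma[sample.int(length(ma), 1)]
      } else {
        w <- rep(1, length(ma))
        if (a_s > 0) {
          # degree-matched seeking: a female with many past partners
          # targets males that also have many, and fresh females
          # target fresh males, similar in quality to herself
          dm_cur <- rowSums(inseminated[ma, , drop = FALSE] > 0L)
          df_cur <- sum(inseminated[, fi] > 0L)
          w <- w * exp(a_s * (sqrt(dm_cur * df_cur) / 2 -
                                (sqrt(dm_cur) - sqrt(df_cur))^2 -
                                (s_m[ma] - s_f[fi])^2))
        }
        if (b_fs > 0) {
          # consistent preference: males that fought her past mates are
          # of a similar type, so she is drawn to them too
          mates_f <- inseminated[, fi] > 0L
          if (any(mates_f)) {
            rival <- rowSums(fought[ma, mates_f, drop = FALSE]) > 0
            w <- w * exp(b_fs * rival)
          }
        }
        j <- ma[sample.int(length(ma), 1, prob = w / sum(w))]
      }
      last_target[fi] <<- j
      loc[j, d]
    } else {
      last_target[fi] <<- NA_integer_
      draw_cluster(i)
    }
  }

  f_day <- integer(); f_arr <- integer(); f_res <- integer(); f_bur <- integer()
  m_day <- integer(); m_male <- integer(); m_fem <- integer()
  m_transfer <- logical()

  # single day loop: female movement responds to the current state
  # (who is alive, whom she has mated), then fights, then matings.
  # Each burrow visit a female makes yields at most one mating partner
  # (her consort, preferentially the male she was seeking); a new
  # partner requires a new visit.  This mate monopolization is what
  # keeps fighting and sperm competition conditionally independent in
  # null configurations: a single female visit can never link the two
  # males she found at one burrow.
  cur_m <- rep(NA_integer_, n_m)
  cur_f <- rep(NA_integer_, n_f)
  consort <- rep(NA_integer_, n_f)   # chosen partner for the current visit
  chosen <- rep(FALSE, n_f)          # has she chosen during this visit?
  last_target <- rep(NA_integer_, n_f)
  for (d in seq_len(config$season_length)) {
    # male movement: sedentary residents who occasionally relocate
    for (i in males_alive[[d]]) {
      if (d == emergence[i]) {
        cur_m[i] <- draw_cluster(i)
        arrived[i, d] <- TRUE
      } else {
        if (stats::runif(1) < move_prob[i]) cur_m[i] <- draw_cluster(i)
        arrived[i, d] <- cur_m[i] != loc[i, d - 1]
      }
      loc[i, d] <- cur_m[i]
    }
    # planted within-pair coupling: a male may pay a brief aggressive
    # visit to a sperm-competition rival (a male who inseminated one of
    # his own mates) and fight him at the rival's burrow; the skirmish
    # does not displace either resident
    if (b_fs > 0) {
      for (i in males_alive[[d]]) {
        mates_i <- inseminated[i, ] > 0L
        if (!any(mates_i)) next
        rivals <- which(rowSums(inseminated[, mates_i, drop = FALSE] > 0L) > 0)
        rivals <- rivals[rivals != i & rivals %in% males_alive[[d]]]
        if (length(rivals) == 0) next
        if (stats::runif(1) < 1 - exp(-0.1 * b_fs * length(rivals))) {
          j <- if (length(rivals) == 1) rivals else
            rivals[sample.int(length(rivals), 1)]
          if (stats::runif(1) < config$fight_prob_on_male_encounter) {
            f_day <- c(f_day, d); f_arr <- c(f_arr, i)
            f_res <- c(f_res, j); f_bur <- c(f_bur, loc[j, d])
            fought[i, j] <- TRUE; fought[j, i] <- TRUE
            if (stats::runif(1) < config$refight_prob) {
              f_day <- c(f_day, d); f_arr <- c(f_arr, j)
              f_res <- c(f_res, i); f_bur <- c(f_bur, loc[j, d])
            }
          }
        }
      }
    }
    for (i in seq(n_m + 1L, n)) {
      if (d < emergence[i] || d > death[i]) next
      fi <- i - n_m
      if (d == emergence[i] ||
          stats::runif(1) < female_move_prob[fi]) {
        new_b <- draw_female(i, d)
        if (is.na(cur_f[fi]) || new_b != cur_f[fi]) {
          consort[fi] <- NA_integer_   # new visit, not yet chosen
          chosen[fi] <- FALSE
        }
        cur_f[fi] <- new_b
      }
      loc[i, d] <- cur_f[fi]
    }
    present <- which(!is.na(loc[, d]))
    if (length(present) < 2) next
    by_burrow <- split(present, loc[present, d])
    for (b in names(by_burrow)) {
      grp <- by_burrow[[b]]
      ms <- grp[grp <= n_m]
      fs <- grp[grp > n_m] - n_m
      if (length(ms) >= 2) {
        # fights happen on arrival: a male moving onto a burrow where
        # another male sits may fight him; settled cohabitants do not
        # re-fight every day
        pairs <- utils::combn(ms, 2)
        for (pp in seq_len(ncol(pairs))) {
          i <- pairs[1, pp]; j <- pairs[2, pp]
          arr_i <- arrived[i, d]; arr_j <- arrived[j, d]
          if (!arr_i && !arr_j) next
          if (stats::runif(1) < config$fight_prob_on_male_encounter) {
            if (arr_i && arr_j) {
              if (stats::runif(1) < 0.5) { arr <- i; res <- j } else { arr <- j; res <- i }
            } else if (arr_i) { arr <- i; res <- j } else { arr <- j; res <- i }
            f_day <- c(f_day, d); f_arr <- c(f_arr, arr)
            f_res <- c(f_res, res); f_bur <- c(f_bur, as.integer(b))
            fought[i, j] <- TRUE; fought[j, i] <- TRUE
            if (stats::runif(1) < config$refight_prob) {
              # return bout, roles reversed
              f_day <- c(f_day, d); f_arr <- c(f_arr, res)
              f_res <- c(f_res, arr); f_bur <- c(f_bur, as.integer(b))
            }
          }
        }
      }
      if (length(ms) >= 1 && length(fs) >= 1) {
        # one partner per visit: she chooses once (her phonotaxis
        # target if he is here, otherwise a male present when she first
        # meets any) and mates only him until she moves on
        for (f in fs) {
          if (!chosen[f]) {
            consort[f] <- if (!is.na(last_target[f]) && last_target[f] %in% ms) {
              last_target[f]
            } else if (length(ms) == 1) ms else ms[sample.int(length(ms), 1)]
            chosen[f] <- TRUE
          }
          if (!(consort[f] %in% ms)) next  # her choice left or died
          m <- consort[f]
          mult <- exp(a_s * (sqrt(sum(inseminated[m, ] > 0L) *
                                    sum(inseminated[, f] > 0L)) / 2 -
                               (s_m[m] - s_f[f])^2 / 2))
          mult <- min(mult, 20)
          if (config$beta_fight_sperm > 0 &&
              any(fought[m, ] & inseminated[, f] > 0L)) {
            mult <- mult * exp(config$beta_fight_sperm)
          }
          p_mate <- 1 - exp(-config$mating_rate_scale * mult)
          if (stats::runif(1) < p_mate) {
            transferred <- stats::runif(1) < config$spermatophore_success_prob
            m_day <- c(m_day, d); m_male <- c(m_male, m)
            m_fem <- c(m_fem, f); m_transfer <- c(m_transfer, transferred)
            if (transferred) inseminated[m, f] <- inseminated[m, f] + 1L
          }
        }
      }
    }
  }

  occ_rows <- which(!is.na(loc), arr.ind = TRUE)
  occ <- stats::aggregate(
    list(duration = rep(1, nrow(occ_rows))),
    by = list(individual_id = ids[occ_rows[, 1]],
              burrow_id = burrow_ids[loc[occ_rows]]),
    FUN = sum)

  if (length(f_day) == 0 || length(m_day) == 0) {
    warning("synthetic configuration produced ", length(f_day), " fights and ",
            length(m_day), " matings; consider a denser configuration",
            call. = FALSE)
  }

  observation_set(
    roster = data.frame(id = ids,
                        sex = rep(c("male", "female"), c(n_m, n_f)),
                        emergence_day = emergence, death_day = death),
    occupancy = occ[c("individual_id", "burrow_id", "duration")],
    fights = data.frame(day = f_day,
                        arriving_male_id = male_ids[f_arr],
                        resident_male_id = male_ids[f_res],
                        burrow_id = burrow_ids[f_bur]),
    matings = data.frame(day = m_day,
                         male_id = male_ids[m_male],
                         female_id = female_ids[m_fem],
                         spermatophore_transferred = m_transfer)
  )
}

#' Summary counts for an observation set
#'
#' Magnitude checks for generated (or read) data: population and event
#' counts, mean observed days per individual, and the male isolate
#' fraction (males that never shared a burrow with another male).
#'
#' @param obs an [observation_set()].
#' @return A one-row data frame of summary statistics.
#' @export
summarize_observations <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  males <- obs$roster$id[obs$roster$sex == "male"]
  n_m <- length(males)
  retained <- if (n_m > 0) filter_isolates(obs) else character()
  obs_days <- obs$roster$death_day - obs$roster$emergence_day + 1L
  data.frame(
    n_individuals = nrow(obs$roster),
    n_males = n_m,
    n_females = sum(obs$roster$sex == "female"),
    n_burrows_used = length(unique(obs$occupancy$burrow_id)),
    n_fights = nrow(obs$fights),
    n_matings = nrow(obs$matings),
    n_transferred = sum(obs$matings$spermatophore_transferred),
    mean_observed_days = if (nrow(obs$roster) > 0) mean(obs_days) else 0,
    n_isolates = n_m - length(retained),
    isolate_fraction = if (n_m > 0) (n_m - length(retained)) / n_m else 0
  )
}
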