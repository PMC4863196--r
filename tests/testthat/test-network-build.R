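test_that("fighting network counts arrivals by direction", {
  obs <- tiny_obs()
  f <- build_fighting_network(obs)
  expect_equal(f["m1", "m2"], 2)
  expect_equal(f["m2", "m1"], 1)
  expect_equal(f["m3", "m1"], 0)
  expect_false(is_symmetric(f))
  # no fights -> zero matrix
  f0 <- build_fighting_network(observation_set(obs$roster))
  expect_true(all(f0 == 0))
})

test_that("fighting network equals a brute-force tally on synthetic data", {
  obs <- generate_observations(small_cfg(3))
  males <- sort(obs$roster$id[obs$roster$sex == "male"])
  f <- build_fighting_network(obs)
  oracle <- matrix(0, length(males), length(males),
                   dimnames = list(males, males))
  for (k in seq_len(nrow(obs$fights))) {
    row <- obs$fights[k, ]
    oracle[row$arriving_male_id, row$resident_male_id] <-
      oracle[row$arriving_male_id, row$resident_male_id] + 1
  }
  expect_equal(unclass(f)[males, males], oracle, ignore_attr = TRUE)
})

test_that("mating matrix counts only spermatophore transfers", {
  obs <- tiny_obs()
  M <- build_mating_bipartite(obs)
  expect_equal(M["m1", "f1"], 1)  # 2 matings, 1 transferred
  expect_equal(M["m2", "f1"], 1)
  expect_equal(M["m1", "f2"], 1)
  expect_equal(M["m3", "f1"], 0)
  none <- obs
  none$matings$spermatophore_transferred <- FALSE
  expect_true(all(build_mating_bipartite(none) == 0))
})

test_that("sperm-competition projection follows the investment rule", {
  # one mating with each of two shared females vs two matings with one
  # shared female give identical pair strengths
  mk <- function(m) bipartite_matrix(m, row_ids = c("i", "j"),
                                     col_ids = c("fa", "fb"))
  two_females <- project_sperm_competition(mk(rbind(c(1, 1), c(1, 1))))
  one_female <- project_sperm_competition(mk(rbind(c(2, 0), c(2, 0))))
  expect_equal(two_females["i", "j"], 2)
  expect_equal(two_females["j", "i"], 2)
  expect_equal(one_female["i", "j"], 2)
  expect_equal(one_female["j", "i"], 2)
  # disjoint females -> no competition
  disjoint <- project_sperm_competition(mk(rbind(c(3, 0), c(0, 2))))
  expect_true(all(disjoint == 0))
})

test_that("projection is invariant to female relabelling and inert females", {
  obs <- generate_observations(small_cfg(4))
  M <- build_mating_bipartite(obs)
  P <- project_sperm_competition(M)
  # brute force from the definition
  males <- rownames(M)
  oracle <- matrix(0, length(males), length(males),
                   dimnames = list(males, males))
  for (i in males) for (j in males) {
    if (i == j) next
    oracle[i, j] <- sum(M[i, M[j, ] > 0])
  }
  expect_equal(unclass(P), oracle, ignore_attr = TRUE)
  # permuting female columns changes nothing
  Mp <- bipartite_matrix(M[, rev(colnames(M))])
  expect_equal(unclass(project_sperm_competition(Mp)), unclass(P),
               ignore_attr = TRUE)
  # a female mated by a single male adds nothing
  Mx <- cbind(unclass(M), extra = c(5, rep(0, nrow(M) - 1)))
  Mx <- bipartite_matrix(Mx)
  expect_equal(unclass(project_sperm_competition(Mx)), unclass(P),
               ignore_attr = TRUE)
})

test_that("temporal overlap counts shared days inclusively", {
  obs <- observation_set(data.frame(
    id = c("a", "b", "c"), sex = "male",
    emergence_day = c(10L, 15L, 40L), death_day = c(20L, 30L, 50L)))
  tm <- build_temporal_overlap(obs)
  expect_equal(tm["a", "b"], 6)  # days 15..20
  expect_equal(tm["a", "c"], 0)  # disjoint
  expect_equal(diag(unclass(tm)), c(a = 0, b = 0, c = 0))
  expect_true(is_symmetric(tm))
})

test_that("temporal overlap equals brute-force day enumeration", {
  obs <- generate_observations(small_cfg(5))
  ids <- sort(obs$roster$id)
  tm <- build_temporal_overlap(obs, ids = ids)
  r <- obs$roster[match(ids, obs$roster$id), ]
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    expected <- if (i == j) 0 else {
      length(intersect(seq(r$emergence_day[i], r$death_day[i]),
                       seq(r$emergence_day[j], r$death_day[j])))
    }
    expect_equal(unname(tm[i, j]), expected)
  }
})

test_that("spatial overlap symmetrizes shared-burrow time geometrically", {
  obs <- observation_set(
    roster = data.frame(id = c("i", "j"), sex = "male",
                        emergence_day = 1L, death_day = 20L),
    occupancy = data.frame(individual_id = c("i", "j"),
                           burrow_id = c("b", "b"), duration = c(4, 9)))
  s <- build_spatial_overlap(obs)
  expect_equal(s["i", "j"], 6)  # sqrt(4 * 9)
  # no shared burrow -> zero
  obs2 <- observation_set(
    roster = data.frame(id = c("i", "j"), sex = "male",
                        emergence_day = 1L, death_day = 20L),
    occupancy = data.frame(individual_id = c("i", "j"),
                           burrow_id = c("b1", "b2"), duration = c(4, 9)))
  expect_equal(build_spatial_overlap(obs2)["i", "j"], 0)
})

test_that("spatial overlap equals a brute-force double loop over burrows", {
  obs <- generate_observations(small_cfg(6))
  males <- filter_isolates(obs)
  s <- build_spatial_overlap(obs, ids = males)
  occ <- obs$occupancy
  time_at <- function(ind, b) sum(occ$duration[occ$individual_id == ind &
                                                 occ$burrow_id == b])
  burrows <- unique(occ$burrow_id)
  for (i in males) for (j in males) {
    if (i == j) next
    wij <- wji <- 0
    for (b in burrows) {
      ti <- time_at(i, b); tj <- time_at(j, b)
      if (ti > 0 && tj > 0) { wij <- wij + ti; wji <- wji + tj }
    }
    expect_equal(unname(s[i, j]), sqrt(wij * wji))
  }
})

test_that("geometric-mean symmetrization matches its worked values", {
  m <- rbind(c(0, 5, 1), c(5, 0, 0), c(9, 0, 0))
  D <- dyad_matrix(m, node_ids = c("a", "b", "c"))
  s <- symmetrize_geometric(D)
  expect_equal(s["a", "b"], 5)   # reciprocal 5 and 5
  expect_equal(s["a", "c"], 3)   # reciprocal 1 and 9
  expect_equal(s["b", "c"], 0)   # a zero annihilates
  expect_true(is_symmetric(s))
})

test_that("geometric mean never exceeds the arithmetic mean (AM-GM)", {
  D <- rand_dir_dm(12, 11)
  s <- symmetrize_geometric(D)
  am <- (unclass(D) + t(unclass(D))) / 2
  expect_true(all(unclass(s) <= am + 1e-12))
  eq <- abs(unclass(s) - am) < 1e-12
  recip_equal <- abs(unclass(D) - t(unclass(D))) < 1e-12
  expect_identical(eq, recip_equal)
})

test_that("standardization centers and scales the unordered dyad set", {
  # balanced 0/2 dyads standardize to -1/+1 under the population-SD
  # (divide-by-n) convention
  D <- rand_sym_dm(4, 1, values = function(k) c(0, 0, 2, 2, 0, 2)[seq_len(k)])
  half_two <- rand_sym_dm(4, 1, values = function(k) c(0, 0, 0, 2, 2, 2))
  z <- standardize_offdiag(half_two)
  expect_setequal(round(dyad_values(z), 12), c(-1, 1))
  vals <- dyad_values(standardize_offdiag(D))
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(vals^2)), 1, tolerance = 1e-12)
  # idempotence up to floating tolerance
  z2 <- standardize_offdiag(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-10)
  # diagonal untouched
  expect_equal(diag(unclass(z)), rep(0, 4), ignore_attr = TRUE)
  # constant off-diagonal -> degenerate error
  Dc <- dyad_matrix(matrix(1, 3, 3), symmetric = TRUE)
  expect_error(standardize_offdiag(Dc), "degenerate")
})

test_that("isolate filtering keeps exactly the burrow-sharing males", {
  obs <- tiny_obs()  # m1, m2 share b1; m3 alone on b3
  expect_identical(filter_isolates(obs), c("m1", "m2"))
  # monotone: adding an occupancy record never removes a male
  obs2 <- observation_set(
    roster = obs$roster,
    occupancy = rbind(obs$occupancy,
                      data.frame(individual_id = "m3", burrow_id = "b1",
                                 duration = 1)),
    fights = obs$fights, matings = obs$matings)
  expect_true(all(filter_isolates(obs) %in% filter_isolates(obs2)))
  expect_identical(filter_isolates(obs2), c("m1", "m2", "m3"))
})

test_that("isolate filtering matches a brute-force scan on synthetic data", {
  obs <- generate_observations(small_cfg(8))
  males <- obs$roster$id[obs$roster$sex == "male"]
  occ <- obs$occupancy[obs$occupancy$duration > 0, ]
  keep <- vapply(males, function(m) {
    mine <- occ$burrow_id[occ$individual_id == m]
    others <- occ$burrow_id[occ$individual_id %in% setdiff(males, m)]
    length(intersect(mine, others)) > 0
  }, logical(1))
  expect_identical(filter_isolates(obs), sort(males[keep]))
})

test_that("elementwise product combines aligned matrices and checks alignment", {
  A <- rand_sym_dm(6, 21)
  B <- rand_sym_dm(6, 22)
  P <- elementwise_product(A, B)
  expect_equal(unclass(P), unclass(A) * unclass(B), ignore_attr = TRUE)
  expect_true(is_symmetric(P))
  B2 <- rand_sym_dm(5, 23)
  expect_error(elementwise_product(A, B2), "node ids")
})
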