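# Small hand-written observation set: 3 males, 2 females, 3 burrows.
tiny_obs <- function() {
  observation_set(
    roster = data.frame(
      id = c("m1", "m2", "m3", "f1", "f2"),
      sex = c("male", "male", "male", "female", "female"),
      emergence_day = c(1L, 2L, 5L, 1L, 3L),
      death_day = c(20L, 15L, 30L, 25L, 10L)
    ),
    occupancy = data.frame(
      individual_id = c("m1", "m1", "m2", "m3", "f1", "f2"),
      burrow_id = c("b1", "b2", "b1", "b3", "b1", "b2"),
      duration = c(4, 2, 9, 5, 3, 1)
    ),
    fights = data.frame(
      day = c(3L, 4L, 6L),
      arriving_male_id = c("m1", "m1", "m2"),
      resident_male_id = c("m2", "m2", "m1"),
      burrow_id = c("b1", "b1", "b1")
    ),
    matings = data.frame(
      day = c(5L, 6L, 7L, 8L),
      male_id = c("m1", "m1", "m2", "m1"),
      female_id = c("f1", "f1", "f1", "f2"),
      spermatophore_transferred = c(TRUE, FALSE, TRUE, TRUE)
    )
  )
}

rand_sym_dm <- function(n, seed, values = function(k) rpois(k, 2)) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values(n * (n - 1) / 2)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dyad_matrix(m, node_ids = paste0("n", seq_len(n)), symmetric = TRUE)
}

rand_dir_dm <- function(n, seed, values = function(k) rpois(k, 2)) {
  set.seed(seed)
  m <- matrix(values(n * n), n, n)
  dyad_matrix(m, node_ids = paste0("n", seq_len(n)))
}

# All permutations of 1:n via Heap's algorithm (independent of the
# package's recursive enumerator).
heap_perms <- function(n) {
  a <- seq_len(n)
  out <- list(a)
  c_counts <- integer(n)
  i <- 1L
  while (i <= n) {
    if (c_counts[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_counts[i] + 1L]; a[c_counts[i] + 1L] <- a[i]; a[i] <- tmp
      }
      out[[length(out) + 1L]] <- a
      c_counts[i] <- c_counts[i] + 1L
      i <- 1L
    } else {
      c_counts[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_males = 20, n_females = 20, n_burrows = 20,
                   burrow_cluster_count = 8, season_length = 60,
                   emergence_spread = 20, seed = seed, ...)
}
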