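# Independent oracles used across the suite. These deliberately use naive,
# loop-based computations so they share no code path with the package.

# Two-pass sample variance / COV, written out longhand.
oracle_var <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / (length(x) - 1)
}
oracle_cov <- function(x) sqrt(oracle_var(x)) / (sum(x) / length(x))

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# siteCOV of one assignment: median COV over traps with >= 2 fish.
oracle_sitecov <- function(lengths_list) {
  covs <- c()
  for (l in lengths_list) if (length(l) >= 2) covs <- c(covs, oracle_cov(l))
  if (!length(covs)) return(NA_real_)
  oracle_median(covs)
}

# Exhaustive enumeration of every distinct assignment of the pooled fish to
# traps with the observed per-trap counts. Each distinct assignment of fish
# *indices* is equally likely under a uniform permutation, so the returned
# vector (one siteCOV per assignment) is the exact null distribution.
enumerate_null_sitecovs <- function(lengths_list) {
  counts <- vapply(lengths_list, length, integer(1))
  counts <- counts[counts > 0]
  pool <- unlist(lengths_list)
  res <- numeric(0)
  recurse <- function(avail, remaining_counts, groups) {
    if (!length(remaining_counts)) {
      res[length(res) + 1L] <<- oracle_sitecov(groups)
      return(invisible())
    }
    k <- remaining_counts[1]
    # combn(x, m) misreads a length-1 numeric x as seq_len(x)
    picks <- if (length(avail) == 1L) list(avail)
    else utils::combn(avail, k, simplify = FALSE)
    for (p in picks)
      recurse(setdiff(avail, p), remaining_counts[-1],
              c(groups, list(pool[p])))
  }
  recurse(seq_along(pool), counts, list())
  res
}

# Friedman statistic from the textbook rank-sum formula (no tie handling;
# only used on tie-free inputs).
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  12 / (n * k * (k + 1)) * sum((rj - n * (k + 1) / 2)^2)
}

# Exhaustive search over every cut of the sorted values, recomputing the
# within-group sums of squares from scratch for each cut.
oracle_best_split <- function(x) {
  xs <- sort(x)
  best_ss <- Inf; best_cut <- NA_real_
  for (j in 1:(length(xs) - 1)) {
    lo <- xs[1:j]; hi <- xs[(j + 1):length(xs)]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_cut <- (xs[j] + xs[j + 1]) / 2
    }
  }
  best_cut
}

# Tiny hand-built catch/length tables for io tests.
toy_catch_df <- function() {
  data.frame(site_id = "Brandon", week = 3L, time_of_day = "am",
             trap_location = 1:5, n_total = c(3L, 2L, 0L, 5L, 1L),
             n_red_males = c(1L, 0L, 0L, 2L, 0L))
}
toy_length_df <- function() {
  data.frame(site_id = "Brandon", week = 3L,
             trap_location = c(1, 1, 1, 2, 2, 4, 4, 4, 4, 4, 5),
             fish_index = c(1:3, 1:2, 1:5, 1),
             body_length_mm = c(41.5, 44.0, 39.5, 21.0, 23.5,
                                50.0, 48.5, 52.0, 47.0, 51.5, 45.0))
}
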