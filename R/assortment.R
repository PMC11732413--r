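# Body-size assortment: per-trap coefficient of variation, observed siteCOV,
# and a constrained-randomization null that shuffles individuals across traps
# while preserving the number caught per trap.

#' Coefficient of variation of body lengths in one trap
#'
#' Sample standard deviation divided by the mean. Zero means all individuals
#' in the trap are the same size; larger values mean more size heterogeneity
#' relative to the mean. Traps with fewer than two measured individuals carry
#' no information about within-trap variation and return `NA`.
#'
#' @param lengths Numeric vector of body lengths (mm).
#' @return `sd(lengths)/mean(lengths)`, or `NA_real_` if fewer than two
#'   lengths are supplied.
#' @examples
#' trap_cov(c(40, 50, 60))  # 0.2
#' @export
trap_cov <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) return(NA_real_)
  if (any(!is.finite(lengths) | lengths <= 0))
    stop("body lengths must be positive and finite")
  stats::sd(lengths) / mean(lengths)
}

# Per-trap measured counts, pooled lengths and eligibility for a session given
# either a session_catch object or a bare list of length vectors.
session_length_list <- function(session) {
  if (inherits(session, "session_catch")) session$lengths
  else if (is.list(session)) lapply(session, as.numeric)
  else stop("session must be a session_catch or a list of length vectors")
}

#' Observed siteCOV of a sampling session
#'
#' The session-level assortment statistic: the median of the per-trap
#' coefficients of variation over eligible traps (those holding at least two
#' measured individuals). With an even number of eligible traps the median is
#' the midpoint of the two central values.
#'
#' @param session A `session_catch` or a list of per-trap length vectors.
#' @return The observed siteCOV, or `NA_real_` with attribute
#'   `reason = "no_eligible_trap"` when no trap has two measured fish.
#' @export
observed_sitecov <- function(session) {
  lens <- session_length_list(session)
  covs <- vapply(lens, trap_cov, numeric(1))
  covs <- covs[!is.na(covs)]
  if (!length(covs))
    return(structure(NA_real_, reason = "no_eligible_trap"))
  stats::median(covs)
}

#' Is a session suitable for the assortment randomization test?
#'
#' A session is unsuitable when fewer than two traps hold at least two
#' measured individuals — including the case where every fish fell in a single
#' trap — because the randomization null is then degenerate or the median
#' statistic rests on a single trap.
#'
#' @param session A `session_catch` or a list of per-trap length vectors.
#' @return `TRUE`/`FALSE`.
#' @export
assortment_suitable <- function(session) {
  n <- vapply(session_length_list(session), length, integer(1))
  sum(n >= 2L) >= 2L
}

# Vectorised null engine. Permutes the pooled length vector and re-splits by
# the observed per-trap measured counts; traps with < 2 measured fish never
# contribute a COV (their counts are preserved, so eligibility is fixed).
# Grouped sums via rowsum() over chunks of iterations keep this O(n_iter * n)
# with small constants.
null_sitecovs_engine <- function(lengths_list, n_iter, chunk = 500L) {
  counts <- vapply(lengths_list, length, integer(1))
  keep <- counts > 0L
  counts <- counts[keep]
  pool <- unlist(lengths_list[keep], use.names = FALSE)
  n <- length(pool)
  grp <- rep(seq_along(counts), counts)
  eligible <- counts >= 2L
  cnt_e <- counts[eligible]
  out <- numeric(n_iter)
  done <- 0L
  while (done < n_iter) {
    b <- min(chunk, n_iter - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    X <- matrix(pool[idx], nrow = n, ncol = b)
    S <- rowsum(X, grp, reorder = TRUE)
    S2 <- rowsum(X * X, grp, reorder = TRUE)
    S <- S[eligible, , drop = FALSE]
    S2 <- S2[eligible, , drop = FALSE]
    mu <- S / cnt_e
    va <- (S2 - S * mu) / (cnt_e - 1)
    covs <- sqrt(pmax(va, 0)) / mu
    out[done + seq_len(b)] <- apply(covs, 2L, stats::median)
    done <- done + b
  }
  out
}

#' Constrained-randomization null distribution of siteCOV
#'
#' Generates the expected distribution of the siteCOV under random assortment:
#' in each iteration the pooled measured individuals of the session are
#' redistributed uniformly at random across the traps while keeping the
#' observed number of measured individuals in each trap, and the median
#' per-trap coefficient of variation is recorded.
#'
#' @param session A `session_catch` or a list of per-trap length vectors.
#' @param n_iter Number of randomization iterations (default 10000).
#' @param seed Optional integer seed; when given, results are reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of `n_iter` expected siteCOV values.
#' @export
randomize_session <- function(session, n_iter = 10000L, seed = NULL) {
  stopifnot(n_iter >= 1L)
  lens <- session_length_list(session)
  if (!assortment_suitable(lens))
    stop_validation("session unsuitable for randomization: fewer than two ",
                    "traps with two or more measured fish")
  if (is.null(seed)) null_sitecovs_engine(lens, as.integer(n_iter))
  else with_seed(seed, null_sitecovs_engine(lens, as.integer(n_iter)))
}

#' Quantile of the observed siteCOV in its null distribution
#'
#' The proportion of null (expected) siteCOV values less than or equal to the
#' observed value; ties count as "less than or equal".
#'
#' @param observed Observed siteCOV.
#' @param nulls Numeric vector of null siteCOVs.
#' @return A proportion in `[0, 1]`.
#' @export
assortment_quantile <- function(observed, nulls) {
  stopifnot(length(nulls) >= 1L, is.finite(observed))
  # the null is discrete (finitely many redistributions), so exact ties with
  # the observed value are real support points; a relative tolerance keeps
  # the tie comparison stable across arithmetically different COV evaluations
  tol <- 1e-9 * max(1, abs(observed))
  mean(nulls <= observed + tol)
}

#' Classify an assortment quantile
#'
#' Two-tailed test: quantiles below `lower_alpha` indicate positive assortment
#' (individuals group with similar sizes — less within-trap variation than
#' chance), quantiles above `upper_alpha` indicate negative assortment.
#'
#' @param quantile Quantile from [assortment_quantile()].
#' @param lower_alpha,upper_alpha Significance cutoffs (defaults 0.025 and
#'   0.975).
#' @return `"positive"`, `"negative"` or `"none"`.
#' @examples
#' classify_assortment(0.004)  # positive
#' classify_assortment(0.68)   # none
#' @export
classify_assortment <- function(quantile, lower_alpha = 0.025,
                                upper_alpha = 0.975) {
  stopifnot(lower_alpha >= 0, upper_alpha <= 1, lower_alpha < upper_alpha,
            quantile >= 0, quantile <= 1)
  if (quantile < lower_alpha) "positive"
  else if (quantile > upper_alpha) "negative"
  else "none"
}

#' Assortment test for one sampling session
#'
#' Runs the full per-session procedure: observed siteCOV, constrained
#' randomization null, quantile and two-tailed classification.
#'
#' @inheritParams randomize_session
#' @inheritParams classify_assortment
#' @return An object of class `assortment_test` with elements
#'   `observed_sitecov`, `null_sitecovs`, `quantile`, `classification`,
#'   `n_iter`, `seed`, `site_id`, `week`.
#' @examples
#' dat <- generate_dataset(paper_scale_preset(seed = 1))
#' s <- read_catch_table(dat$catches, dat$lengths)[[1]]
#' test_assortment(s, n_iter = 200, seed = 42)
#' @export
test_assortment <- function(session, n_iter = 10000L, seed = NULL,
                            lower_alpha = 0.025, upper_alpha = 0.975) {
  site_id <- if (inherits(session, "session_catch")) session$site_id else NA
  week <- if (inherits(session, "session_catch")) session$week else NA
  if (!assortment_suitable(session)) {
    res <- list(site_id = site_id, week = week,
                observed_sitecov = NA_real_, null_sitecovs = numeric(0),
                quantile = NA_real_, classification = "unsuitable",
                n_iter = as.integer(n_iter), seed = seed)
    return(structure(res, class = "assortment_test"))
  }
  obs <- observed_sitecov(session)
  nulls <- randomize_session(session, n_iter = n_iter, seed = seed)
  q <- assortment_quantile(obs, nulls)
  structure(list(site_id = site_id, week = week, observed_sitecov = obs,
                 null_sitecovs = nulls, quantile = q,
                 classification = classify_assortment(q, lower_alpha,
                                                      upper_alpha),
                 n_iter = as.integer(n_iter), seed = seed),
            class = "assortment_test")
}

#' @export
print.assortment_test <- function(x, ...) {
  cat("Constrained-randomization test for body-size assortment\n")
  if (!is.na(x$site_id))
    cat(sprintf("  session: site %s, week %s\n", x$site_id, x$week))
  if (x$classification == "unsuitable") {
    cat("  unsuitable: fewer than two traps with >= 2 measured fish\n")
    return(invisible(x))
  }
  cat(sprintf("  observed siteCOV = %.4f, null median = %.4f (%d iterations)\n",
              x$observed_sitecov, stats::median(x$null_sitecovs), x$n_iter))
  cat(sprintf("  quantile = %.4f -> %s assortment\n", x$quantile,
              if (x$classification == "none") "no evidence of"
              else x$classification))
  invisible(x)
}

#' Plot the null siteCOV distribution of an assortment test
#'
#' Histogram of the expected siteCOV values with the observed siteCOV as a
#' vertical red line.
#'
#' @param x An `assortment_test`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.assortment_test <- function(x, ...) {
  if (x$classification == "unsuitable") stop("session was unsuitable")
  graphics::hist(x$null_sitecovs, xlab = "expected siteCOV",
                 main = sprintf("quantile = %.3f", x$quantile), ...)
  graphics::abline(v = x$observed_sitecov, col = "red", lwd = 2)
  invisible(x)
}

#' Assortment tests for all sessions
#'
#' Applies [test_assortment()] to every session, deriving one independent RNG
#' stream per session from the master seed so any session can be reproduced in
#' isolation. Suitability is judged from the measured-fish distribution across
#' traps; optionally sessions failing the aggregation minimum-catch rule can
#' also be excluded.
#'
#' @param sessions A `trap_sessions` object.
#' @param n_iter Randomization iterations per session (default 10000).
#' @param seed Master seed (integer).
#' @param lower_alpha,upper_alpha Two-tailed cutoffs.
#' @param min_catch Optional: also mark sessions with `session_total <
#'   min_catch` unsuitable. `NULL` (default) keeps assortment suitability
#'   independent of the aggregation threshold.
#' @param keep_nulls Keep each session's null distribution (as attribute
#'   `nulls`, a named list)? Default `FALSE`.
#' @return A data.frame of class `assortment_results` with one row per
#'   session: `site_id`, `week`, `n_measured`, `observed_sitecov`, `quantile`,
#'   `classification`, `n_iter`, `seed`.
#' @export
assort_sessions <- function(sessions, n_iter = 10000L, seed = 1L,
                            lower_alpha = 0.025, upper_alpha = 0.975,
                            min_catch = NULL, keep_nulls = FALSE) {
  tests <- lapply(unclass(sessions), function(s) {
    unsuitable_by_catch <- !is.null(min_catch) && s$session_total < min_catch
    if (unsuitable_by_catch || !assortment_suitable(s)) {
      t <- test_assortment(list(numeric(0)), n_iter = n_iter)
      t$site_id <- s$site_id; t$week <- s$week
      t$n_measured <- sum(s$traps$n_measured)
      return(t)
    }
    t <- test_assortment(s, n_iter = n_iter,
                         seed = derive_session_seed(seed, s$site_id, s$week),
                         lower_alpha = lower_alpha,
                         upper_alpha = upper_alpha)
    t$n_measured <- sum(s$traps$n_measured)
    t
  })
  out <- do.call(rbind, lapply(tests, function(t)
    data.frame(site_id = t$site_id, week = t$week,
               n_measured = t$n_measured,
               observed_sitecov = t$observed_sitecov, quantile = t$quantile,
               classification = t$classification,
               n_iter = t$n_iter, seed = t$seed %||% NA_integer_)))
  rownames(out) <- NULL
  if (keep_nulls)
    attr(out, "nulls") <- stats::setNames(
      lapply(tests, `[[`, "null_sitecovs"),
      paste(out$site_id, out$week, sep = "_"))
  class(out) <- c("assortment_results", "data.frame")
  out
}

#' @export
print.assortment_results <- function(x, ...) {
  tab <- table(factor(x$classification,
                      c("positive", "negative", "none", "unsuitable")))
  cat(sprintf("Assortment tests for %d sessions (%d iterations each):\n",
              nrow(x), x$n_iter[1]))
  cat(sprintf("  positive %d, negative %d, none %d, unsuitable %d\n",
              tab["positive"], tab["negative"], tab["none"],
              tab["unsuitable"]))
  print.data.frame(x, ...)
  invisible(x)
}
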