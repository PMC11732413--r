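# Environmental summaries and screens: two-step trap/session averaging,
# Spearman correlations among covariates, and per-site Friedman tests for
# trap-location preference.

#' Summarize environmental series per trap and per session
#'
#' Trap level: the mean of the one-minute temperature and light readings over
#' the session window, and the mean of the start/end spot measurements for
#' turbidity and dissolved oxygen (one available phase is used alone, with a
#' flag). Session level: the mean of the trap-level means — deliberately the
#' two-step average, not the pooled-series mean, so each trap contributes
#' equally.
#'
#' @param env An `env_series` object from [read_env_tables()].
#' @param level `"both"` (default), `"trap"` or `"session"`.
#' @return A data.frame of class `env_summary` with columns `site_id`, `week`,
#'   `trap_location` (`NA` for session-level rows), `temperature_c`,
#'   `light_lumft2`, `turbidity_ntu`, `do_mgl`, `flags`.
#' @export
summarize_env <- function(env, level = c("both", "trap", "session")) {
  level <- match.arg(level)
  stopifnot(inherits(env, "env_series"))
  if (!length(env)) stop("no environment records to summarize")
  trap <- do.call(rbind, lapply(unclass(env), function(e) {
    data.frame(site_id = e$site_id, week = e$week,
               trap_location = e$trap_location,
               temperature_c = mean(e$series$temperature_c),
               light_lumft2 = mean(e$series$light_lumft2),
               turbidity_ntu = mean(e$turbidity, na.rm = TRUE),
               do_mgl = mean(e$do, na.rm = TRUE),
               flags = paste(e$flags, collapse = ";"))
  }))
  trap$turbidity_ntu[is.nan(trap$turbidity_ntu)] <- NA_real_
  trap$do_mgl[is.nan(trap$do_mgl)] <- NA_real_
  rownames(trap) <- NULL
  if (level == "trap") {
    class(trap) <- c("env_summary", "data.frame")
    return(trap)
  }
  vars <- c("temperature_c", "light_lumft2", "turbidity_ntu", "do_mgl")
  key <- unique(trap[, c("site_id", "week")])
  sess <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    rows <- trap[trap$site_id == key$site_id[i] & trap$week == key$week[i], ]
    out <- data.frame(site_id = key$site_id[i], week = key$week[i],
                      trap_location = NA_integer_)
    for (v in vars) out[[v]] <- mean(rows[[v]], na.rm = TRUE)
    out$flags <- paste(unique(rows$flags[nzchar(rows$flags)]), collapse = ";")
    out
  }))
  rownames(sess) <- NULL
  out <- switch(level, session = sess, both = rbind(trap, sess))
  class(out) <- c("env_summary", "data.frame")
  out
}

#' Spearman correlation screen among continuous explanatory variables
#'
#' Pairwise Spearman rank correlations among the trap-level covariates
#' (temperature, light intensity, dissolved oxygen, turbidity) and the week of
#' data collection, used to judge collinearity before single-covariate
#' modelling. Two-sided p-values use the asymptotic t approximation. No
#' multiple-testing correction is applied.
#'
#' @param summaries An `env_summary` data.frame (trap-level rows are used).
#' @param vars Variables to correlate; defaults to the four covariates plus
#'   `week`.
#' @return A data.frame with one row per pair: `var1`, `var2`, `rho`, `p`,
#'   `n`. Pairs with a constant member get `NA` rho.
#' @export
covariate_correlations <- function(summaries,
                                   vars = c("temperature_c", "light_lumft2",
                                            "do_mgl", "turbidity_ntu",
                                            "week")) {
  df <- if ("trap_location" %in% names(summaries))
    summaries[!is.na(summaries$trap_location), , drop = FALSE]
  else summaries
  missing <- setdiff(vars, names(df))
  if (length(missing)) stop("variables not present: ",
                            paste(missing, collapse = ", "))
  pairs <- utils::combn(vars, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- df[[pairs[1, j]]]; v2 <- df[[pairs[2, j]]]
    ok <- is.finite(v1) & is.finite(v2)
    n <- sum(ok)
    if (n < 3L || length(unique(v1[ok])) < 2L || length(unique(v2[ok])) < 2L)
      return(data.frame(var1 = pairs[1, j], var2 = pairs[2, j],
                        rho = NA_real_, p = NA_real_, n = n))
    ct <- suppressWarnings(stats::cor.test(v1[ok], v2[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(var1 = pairs[1, j], var2 = pairs[2, j],
               rho = unname(ct$estimate), p = ct$p.value, n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Per-site Friedman test for trap-location preference
#'
#' Tests, separately for each site, whether the number of individuals caught
#' differs consistently across trap locations over the repeated weekly
#' sessions (weeks are the blocks, trap locations the treatments). A small
#' p-value indicates a preference for particular trap locations. Mid-ranks and
#' the standard tie correction are used.
#'
#' @param sessions A `trap_sessions` object.
#' @return A data.frame with one row per testable site: `site_id`,
#'   `statistic` (Friedman chi-squared), `df`, `p`, `n_blocks`. Sites with
#'   fewer than two complete sessions are skipped with a warning. The
#'   underlying `htest` objects are attached as attribute `tests`.
#' @export
trap_preference_test <- function(sessions) {
  sites <- unique(vapply(unclass(sessions), `[[`, "", "site_id"))
  rows <- list(); tests <- list(); skipped <- character(0)
  for (site in sites) {
    ss <- Filter(function(s) s$site_id == site, unclass(sessions))
    k <- max(vapply(ss, function(s) nrow(s$traps), integer(1)))
    complete <- Filter(function(s) nrow(s$traps) == k, ss)
    if (length(complete) < 2L) {
      skipped <- c(skipped, site)
      next
    }
    m <- t(vapply(complete, function(s)
      s$traps$n_total[order(s$traps$trap_location)], numeric(k)))
    ht <- stats::friedman.test(m)
    if (!is.finite(ht$statistic)) {
      # every block fully tied: the tie-corrected statistic is 0/0; there is
      # no rank variation at all, hence no evidence of preference
      ht$statistic[] <- 0
      ht$p.value <- 1
    }
    tests[[site]] <- ht
    rows[[site]] <- data.frame(site_id = site,
                               statistic = unname(ht$statistic),
                               df = unname(ht$parameter),
                               p = ht$p.value, n_blocks = nrow(m))
  }
  if (length(skipped))
    warning("site(s) with fewer than two complete sessions skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(0), statistic = numeric(0),
                      df = numeric(0), p = numeric(0), n_blocks = integer(0))
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}
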