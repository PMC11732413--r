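# Aggregation scoring: the index of dispersion of simultaneous trap counts.

#' Index of dispersion (variance-to-mean ratio) of trap counts
#'
#' The aggregation score for one sampling session: the variance of the counts
#' of individuals caught in each simultaneously deployed trap divided by their
#' mean. A score of 0 means individuals were spread perfectly evenly across
#' traps (avoidance), values near 1 are consistent with random (Poisson-like)
#' scatter, and values above 1 indicate aggregation.
#'
#' @param counts Integer vector of per-trap counts (length >= 2).
#' @param denominator `"sample"` (n-1, the ecology convention and the
#'   default) or `"population"` (n) variance.
#' @return The index of dispersion, a non-negative number; 0 exactly when all
#'   counts are equal.
#' @examples
#' index_of_dispersion(c(10, 10, 10, 10, 10))  # perfectly even -> 0
#' index_of_dispersion(c(25, 0, 0, 0, 0))      # all in one trap -> 25
#' @export
index_of_dispersion <- function(counts, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need counts from at least two traps")
  if (any(!is.finite(counts) | counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0))
    stop_validation("degenerate session: all trap counts are zero, ",
                    "index of dispersion is undefined")
  m <- mean(counts)
  v <- stats::var(counts)
  if (denominator == "population") v <- v * (length(counts) - 1) / length(counts)
  v / m
}

#' Score sampling sessions for aggregation
#'
#' Computes the index of dispersion for every session and applies the
#' minimum-catch inclusion rule: with few individuals the score is
#' mechanically constrained to low values, so sessions whose total catch is
#' below `min_catch` are flagged `included = FALSE` (they are retained for the
#' score-vs-catch diagnostic). Sessions where no individual was caught in any
#' trap cannot be scored and get `NA` with a warning.
#'
#' @param sessions A `trap_sessions` object (see [read_catch_table()]).
#' @param min_catch Minimum session total for inclusion (default 26).
#' @param denominator Passed to [index_of_dispersion()].
#' @return A data.frame of class `aggregation_scores` with columns `site_id`,
#'   `week`, `time_of_day`, `session_total`, `score`, `included`,
#'   `threshold_used`.
#' @examples
#' dat <- generate_dataset(paper_scale_preset(seed = 1))
#' sessions <- read_catch_table(dat$catches)
#' agg <- score_sessions(sessions, min_catch = 26)
#' head(agg)
#' @export
score_sessions <- function(sessions, min_catch = 26L,
                           denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  stopifnot(min_catch >= 1)
  if (!length(sessions)) {
    out <- data.frame(site_id = character(0), week = integer(0),
                      time_of_day = character(0), session_total = integer(0),
                      score = numeric(0), included = logical(0),
                      threshold_used = integer(0))
    class(out) <- c("aggregation_scores", "data.frame")
    return(out)
  }
  rows <- lapply(unclass(sessions), function(s) {
    score <- if (s$session_total == 0) NA_real_ else
      index_of_dispersion(s$traps$n_total, denominator)
    data.frame(site_id = s$site_id, week = s$week,
               time_of_day = s$time_of_day, session_total = s$session_total,
               score = score,
               included = !is.na(score) && s$session_total >= min_catch,
               threshold_used = as.integer(min_catch))
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$score)) {
    bad <- out[is.na(out$score), ]
    warning("all-zero session(s) excluded (score undefined): ",
            paste(sprintf("(%s, week %d)", bad$site_id, bad$week),
                  collapse = "; "), call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("aggregation_scores", "data.frame")
  out
}

#' Score-vs-catch diagnostic table
#'
#' Supports the visual choice of the minimum-catch threshold: sessions sorted
#' by total catch together with the running maximum of the aggregation score
#' over all sessions with totals at or below each catch size. The threshold is
#' the smallest catch size at which large scores start to appear.
#'
#' @param results An `aggregation_scores` data.frame from [score_sessions()].
#' @return A data.frame sorted by `session_total` with an added
#'   `running_max_score` column (all-zero sessions are dropped).
#' @export
score_vs_catch_diagnostic <- function(results) {
  stopifnot(nrow(results) >= 1L)
  res <- results[!is.na(results$score), , drop = FALSE]
  res <- res[order(res$session_total), , drop = FALSE]
  res$running_max_score <- cummax(res$score)
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}

#' @export
print.aggregation_scores <- function(x, ...) {
  cat(sprintf(
    "Aggregation scores for %d sessions (min catch %s): %d included, %d excluded\n",
    nrow(x), x$threshold_used[1] %||% NA, sum(x$included),
    sum(!x$included)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot aggregation score against session total catch
#'
#' The threshold diagnostic: one point per sampling session, excluded sessions
#' (total catch below the threshold) in red, the inclusion threshold as a
#' dashed vertical line and the random-distribution reference score of 1 as a
#' dotted horizontal line.
#'
#' @param x An `aggregation_scores` data.frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aggregation_scores <- function(x, ...) {
  ok <- !is.na(x$score)
  graphics::plot(x$session_total[ok], x$score[ok],
                 col = ifelse(x$included[ok], "black", "red"), pch = 16,
                 xlab = "total fish caught in session",
                 ylab = "aggregation score (variance/mean)", ...)
  graphics::abline(v = x$threshold_used[1] - 0.5, lty = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
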