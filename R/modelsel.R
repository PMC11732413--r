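# Single-covariate mixed-model comparison: AICc ranking against a null model,
# with slope, standard error and incidence rate ratio per candidate.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`. `k` counts every estimated
#' parameter: fixed effects including the intercept, the dispersion parameter
#' of a negative-binomial family, and each random-effect variance component.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value; `NA` with a warning when `n <= k + 1` (the
#'   correction is undefined).
#' @examples
#' aicc(-100, k = 4, n = 50)  # 208 + 40/45
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1", call. = FALSE)
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Incidence rate ratio from a log-link slope
#'
#' `exp(slope)`: the multiplicative change in the expected response per unit
#' increase of the covariate under a log link.
#'
#' @param slope Regression coefficient on the log scale.
#' @return `exp(slope)`.
#' @examples
#' irr(0.201)   # 1.223
#' irr(-0.247)  # 0.781
#' @export
irr <- function(slope) {
  stopifnot(is.finite(slope))
  exp(slope)
}

#' Percent change in the response implied by a log-link slope
#'
#' Restates a slope as the percentage change per unit covariate:
#' `100 * (1 - exp(slope))` for a decrease (negative slope) and
#' `100 * (exp(slope) - 1)` for an increase.
#'
#' @param slope Regression coefficient on the log scale.
#' @return The magnitude of the percent change, with attribute `direction`
#'   (`"decrease"` or `"increase"`).
#' @examples
#' percent_change(-3.423)  # ~97, decrease
#' percent_change(log(2))  # 100, increase
#' @export
percent_change <- function(slope) {
  stopifnot(is.finite(slope))
  if (slope < 0)
    structure(100 * (1 - exp(slope)), direction = "decrease")
  else
    structure(100 * (exp(slope) - 1), direction = "increase")
}

# Exact 1-D 2-means: over the sorted values, every cut is scanned and the one
# minimizing total within-cluster sum of squares is returned.
one_d_two_means <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  j <- seq_len(n - 1L)
  ss_lo <- cs2[j] - cs[j]^2 / j
  ss_hi <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / (n - j)
  best <- which.min(ss_lo + ss_hi)
  list(cutoff = (xs[best] + xs[best + 1L]) / 2,
       gap = xs[best + 1L] - xs[best],
       within_ss = ss_lo[best] + ss_hi[best],
       n_lo = best, n_hi = n - best)
}

#' Split fish into adults and juveniles by body length, per week
#'
#' Recruitment during the season makes the length distribution bimodal within
#' a week, with the juvenile mode growing over time; a single global cutoff is
#' therefore inappropriate. `two_means` finds, per week, the exact optimal
#' one-dimensional 2-cluster split (exhaustive scan over sorted lengths);
#' `fixed_cutoff` applies a user cutoff to every week. Weeks where the
#' between-cluster gap does not exceed the pooled within-cluster standard
#' deviation (no clear divide, e.g. a unimodal week) are flagged and all fish
#' are assigned to the cluster whose global mean is nearer.
#'
#' @param lengths Either a numeric vector of body lengths (mm) with `weeks`
#'   giving the week of each fish, or a data.frame containing
#'   `body_length_mm` and `week` columns (other columns are carried through).
#' @param weeks Week per fish when `lengths` is a vector.
#' @param method `"two_means"` (default) or `"fixed_cutoff"`.
#' @param cutoff Length cutoff in mm for `fixed_cutoff`.
#' @return An object of class `adult_split`: list with `fish` (input rows
#'   plus an `age_class` column of `"adult"`/`"juvenile"`), `cutoffs` (per
#'   week: `cutoff`, `flagged`) and `method`.
#' @examples
#' sp <- split_adults_juveniles(c(20, 21, 22, 48, 50, 52), rep(1, 6))
#' sp$fish$age_class
#' @export
split_adults_juveniles <- function(lengths, weeks = NULL,
                                   method = c("two_means", "fixed_cutoff"),
                                   cutoff = NULL) {
  method <- match.arg(method)
  if (is.data.frame(lengths)) {
    fish <- lengths
    stopifnot(all(c("body_length_mm", "week") %in% names(fish)))
  } else {
    stopifnot(length(lengths) == length(weeks))
    fish <- data.frame(week = weeks, body_length_mm = as.numeric(lengths))
  }
  if (method == "fixed_cutoff") {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
    fish$age_class <- ifelse(fish$body_length_mm > cutoff, "adult",
                             "juvenile")
    cuts <- data.frame(week = sort(unique(fish$week)), cutoff = cutoff,
                       flagged = FALSE)
    return(structure(list(fish = fish, cutoffs = cuts, method = method),
                     class = "adult_split"))
  }
  wk <- sort(unique(fish$week))
  fish$age_class <- NA_character_
  cuts <- data.frame(week = wk, cutoff = NA_real_, flagged = FALSE)
  # global split used as fallback for degenerate weeks
  gsp <- if (length(unique(fish$body_length_mm)) >= 2L)
    one_d_two_means(fish$body_length_mm) else NULL
  for (i in seq_along(wk)) {
    idx <- fish$week == wk[i]
    x <- fish$body_length_mm[idx]
    if (length(x) < 2L || length(unique(x)) < 2L) {
      cuts$flagged[i] <- TRUE
      fallback <- if (!is.null(gsp)) gsp$cutoff else mean(x)
      fish$age_class[idx] <- ifelse(x > fallback, "adult", "juvenile")
      next
    }
    sp <- one_d_two_means(x)
    within_sd <- sqrt(sp$within_ss / max(length(x) - 2L, 1L))
    if (sp$gap <= within_sd) {
      # no clear divide: unimodal week
      cuts$flagged[i] <- TRUE
      fallback <- if (!is.null(gsp)) gsp$cutoff else sp$cutoff
      fish$age_class[idx] <- ifelse(x > fallback, "adult", "juvenile")
      cuts$cutoff[i] <- fallback
    } else {
      cuts$cutoff[i] <- sp$cutoff
      fish$age_class[idx] <- ifelse(x > sp$cutoff, "adult", "juvenile")
    }
  }
  structure(list(fish = fish, cutoffs = cuts, method = method),
            class = "adult_split")
}

#' @export
print.adult_split <- function(x, ...) {
  cat(sprintf("Adult/juvenile split (%s): %d fish, %d weeks, %d flagged\n",
              x$method, nrow(x$fish), nrow(x$cutoffs), sum(x$cutoffs$flagged)))
  print(x$cutoffs, row.names = FALSE)
  invisible(x)
}

default_covariate_sets <- function(response) {
  env <- c("temperature_c", "light_lumft2", "do_mgl", "turbidity_ntu")
  switch(response,
         catch_per_trap = c(env, "week", "time_of_day"),
         prop_adult = c(env, "time_of_day"),
         aggregation_score = c(env, "week", "time_of_day",
                               "prop_red_males"))
}

fixef_slope <- function(fit, covariate, data) {
  co <- summary(fit)$coefficients$cond
  term <- if (is.character(data[[covariate]]) || is.factor(data[[covariate]]))
    grep(paste0("^", covariate), rownames(co), value = TRUE)[1]
  else covariate
  if (is.na(term) || !term %in% rownames(co))
    return(c(slope = NA_real_, se = NA_real_))
  c(slope = co[term, "Estimate"], se = co[term, "Std. Error"])
}

#' Fit and rank a single-covariate mixed-model set
#'
#' Implements the model-comparison design: for one response variable, a set
#' of generalized linear mixed models each containing a single fixed effect
#' (plus a null model), all sharing the same random-intercept structure, is
#' fitted by maximum likelihood and ranked by AICc. Responses and their
#' defaults:
#'
#' * `catch_per_trap` — fish per trap per session; negative binomial with log
#'   link; random intercept for trap location nested in site.
#' * `prop_adult` — adults vs juveniles per trap as a two-column
#'   successes/failures response; binomial; week is additionally included in
#'   every candidate (it defines the age classes), and the comparison set
#'   contains a week-only model and an intercept-only null; nested random
#'   intercepts as above.
#' * `aggregation_score` — session-level index of dispersion, rounded to the
#'   nearest integer and fitted as negative binomial with log link (a
#'   gamma-log alternative is available via `family`); random intercept for
#'   site only.
#'
#' A model whose AICc is more than two units below the null's is flagged as
#' strongly supported. Models that fail to converge are retained in the output
#' with `converged = FALSE` but excluded from the ranking.
#'
#' @param data A data.frame holding the response and covariates: trap-level
#'   rows (`n_total` or `n_adult`/`n_juvenile`, `site_id`, `trap_location`,
#'   covariates) or session-level rows (`score`, `site_id`, covariates). See
#'   [model_frames()] for assembling it from pipeline objects.
#' @param response `"catch_per_trap"`, `"prop_adult"` or
#'   `"aggregation_score"`.
#' @param covariates Candidate fixed effects; defaults per response as above.
#' @param family Optional glmmTMB family object overriding the default.
#' @param standardize Z-standardize numeric covariates before fitting
#'   (default `FALSE`: slopes are reported per raw unit).
#' @return An object of class `model_set`: a data.frame with one row per
#'   model (`fixed_effect`, `slope`, `se`, `irr`, `loglik`, `k`, `n`, `aicc`,
#'   `delta_aicc`, `strong_support`, `converged`), sorted by AICc, with the
#'   fitted models in attribute `fits` and the response in attribute
#'   `response`.
#' @export
fit_model_set <- function(data, response = c("catch_per_trap", "prop_adult",
                                             "aggregation_score"),
                          covariates = NULL, family = NULL,
                          standardize = FALSE) {
  response <- match.arg(response)
  covariates <- covariates %||% default_covariate_sets(response)
  data <- as.data.frame(data)
  data$site_id <- factor(data$site_id)
  if ("trap_location" %in% names(data))
    data$trap_location <- factor(data$trap_location)
  if ("time_of_day" %in% names(data))
    data$time_of_day <- factor(data$time_of_day, levels = c("am", "pm"))

  if (response == "catch_per_trap") {
    lhs <- "n_total"
    random <- "(1 | site_id/trap_location)"
    fam <- family %||% glmmTMB::nbinom2()
    base_terms <- character(0)
    needed <- "n_total"
  } else if (response == "prop_adult") {
    lhs <- "cbind(n_adult, n_juvenile)"
    random <- "(1 | site_id/trap_location)"
    fam <- family %||% stats::binomial()
    base_terms <- "week"
    needed <- c("n_adult", "n_juvenile", "week")
  } else {
    lhs <- "score_int"
    data$score_int <- as.integer(round(data$score))
    random <- "(1 | site_id)"
    fam <- family %||% glmmTMB::nbinom2()
    base_terms <- character(0)
    needed <- "score"
    if (identical(fam$family, "Gamma")) {
      lhs <- "score"
      if (any(data$score <= 0, na.rm = TRUE))
        stop("gamma family requires strictly positive aggregation scores")
    }
  }
  missing <- setdiff(c(needed, covariates), names(data))
  if (length(missing)) stop("data is missing column(s): ",
                            paste(missing, collapse = ", "))
  keep <- stats::complete.cases(data[, unique(c(needed, covariates)),
                                     drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (standardize)
    for (v in covariates)
      if (is.numeric(data[[v]])) data[[v]] <- as.numeric(scale(data[[v]]))

  model_terms <- stats::setNames(as.list(covariates), covariates)
  if (response == "prop_adult")
    model_terms <- c(model_terms, list(week = "week"))
  model_terms <- c(model_terms, list(none = character(0)))

  rows <- list(); fits <- list()
  for (nm in names(model_terms)) {
    rhs_fixed <- unique(c(model_terms[[nm]], base_terms))
    # the intercept-only null drops even the always-included week term
    if (nm == "none") rhs_fixed <- character(0)
    rhs <- paste(c(if (length(rhs_fixed)) rhs_fixed else "1", random),
                 collapse = " + ")
    label <- nm
    f <- stats::as.formula(paste(lhs, "~", rhs))
    fit <- try(suppressWarnings(glmmTMB::glmmTMB(f, data = data,
                                                 family = fam)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[nm]] <- data.frame(fixed_effect = label, slope = NA_real_,
                               se = NA_real_, irr = NA_real_,
                               loglik = NA_real_, k = NA_integer_,
                               n = NA_integer_, aicc = NA_real_,
                               converged = FALSE)
      next
    }
    fits[[nm]] <- fit
    # a model leaves the ranking only on genuine optimizer failure; nlminb's
    # "false convergence" at a zero-variance boundary and a singular Hessian
    # both still yield a valid maximized likelihood, so those fits stay
    # ranked (the near-zero gradient is the arbiter)
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    ll <- as.numeric(ll)
    # glmmTMB reports logLik as NA whenever the Hessian is singular, but the
    # maximized objective (the negative log-likelihood) is still valid there
    if (!is.finite(ll) && is.finite(fit$fit$objective))
      ll <- -fit$fit$objective
    grad <- fit$sdr$gradient.fixed %||% NA_real_
    conv <- is.finite(ll) &&
      (isTRUE(fit$fit$convergence == 0) ||
         (all(is.finite(grad)) && max(abs(grad)) < 1e-3))
    n <- stats::nobs(fit)
    sl <- if (nm == "none") c(slope = NA_real_, se = NA_real_)
    else fixef_slope(fit, nm, data)
    rows[[nm]] <- data.frame(fixed_effect = label, slope = unname(sl["slope"]),
                             se = unname(sl["se"]),
                             irr = if (is.na(sl["slope"])) NA_real_
                             else irr(unname(sl["slope"])),
                             loglik = as.numeric(ll), k = k, n = n,
                             aicc = aicc(as.numeric(ll), k, n),
                             converged = conv)
  }
  out <- do.call(rbind, rows)
  ranked <- out$converged & !is.na(out$aicc)
  out$delta_aicc <- NA_real_
  if (any(ranked)) out$delta_aicc[ranked] <- out$aicc[ranked] -
    min(out$aicc[ranked])
  # baseline for "strong support": the intercept-only null, except for the
  # prop_adult set where week sits in every candidate so the week-only model
  # is the meaningful reference
  baseline <- if (response == "prop_adult") "week" else "none"
  null_aicc <- out$aicc[out$fixed_effect == baseline & ranked]
  out$strong_support <- ranked & length(null_aicc) == 1L &
    !is.na(out$aicc) & out$aicc < (null_aicc[1] - 2)
  out <- out[order(!ranked, out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("model_set", "data.frame"), fits = fits,
            response = response,
            week_in_all = response == "prop_adult")
}

#' @export
print.model_set <- function(x, digits = 3, ...) {
  cat(sprintf("AICc-ranked single-covariate model set (response: %s)\n",
              attr(x, "response")))
  if (isTRUE(attr(x, "week_in_all")))
    cat("  (week included in every candidate; 'none' = intercept-only null)\n")
  disp <- data.frame(fixed_effect = x$fixed_effect,
                     slope = round(x$slope, digits),
                     se = round(x$se, digits), irr = round(x$irr, digits),
                     delta_aicc = round(x$delta_aicc, 1), df = x$k,
                     strong = ifelse(x$strong_support, "*", ""),
                     conv = ifelse(x$converged, "", "failed"))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Pearson dispersion statistic of a fitted model
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom. Values near 1 indicate the family's variance assumption is
#' adequate; values well above 1 indicate overdispersion (e.g. Poisson fitted
#' to negative-binomial counts).
#'
#' @param fit A fitted model with `residuals(type = "pearson")` and
#'   `df.residual` methods (`glmmTMB`, `glm`, ...).
#' @return The dispersion statistic (non-negative scalar).
#' @export
dispersion_check <- function(fit) {
  r <- stats::residuals(fit, type = "pearson")
  sum(r^2) / stats::df.residual(fit)
}
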