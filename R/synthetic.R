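# Synthetic field-trapping data with known ground truth.
#
# The generator works at the level the statistics can see: aggregation is
# induced by the trap-allocation model (Dirichlet-multinomial concentration,
# or i.i.d. negative-binomial traps), assortment by a between-trap shift in
# mean body length, demography by a week-dependent juvenile fraction and a
# growing juvenile length mode, and environmental structure by a one-factor
# Gaussian copula around seasonal trends. No fish movement is simulated.

#' Configuration for the synthetic trap-catch generator
#'
#' All arguments have defaults emulating a modest field study; see
#' [paper_scale_preset()] for the 4-site x 13-week x 5-trap study-scale
#' configuration.
#'
#' @param n_sites,n_weeks,n_traps Study design: number of pond sites, weekly
#'   sampling sessions per site, and traps deployed simultaneously per
#'   session.
#' @param catch_mean Expected catch per trap per session.
#' @param catch_dispersion Negative-binomial size parameter of the session
#'   total (smaller = more overdispersed totals).
#' @param allocation How a session's total is split across traps:
#'   `list(model = "dirichlet_multinomial", alpha = ...)` (per-trap Dirichlet
#'   concentration; small alpha = strong aggregation) or `list(model =
#'   "nb_per_trap", mean = ..., size = ...)` (independent NB counts per trap;
#'   session totals are then their sum).
#' @param between_trap_sd_mm SD of the per-trap shift in mean body length
#'   (mm); 0 = no size assortment.
#' @param within_trap_sd_mm SD of individual body length around the trap/age
#'   mean (mm).
#' @param adult_mean_mm Mean adult body length (mm), constant over the season.
#' @param juvenile_mean_mm Mean juvenile length at week 1 (mm).
#' @param juvenile_growth_mm_per_week Weekly growth of the juvenile mode (mm).
#' @param prop_juvenile_logit `c(a, b)`: logit of the juvenile fraction at
#'   week `w` is `a + b*w` (recruitment raises it over the season).
#' @param red_male_logit `c(a, b)`: logit of the probability that an adult is
#'   a breeding-condition (red) male at week `w` is `a + b*w` (the breeding
#'   season wanes, so `b < 0`). Juveniles are never red.
#' @param red_male_aggregation_slope Effect of the session red-male
#'   proportion on the log Dirichlet concentration: `log(alpha_session) =
#'   log(alpha) + slope * p_red`. Positive values make sessions with many
#'   territorial red males less aggregated.
#' @param covariate_slopes Named list of true log-scale effects of trap-level
#'   environmental covariates on the expected catch, e.g.
#'   `list(temperature_c = 0.3)` (per raw covariate unit, centred at the
#'   covariate's configured mean).
#' @param env_model Per-covariate `list(mean, sd, week_slope, rho_temp)`:
#'   session means follow `mean + week_slope*(week - midseason) + sd*z` with
#'   `z` from a one-factor Gaussian copula whose factor is temperature;
#'   `rho_temp` is the target Spearman rank correlation with temperature.
#' @param site_sd_frac,trap_sd_frac Site- and trap-level SD of covariate
#'   offsets as a fraction of the covariate `sd`.
#' @param series_sd_frac,ar1_phi Logger-series noise: stationary SD as a
#'   fraction of the covariate `sd`, and AR(1) autocorrelation of the
#'   one-minute readings.
#' @param session_minutes Length of the logger series (one reading per
#'   minute).
#' @param measured_fraction Probability that a caught fish is measured for
#'   length (1 = all measured).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 4L, n_weeks = 13L, n_traps = 5L,
                             catch_mean = 18,
                             catch_dispersion = 1.2,
                             allocation = list(model = "dirichlet_multinomial",
                                               alpha = 0.5),
                             between_trap_sd_mm = 0,
                             within_trap_sd_mm = 4,
                             adult_mean_mm = 50,
                             juvenile_mean_mm = 12,
                             juvenile_growth_mm_per_week = 1.8,
                             prop_juvenile_logit = c(a = -4, b = 0.5),
                             red_male_logit = c(a = 0.5, b = -0.5),
                             red_male_aggregation_slope = 0,
                             covariate_slopes = list(),
                             env_model = list(
                               temperature_c = list(mean = 15.5, sd = 3.5,
                                                    week_slope = -0.45,
                                                    rho_temp = 1),
                               light_lumft2 = list(mean = 520, sd = 280,
                                                   week_slope = -45,
                                                   rho_temp = 0.5),
                               do_mgl = list(mean = 9.5, sd = 1.8,
                                             week_slope = 0,
                                             rho_temp = -0.2),
                               turbidity_ntu = list(mean = 14, sd = 10,
                                                    week_slope = 0,
                                                    rho_temp = 0.1)),
                             site_sd_frac = 0.5, trap_sd_frac = 0.15,
                             series_sd_frac = 0.1, ar1_phi = 0.9,
                             session_minutes = 120L,
                             measured_fraction = 1,
                             seed = 1L) {
  allocation$model <- match.arg(allocation$model,
                                c("dirichlet_multinomial", "nb_per_trap"))
  if (allocation$model == "dirichlet_multinomial") {
    if (is.null(allocation$alpha) || allocation$alpha <= 0)
      stop("dirichlet_multinomial allocation needs alpha > 0")
  } else {
    allocation$mean <- allocation$mean %||% catch_mean
    allocation$size <- allocation$size %||% 2
  }
  stopifnot(within_trap_sd_mm > 0, between_trap_sd_mm >= 0,
            measured_fraction > 0, measured_fraction <= 1,
            n_traps >= 2, catch_mean > 0, catch_dispersion > 0)
  rho <- vapply(env_model, function(e) e$rho_temp, numeric(1))
  if (any(!is.finite(rho) | abs(rho) > 1))
    stop("infeasible rank-correlation target: |rho_temp| must be <= 1")
  bad <- names(covariate_slopes)[!names(covariate_slopes) %in%
                                   c(names(env_model), "week")]
  if (length(bad)) stop("covariate_slopes refer to unknown covariate(s): ",
                        paste(bad, collapse = ", "))
  rm(rho, bad)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Study-scale generator preset
#'
#' A configuration matching the scale of the motivating field study: 4 pond
#' sites sampled on 13 alternating weeks (May-November) with 5 simultaneously
#' deployed traps, a per-trap mean catch of about 18 with strongly
#' overdispersed totals, strong aggregation (Dirichlet concentration 0.5),
#' a positive effect of the red-male proportion on the allocation
#' concentration (more breeding males, less aggregation), no body-size
#' assortment, and a temperature-light rank correlation of 0.5.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @examples
#' cfg <- paper_scale_preset(seed = 7)
#' cfg$n_sites * cfg$n_weeks  # 52 sessions
#' @export
paper_scale_preset <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 4L, n_weeks = 13L, n_traps = 5L,
                   catch_mean = 18, catch_dispersion = 1.2,
                   allocation = list(model = "dirichlet_multinomial",
                                     alpha = 0.5),
                   red_male_aggregation_slope = 3)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Generate a complete synthetic field dataset
#'
#' Draws catches, per-fish body lengths and environmental tables for every
#' site-week sampling session under the configured ground truth, in the exact
#' CSV schemas consumed by [read_catch_table()] and [read_env_tables()].
#'
#' @param config A `synthetic_config`.
#' @param include_env Generate the (bulky) one-minute logger series and spot
#'   tables? `FALSE` returns `NULL` for both, which is faster for tests that
#'   only need catches and lengths.
#' @return A list with `catches`, `lengths`, `env_loggers`, `env_spot`
#'   (data.frames) and `truth`: per-session ground truth (`p_red`,
#'   `allocation concentration`, expected total, per-trap true covariate
#'   means), per-fish age classes, and the true covariate slopes.
#' @examples
#' dat <- generate_dataset(paper_scale_preset(seed = 7))
#' nrow(dat$catches)  # 4 sites x 13 weeks x 5 traps = 260
#' @export
generate_dataset <- function(config, include_env = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config, include_env))
}

generate_dataset_impl <- function(cfg, include_env) {
  K <- cfg$n_traps
  sites <- if (cfg$n_sites <= 26L) paste0("pond_", LETTERS[seq_len(cfg$n_sites)])
  else sprintf("pond_%03d", seq_len(cfg$n_sites))
  covs <- names(cfg$env_model)
  mid <- (cfg$n_weeks + 1) / 2
  # latent-normal loadings reproducing the target Spearman correlations
  load <- vapply(cfg$env_model, function(e) 2 * sin(pi * e$rho_temp / 6),
                 numeric(1))
  load["temperature_c"] <- 1
  # site offsets share the copula factor structure so between-site variation
  # does not dilute the target cross-covariate rank correlations
  f_site <- stats::rnorm(cfg$n_sites)
  site_off <- matrix(NA_real_, cfg$n_sites, length(covs),
                     dimnames = list(sites, covs))
  for (v in covs)
    site_off[, v] <- cfg$site_sd_frac * cfg$env_model[[v]]$sd *
      (load[v] * f_site + sqrt(max(0, 1 - load[v]^2)) *
         stats::rnorm(cfg$n_sites))
  am_first <- stats::runif(cfg$n_sites) < 0.5

  catches <- lengths_tab <- loggers <- spot <- list()
  truth_sessions <- truth_fish <- truth_env <- list()
  base_date <- as.Date("2021-05-03")

  for (si in seq_len(cfg$n_sites)) {
    for (w in seq_len(cfg$n_weeks)) {
      tod <- if (xor(am_first[si], w %% 2 == 0)) "pm" else "am"
      # --- environment -------------------------------------------------
      f <- stats::rnorm(1)
      trap_env <- matrix(NA_real_, K, length(covs),
                         dimnames = list(NULL, covs))
      sess_env <- numeric(length(covs)); names(sess_env) <- covs
      for (v in covs) {
        e <- cfg$env_model[[v]]
        z <- load[v] * f + sqrt(max(0, 1 - load[v]^2)) * stats::rnorm(1)
        sv <- e$mean + site_off[si, v] + e$week_slope * (w - mid) + e$sd * z
        tv <- sv + stats::rnorm(K, 0, cfg$trap_sd_frac * e$sd)
        if (v != "temperature_c") tv <- pmax(tv, 0.01)
        trap_env[, v] <- tv
        sess_env[v] <- sv
      }
      # --- catches -----------------------------------------------------
      p_juv <- stats::plogis(cfg$prop_juvenile_logit[["a"]] +
                               cfg$prop_juvenile_logit[["b"]] * w)
      p_red <- stats::plogis(cfg$red_male_logit[["a"]] +
                               cfg$red_male_logit[["b"]] * w)
      mult <- rep(1, K)
      for (v in names(cfg$covariate_slopes)) {
        x <- if (v == "week") rep(w - mid, K)
        else trap_env[, v] - cfg$env_model[[v]]$mean
        mult <- mult * exp(cfg$covariate_slopes[[v]] * x)
      }
      if (cfg$allocation$model == "dirichlet_multinomial") {
        mu_total <- cfg$catch_mean * sum(mult)
        total <- stats::rnbinom(1, mu = mu_total, size = cfg$catch_dispersion)
        alpha_s <- cfg$allocation$alpha *
          exp(cfg$red_male_aggregation_slope * p_red)
        shape <- alpha_s * K * mult / sum(mult)
        p <- rdirichlet1(shape)
        n_trap <- as.integer(stats::rmultinom(1, total, p))
        conc <- alpha_s
      } else {
        mu_trap <- cfg$allocation$mean * mult
        n_trap <- stats::rnbinom(K, mu = mu_trap, size = cfg$allocation$size)
        total <- sum(n_trap)
        mu_total <- sum(mu_trap)
        conc <- NA_real_
      }
      # --- fish --------------------------------------------------------
      trap_shift <- stats::rnorm(K, 0, cfg$between_trap_sd_mm)
      juv_mean <- cfg$juvenile_mean_mm + cfg$juvenile_growth_mm_per_week * w
      n_red <- integer(K)
      for (j in seq_len(K)) {
        n <- n_trap[j]
        if (n == 0) next
        is_juv <- stats::runif(n) < p_juv
        mu_len <- ifelse(is_juv, juv_mean, cfg$adult_mean_mm) + trap_shift[j]
        len <- pmax(stats::rnorm(n, mu_len, cfg$within_trap_sd_mm), 3)
        n_red[j] <- stats::rbinom(1, sum(!is_juv), p_red)
        measured <- if (cfg$measured_fraction < 1)
          stats::runif(n) < cfg$measured_fraction else rep(TRUE, n)
        if (any(measured)) {
          lengths_tab[[length(lengths_tab) + 1L]] <- data.frame(
            site_id = sites[si], week = w, trap_location = j,
            fish_index = seq_len(sum(measured)),
            body_length_mm = round(len[measured], 1))
        }
        truth_fish[[length(truth_fish) + 1L]] <- data.frame(
          site_id = sites[si], week = w, trap_location = j,
          age_class = ifelse(is_juv, "juvenile", "adult"),
          true_length_mm = len, measured = measured)
      }
      catches[[length(catches) + 1L]] <- data.frame(
        site_id = sites[si], week = w, time_of_day = tod,
        trap_location = seq_len(K), n_total = n_trap, n_red_males = n_red)
      truth_env[[length(truth_env) + 1L]] <- cbind(
        data.frame(site_id = sites[si], week = w,
                   trap_location = seq_len(K)),
        as.data.frame(trap_env))
      truth_sessions[[length(truth_sessions) + 1L]] <- data.frame(
        site_id = sites[si], week = w, time_of_day = tod, p_red = p_red,
        p_juvenile = p_juv, concentration = conc, expected_total = mu_total,
        total = total)
      # --- logger series and spot measures ----------------------------
      if (include_env) {
        t0 <- as.POSIXct(paste(base_date + (w - 1) * 14,
                               if (tod == "am") "10:00:00" else "13:00:00"),
                         tz = "UTC")
        mins <- seq_len(cfg$session_minutes) - 1L
        for (j in seq_len(K)) {
          for (v in c("temperature_c", "light_lumft2")) {
            sdv <- cfg$series_sd_frac * cfg$env_model[[v]]$sd
            innov <- stats::rnorm(cfg$session_minutes, 0,
                                  sdv * sqrt(1 - cfg$ar1_phi^2))
            ser <- stats::filter(innov, cfg$ar1_phi, method = "recursive",
                                 init = stats::rnorm(1, 0, sdv))
            val <- trap_env[j, v] + as.numeric(ser)
            if (v == "light_lumft2") val <- pmax(val, 0)
            if (v == "temperature_c") temp_ser <- val else light_ser <- val
          }
          loggers[[length(loggers) + 1L]] <- data.frame(
            site_id = sites[si], week = w, trap_location = j,
            timestamp = format(t0 + mins * 60, "%Y-%m-%dT%H:%M:%S"),
            temperature_c = round(temp_ser, 3),
            light_lumft2 = round(light_ser, 2))
          for (ph in c("start", "end")) {
            spot[[length(spot) + 1L]] <- data.frame(
              site_id = sites[si], week = w, trap_location = j, phase = ph,
              turbidity_ntu = round(pmax(trap_env[j, "turbidity_ntu"] +
                                           stats::rnorm(1, 0, 0.5), 0), 2),
              do_mgl = round(pmax(trap_env[j, "do_mgl"] +
                                    stats::rnorm(1, 0, 0.1), 0), 2))
          }
        }
      }
    }
  }
  list(catches = do.call(rbind, catches),
       lengths = do.call(rbind, lengths_tab),
       env_loggers = if (include_env) do.call(rbind, loggers),
       env_spot = if (include_env) do.call(rbind, spot),
       truth = list(sessions = do.call(rbind, truth_sessions),
                    fish = do.call(rbind, truth_fish),
                    trap_env = do.call(rbind, truth_env),
                    covariate_slopes = cfg$covariate_slopes,
                    config = cfg))
}

#' Write a generated dataset to CSV files
#'
#' @param dataset Output of [generate_dataset()].
#' @param outdir Directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("catches", "lengths", "env_loggers", "env_spot")) {
    if (is.null(dataset[[nm]])) next
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(dataset[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
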