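# End-to-end orchestration: assemble model frames from the stage outputs and
# run the whole pipeline from a single configuration.

#' Assemble trap- and session-level model frames
#'
#' Joins the catch sessions, the environmental summaries, the adult/juvenile
#' split and the aggregation scores into the two data frames the model sets
#' operate on: one row per trap per session (responses `catch_per_trap`,
#' `prop_adult`) and one row per included session (response
#' `aggregation_score`, with session-mean covariates and the red-male
#' proportion).
#'
#' @param sessions A `trap_sessions` object.
#' @param env_summary An `env_summary` data.frame from [summarize_env()]
#'   (trap and session rows), or `NULL` to omit environmental covariates.
#' @param aggregation An `aggregation_scores` data.frame; computed with the
#'   default threshold when `NULL`.
#' @param split An `adult_split` for the measured fish; computed with
#'   `two_means` when `NULL` and lengths are present.
#' @return A list with `trap` and `session` data.frames.
#' @export
model_frames <- function(sessions, env_summary = NULL, aggregation = NULL,
                         split = NULL) {
  catch <- as.data.frame(sessions)
  lens <- session_lengths(sessions)
  if (is.null(split) && nrow(lens))
    split <- split_adults_juveniles(lens)
  if (!is.null(split)) {
    f <- split$fish
    f$n <- 1L
    ad <- stats::aggregate(n ~ site_id + week + trap_location + age_class,
                           data = f, FUN = sum)
    wide <- stats::reshape(ad, idvar = c("site_id", "week", "trap_location"),
                           timevar = "age_class", direction = "wide")
    names(wide) <- sub("^n\\.", "n_", names(wide))
    for (v in c("n_adult", "n_juvenile"))
      if (!v %in% names(wide)) wide[[v]] <- 0L
    wide$n_adult[is.na(wide$n_adult)] <- 0L
    wide$n_juvenile[is.na(wide$n_juvenile)] <- 0L
    catch <- merge(catch, wide[, c("site_id", "week", "trap_location",
                                   "n_adult", "n_juvenile")],
                   by = c("site_id", "week", "trap_location"), all.x = TRUE)
    catch$n_adult[is.na(catch$n_adult)] <- 0L
    catch$n_juvenile[is.na(catch$n_juvenile)] <- 0L
  }
  env_vars <- c("temperature_c", "light_lumft2", "turbidity_ntu", "do_mgl")
  if (!is.null(env_summary)) {
    trap_env <- env_summary[!is.na(env_summary$trap_location),
                            c("site_id", "week", "trap_location", env_vars)]
    catch <- merge(catch, trap_env,
                   by = c("site_id", "week", "trap_location"), all.x = TRUE)
  }
  catch <- catch[order(catch$site_id, catch$week, catch$trap_location), ]
  rownames(catch) <- NULL

  agg <- aggregation %||% score_sessions(sessions)
  sess <- agg[agg$included, , drop = FALSE]
  red <- do.call(rbind, lapply(unclass(sessions), function(s)
    data.frame(site_id = s$site_id, week = s$week,
               prop_red_males = if (s$session_total > 0)
                 sum(s$traps$n_red_males) / s$session_total else NA_real_)))
  sess <- merge(as.data.frame(sess), red, by = c("site_id", "week"))
  if (!is.null(env_summary)) {
    sess_env <- env_summary[is.na(env_summary$trap_location),
                            c("site_id", "week", env_vars)]
    sess <- merge(sess, sess_env, by = c("site_id", "week"), all.x = TRUE)
  }
  sess <- sess[order(sess$site_id, sess$week), ]
  rownames(sess) <- NULL
  list(trap = catch, session = sess)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full trap-catch analysis pipeline
#'
#' Reads (or simulates) the input tables, then runs environmental
#' summarization and screens, aggregation scoring, per-session assortment
#' tests and the AICc model comparisons, writing one CSV per stage plus a
#' run manifest into the output directory.
#'
#' @param config A configuration list or the path to a YAML file with the
#'   same structure. Recognised fields: `inputs` (paths `catches`, `lengths`,
#'   `env_loggers`, `env_spot`) or `simulate` (generator overrides, see
#'   [synthetic_config()]; `preset: paper` selects [paper_scale_preset()]);
#'   `min_catch` (default 26), `n_iter` (default 10000), `lower_alpha`
#'   (0.025), `upper_alpha` (0.975), `seed` (master seed, default 1),
#'   `responses` (model sets to fit; default all three), `outdir`.
#' @param outdir Output directory, overriding `config$outdir` (default
#'   `"trapsocial_run"`).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  min_catch <- config$min_catch %||% 26L
  n_iter <- config$n_iter %||% 10000L
  lower <- config$lower_alpha %||% 0.025
  upper <- config$upper_alpha %||% 0.975
  seed <- config$seed %||% 1L
  responses <- config$responses %||% c("catch_per_trap", "prop_adult",
                                       "aggregation_score")
  outdir <- outdir %||% config$outdir %||% "trapsocial_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    preset <- identical(sim$preset, "paper")
    sim$preset <- NULL
    if (is.null(sim$seed)) sim$seed <- seed
    cfg <- run_stage("simulate", do.call(
      if (preset) paper_scale_preset else synthetic_config, sim))
    dat <- run_stage("simulate", generate_dataset(cfg))
    write_dataset(dat, file.path(outdir, "simulated"))
    inputs <- dat[c("catches", "lengths", "env_loggers", "env_spot")]
  } else {
    inp <- config$inputs %||% stop("config needs either 'inputs' or 'simulate'")
    for (nm in c("catches")) if (is.null(inp[[nm]]))
      stop("config$inputs$", nm, " is required")
    for (nm in names(inp)) if (is.character(inp[[nm]]) &&
                               !file.exists(inp[[nm]]))
      stop("input file not found: ", nm, " = ", inp[[nm]])
    inputs <- inp
  }

  sessions <- run_stage("io", read_catch_table(inputs$catches,
                                               inputs$lengths))
  env_sum <- corr <- fried <- NULL
  if (!is.null(inputs$env_loggers)) {
    env <- run_stage("io", read_env_tables(inputs$env_loggers,
                                           inputs$env_spot))
    env_sum <- run_stage("envstats", summarize_env(env))
    tl <- env_sum[!is.na(env_sum$trap_location), ]
    corr <- run_stage("envstats", covariate_correlations(tl))
    utils::write.csv(env_sum, file.path(outdir, "envsummary.csv"),
                     row.names = FALSE)
    utils::write.csv(corr, file.path(outdir, "env_correlations.csv"),
                     row.names = FALSE)
  }
  fried <- run_stage("envstats", trap_preference_test(sessions))
  utils::write.csv(fried, file.path(outdir, "trap_preference.csv"),
                   row.names = FALSE)

  agg <- run_stage("aggregation", score_sessions(sessions, min_catch))
  utils::write.csv(agg, file.path(outdir, "aggregation.csv"),
                   row.names = FALSE)

  assort <- run_stage("assortment",
                      assort_sessions(sessions, n_iter = n_iter, seed = seed,
                                      lower_alpha = lower,
                                      upper_alpha = upper))
  utils::write.csv(assort, file.path(outdir, "assortment.csv"),
                   row.names = FALSE)

  frames <- run_stage("modelsel", model_frames(sessions, env_sum, agg))
  model_sets <- list()
  for (resp in responses) {
    d <- if (resp == "aggregation_score") frames$session else frames$trap
    covars <- default_covariate_sets(resp)
    if (is.null(env_sum))
      covars <- setdiff(covars, c("temperature_c", "light_lumft2", "do_mgl",
                                  "turbidity_ntu"))
    if (resp == "prop_adult" && !"n_adult" %in% names(d)) next
    ms <- run_stage("modelsel",
                    fit_model_set(d, response = resp, covariates = covars))
    model_sets[[resp]] <- ms
    utils::write.csv(as.data.frame(ms),
                     file.path(outdir, paste0("ranking_", resp, ".csv")),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "trapsocial",
    version = as.character(utils::packageVersion("trapsocial")),
    r_version = as.character(getRversion()),
    seed = seed, min_catch = min_catch, n_iter = n_iter,
    alphas = c(lower, upper),
    config_hash = fnv1a_hash(utils::capture.output(utils::str(config))),
    n_sessions = length(sessions),
    n_included = sum(agg$included),
    assortment_classes = as.list(table(assort$classification)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(sessions = sessions, env_summary = env_sum,
                 correlations = corr, trap_preference = fried,
                 aggregation = agg, assortment = assort, frames = frames,
                 model_sets = model_sets, manifest = manifest,
                 outdir = outdir))
}
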