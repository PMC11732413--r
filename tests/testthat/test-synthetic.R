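test_that("generation is deterministic given config and seed", {
  cfg <- paper_scale_preset(n_sites = 2L, n_weeks = 4L, seed = 123,
                            session_minutes = 15L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$catches, b$catches)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$env_loggers, b$env_loggers)
  expect_identical(a$env_spot, b$env_spot)
  c2 <- generate_dataset(paper_scale_preset(n_sites = 2L, n_weeks = 4L,
                                            seed = 124,
                                            session_minutes = 15L))
  expect_false(identical(a$catches, c2$catches))
})

test_that("per-session trap counts sum to the drawn session total", {
  dat <- generate_dataset(paper_scale_preset(seed = 2), include_env = FALSE)
  totals <- aggregate(n_total ~ site_id + week, dat$catches, sum)
  m <- merge(totals, dat$truth$sessions, by = c("site_id", "week"))
  expect_equal(m$n_total, m$total)
})

test_that("the study-scale preset has the documented shape and scale", {
  dat <- generate_dataset(paper_scale_preset(seed = 7), include_env = FALSE)
  expect_equal(nrow(dat$catches), 260)                     # 4 x 13 x 5
  expect_equal(length(unique(dat$catches$site_id)), 4)
  sess_tot <- aggregate(n_total ~ site_id + week, dat$catches, sum)$n_total
  expect_equal(length(sess_tot), 52)
  se <- sd(sess_tot) / sqrt(length(sess_tot))
  expect_lt(abs(mean(sess_tot) - 5 * 18), 2 * se)
})

test_that("preset environment output gives a positive temperature-light correlation", {
  for (seed in c(1, 2, 3)) {
    dat <- generate_dataset(paper_scale_preset(seed = seed,
                                               session_minutes = 10L))
    es <- summarize_env(read_env_tables(dat$env_loggers, dat$env_spot),
                        "trap")
    cc <- covariate_correlations(es)
    expect_gt(cc$rho[cc$var1 == "temperature_c" &
                       cc$var2 == "light_lumft2"], 0)
  }
})

test_that("aggregation rises monotonically as the Dirichlet concentration falls", {
  med_score <- function(alpha) {
    cfg <- synthetic_config(n_sites = 10L, n_weeks = 20L,
                            allocation = list(model = "dirichlet_multinomial",
                                              alpha = alpha), seed = 5L)
    dat <- generate_dataset(cfg, include_env = FALSE)
    agg <- suppressWarnings(score_sessions(read_catch_table(dat$catches),
                                           min_catch = 1))
    median(agg$score, na.rm = TRUE)
  }
  expect_gt(med_score(0.2), med_score(50))
})

test_that("red males never exceed the adults present in a trap", {
  dat <- generate_dataset(paper_scale_preset(seed = 44), include_env = FALSE)
  f <- dat$truth$fish
  f$n_adult <- as.integer(f$age_class == "adult")
  adults <- aggregate(n_adult ~ site_id + week + trap_location, f, sum)
  m <- merge(dat$catches, adults, by = c("site_id", "week", "trap_location"),
             all.x = TRUE)
  m$n_adult[is.na(m$n_adult)] <- 0
  expect_true(all(m$n_red_males <= m$n_adult))
  expect_true(all(dat$catches$n_red_males <= dat$catches$n_total))
})

test_that("invalid configurations are rejected before generation", {
  expect_error(synthetic_config(env_model = list(
    temperature_c = list(mean = 15, sd = 3, week_slope = 0, rho_temp = 1),
    light_lumft2 = list(mean = 500, sd = 200, week_slope = 0,
                        rho_temp = 1.4))), "infeasible")
  expect_error(synthetic_config(covariate_slopes = list(ph = 0.2)),
               "unknown covariate")
  expect_error(synthetic_config(allocation = list(
    model = "dirichlet_multinomial", alpha = -1)), "alpha")
})

test_that("partial measurement thins the length table but not the counts", {
  cfg <- paper_scale_preset(n_sites = 2L, n_weeks = 6L, seed = 10,
                            measured_fraction = 0.6)
  dat <- generate_dataset(cfg, include_env = FALSE)
  sessions <- read_catch_table(dat$catches, dat$lengths)
  n_meas <- sum(vapply(sessions, function(s) sum(s$traps$n_measured),
                       integer(1)))
  n_tot <- sum(dat$catches$n_total)
  expect_lt(n_meas, n_tot)
  expect_gt(n_meas, 0.4 * n_tot)
})

test_that("written datasets satisfy the io round trip", {
  dat <- generate_dataset(paper_scale_preset(n_sites = 2L, n_weeks = 3L,
                                             seed = 6, session_minutes = 8L))
  dir <- withr::local_tempdir()
  write_dataset(dat, dir)
  sessions <- read_catch_table(file.path(dir, "catches.csv"),
                               file.path(dir, "lengths.csv"))
  expect_length(sessions, 6)
  env <- read_env_tables(file.path(dir, "env_loggers.csv"),
                         file.path(dir, "env_spot.csv"))
  expect_length(env, 30)
  expect_equal(nrow(env[[1]]$series), 8)
})
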