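test_that("AICc matches the hand formula and its limits", {
  expect_equal(aicc(-100, k = 4, n = 50), 200 + 8 + 40 / 45)
  expect_equal(aicc(-100, k = 0, n = 50), 200)
  # correction vanishes as n grows
  expect_equal(aicc(-100, k = 4, n = 1e9), 208, tolerance = 1e-6)
  expect_warning(val <- aicc(-100, k = 10, n = 11), "undefined")
  expect_true(is.na(val))
})

test_that("IRR back-transform is exp(slope) and multiplicative in the sign", {
  expect_equal(irr(0), 1)
  set.seed(5)
  for (s in rnorm(20, sd = 2)) expect_equal(irr(s) * irr(-s), 1)
})

test_that("percent change restates slopes with the right direction", {
  p <- percent_change(-3.423)
  expect_equal(round(as.numeric(p)), 97)
  expect_equal(attr(p, "direction"), "decrease")
  expect_equal(as.numeric(percent_change(0)), 0)
  up <- percent_change(log(2))
  expect_equal(as.numeric(up), 100)
  expect_equal(attr(up, "direction"), "increase")
})

test_that("two-means split finds the adult/juvenile divide", {
  x <- c(20, 21, 22, 48, 50, 52)
  sp <- split_adults_juveniles(x, rep(1, 6))
  expect_equal(sum(sp$fish$age_class == "adult"), 3)
  expect_gt(sp$cutoffs$cutoff, 22)
  expect_lt(sp$cutoffs$cutoff, 48)
  expect_equal(sp$cutoffs$cutoff, oracle_best_split(x))
  expect_false(sp$cutoffs$flagged)

  # a user-supplied cutoff anywhere in the gap reproduces the labels
  fx <- split_adults_juveniles(x, rep(1, 6), method = "fixed_cutoff",
                               cutoff = 35)
  expect_equal(fx$fish$age_class, sp$fish$age_class)
})

test_that("weeks without a clear divide are flagged", {
  set.seed(8)
  uni <- rnorm(40, mean = 45, sd = 3)                  # unimodal week
  sp <- split_adults_juveniles(uni, rep(2, 40))
  expect_true(sp$cutoffs$flagged)
  same <- split_adults_juveniles(rep(30, 5), rep(1, 5))  # degenerate week
  expect_true(same$cutoffs$flagged)
  expect_equal(length(unique(same$fish$age_class)), 1)
})

test_that("per-week splits track a growing juvenile mode", {
  set.seed(3)
  wk <- rep(1:10, each = 30)
  juv <- 12 + 1.8 * wk + rnorm(length(wk), sd = 2)
  adu <- 50 + rnorm(length(wk), sd = 3)
  is_j <- runif(length(wk)) < 0.5
  sp <- split_adults_juveniles(ifelse(is_j, juv, adu), wk)
  expect_gt(mean((sp$fish$age_class == "juvenile") == is_j), 0.98)
})

fit_frames <- function(seed = 19) {
  dat <- generate_dataset(paper_scale_preset(seed = seed,
                                             session_minutes = 12L))
  sessions <- read_catch_table(dat$catches, dat$lengths)
  env <- summarize_env(read_env_tables(dat$env_loggers, dat$env_spot))
  model_frames(sessions, env)
}

test_that("model sets carry a null model and coherent AICc bookkeeping", {
  fr <- fit_frames()
  ms <- fit_model_set(fr$session, "aggregation_score")
  expect_true("none" %in% ms$fixed_effect)
  ok <- ms$converged & !is.na(ms$delta_aicc)
  expect_equal(min(ms$delta_aicc[ok]), 0)
  expect_true(all(ms$delta_aicc[ok] >= 0))
  # reference bookkeeping: one-covariate NB site-intercept models estimate
  # intercept + slope + dispersion + site variance = 4; the null drops the slope
  expect_equal(unique(ms$k[ms$fixed_effect %in%
                             c("temperature_c", "do_mgl", "week")]), 4)
  expect_equal(ms$k[ms$fixed_effect == "none"], 3)
  expect_equal(ms$irr, exp(ms$slope), tolerance = 1e-12)
})

test_that("week is carried in every adult-proportion candidate", {
  fr <- fit_frames()
  ms <- fit_model_set(fr$trap, "prop_adult")
  fits <- attr(ms, "fits")
  for (nm in setdiff(names(fits), "none"))
    expect_true("week" %in% all.vars(formula(fits[[nm]])),
                label = paste("week in", nm))
  expect_false("week" %in% all.vars(formula(fits[["none"]])))
})

test_that("affine covariate rescaling leaves AICc alone and rescales the slope", {
  fr <- fit_frames()
  d <- fr$session
  ms1 <- fit_model_set(d, "aggregation_score", covariates = "temperature_c")
  d$temperature_c <- d$temperature_c / 10 + 3
  ms2 <- fit_model_set(d, "aggregation_score", covariates = "temperature_c")
  r1 <- ms1[ms1$fixed_effect == "temperature_c", ]
  r2 <- ms2[ms2$fixed_effect == "temperature_c", ]
  expect_equal(r1$aicc, r2$aicc, tolerance = 1e-4)
  expect_equal(r2$slope, r1$slope * 10, tolerance = 1e-3)
})

test_that("the Pearson dispersion statistic separates Poisson from overdispersed fits", {
  set.seed(23)
  d <- data.frame(y = rpois(600, 12))
  fit <- glm(y ~ 1, family = poisson, data = d)
  expect_lt(abs(dispersion_check(fit) - 1), 0.2)
  d2 <- data.frame(y = rnbinom(600, mu = 12, size = 0.8))
  fit2 <- glm(y ~ 1, family = poisson, data = d2)
  expect_gt(dispersion_check(fit2), 2)
  # a saturated-perfect fit has zero residuals
  fit3 <- glm(y ~ 1, family = poisson, data = data.frame(y = rep(4, 10)))
  expect_equal(dispersion_check(fit3), 0)
})
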