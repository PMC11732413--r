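make_env <- function(traps) {
  # traps: list of list(temp=..., light=..., turb=c(s,e), do=c(s,e), n=...)
  logs <- do.call(rbind, lapply(seq_along(traps), function(j) {
    tr <- traps[[j]]
    n <- tr$n %||% 10L
    data.frame(site_id = "P", week = 1L, trap_location = j,
               timestamp = format(as.POSIXct("2021-05-03 10:00:00",
                                             tz = "UTC") + 60 * (seq_len(n) - 1),
                                  "%Y-%m-%dT%H:%M:%S"),
               temperature_c = tr$temp, light_lumft2 = tr$light)
  }))
  spots <- do.call(rbind, lapply(seq_along(traps), function(j) {
    tr <- traps[[j]]
    data.frame(site_id = "P", week = 1L, trap_location = j,
               phase = c("start", "end"),
               turbidity_ntu = tr$turb, do_mgl = tr$do)
  }))
  read_env_tables(logs, spots)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trap and session means follow the two-step averaging rule", {
  env <- make_env(list(
    list(temp = 15, light = 1, turb = c(10, 20), do = c(8, 8)),
    list(temp = 15, light = 2, turb = c(10, 10), do = c(9, 9)),
    list(temp = 15, light = 3, turb = c(10, 10), do = c(7, 7)),
    list(temp = 15, light = 4, turb = c(10, 10), do = c(8, 8)),
    list(temp = 15, light = 5, turb = c(10, 10), do = c(8, 8), n = 40L)))
  s <- summarize_env(env)
  trap <- s[!is.na(s$trap_location), ]
  sess <- s[is.na(s$trap_location), ]
  expect_equal(trap$temperature_c, rep(15, 5))       # constant series
  expect_equal(trap$turbidity_ntu[1], 15)            # mean of start/end pair
  expect_equal(sess$light_lumft2, 3)                 # mean of trap means {1..5}
  # two-step average, not pooled-series mean: trap 3 has 4x the readings but
  # still contributes 1/5 of the session mean
  pooled <- with(do.call(rbind, lapply(unclass(env), `[[`, "series")),
                 mean(light_lumft2))
  expect_gt(pooled, 3)
  expect_equal(sess$light_lumft2, 3)
})

test_that("Spearman screen recovers monotone relationships and flags constants", {
  df <- data.frame(site_id = "P", week = 1:12, trap_location = 1L,
                   temperature_c = 1:12, light_lumft2 = (1:12)^3,
                   do_mgl = -(1:12), turbidity_ntu = 5)
  cc <- covariate_correlations(df, vars = c("temperature_c", "light_lumft2",
                                            "do_mgl", "turbidity_ntu"))
  get <- function(a, b) cc[cc$var1 == a & cc$var2 == b, ]
  expect_equal(get("temperature_c", "light_lumft2")$rho, 1)
  expect_equal(get("temperature_c", "do_mgl")$rho, -1)
  expect_true(is.na(get("temperature_c", "turbidity_ntu")$rho))
  expect_equal(get("temperature_c", "light_lumft2")$n, 12)
})

test_that("generator default covariance yields the configured temperature-light correlation", {
  dat <- generate_dataset(paper_scale_preset(seed = 101))
  es <- summarize_env(read_env_tables(dat$env_loggers, dat$env_spot), "trap")
  cc <- covariate_correlations(es)
  r <- cc$rho[cc$var1 == "temperature_c" & cc$var2 == "light_lumft2"]
  expect_equal(cc$n[cc$var1 == "temperature_c" &
                      cc$var2 == "light_lumft2"], 260)
  expect_lt(abs(r - 0.5), 0.15)
})

counts_to_sessions <- function(m) {
  # m: blocks x traps matrix of counts, one site
  rows <- do.call(rbind, lapply(seq_len(nrow(m)), function(w)
    data.frame(site_id = "P", week = w, time_of_day = "am",
               trap_location = seq_len(ncol(m)), n_total = m[w, ],
               n_red_males = 0L)))
  read_catch_table(rows, n_traps = ncol(m))
}

test_that("Friedman trap-preference test matches the rank-sum closed form", {
  # counts identical across traps in every week: no rank variation at all
  flat <- counts_to_sessions(matrix(7, nrow = 6, ncol = 5))
  res <- trap_preference_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # one trap always strictly highest, fully consistent ranks, 13 blocks:
  # closed form 12n/(k(k+1)) * sum_j (r_j - (k+1)/2)^2 = 52 for k = 5
  m <- matrix(rep(c(1, 2, 3, 4, 50), each = 13), nrow = 13)
  res2 <- trap_preference_test(counts_to_sessions(m))
  expect_equal(res2$statistic, 52)
  expect_equal(res2$statistic, oracle_friedman(m))
  expect_equal(res2$df, 4)

  # ranks, not raw counts: any monotone transformation leaves it unchanged
  res3 <- trap_preference_test(counts_to_sessions(m^2))
  expect_equal(res3$statistic, res2$statistic)
})

test_that("five-trap designs always give four degrees of freedom", {
  dat <- generate_dataset(paper_scale_preset(seed = 31), include_env = FALSE)
  res <- trap_preference_test(read_catch_table(dat$catches))
  expect_equal(nrow(res), 4)
  expect_true(all(res$df == 4))
  expect_true(all(res$n_blocks == 13))
})

test_that("sites with a single session are skipped with a warning", {
  one <- counts_to_sessions(matrix(c(1, 2, 3, 4, 5), nrow = 1))
  expect_warning(res <- trap_preference_test(one), "skipped")
  expect_equal(nrow(res), 0)
})
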