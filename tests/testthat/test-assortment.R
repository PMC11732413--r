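test_that("trap COV matches closed forms and the two-pass oracle", {
  expect_identical(trap_cov(c(50, 50, 50)), 0)
  expect_equal(trap_cov(c(40, 50, 60)), 0.2)
  expect_equal(trap_cov(c(30, 70)), sqrt(800) / 50)  # ~0.565685
  expect_equal(trap_cov(c(30, 70)), oracle_cov(c(30, 70)))
  expect_true(is.na(trap_cov(55)))
  expect_true(is.na(trap_cov(numeric(0))))
})

test_that("observed siteCOV is the median over eligible traps", {
  # three traps engineered to COVs 0.1, 0.2, 0.3
  traps <- list(c(40, 50, 60) * 0.5 + 25,      # cov 0.1 via mean 50 sd 5
                c(40, 50, 60),                  # cov 0.2
                c(35, 50, 65))                  # cov 0.3
  expect_equal(observed_sitecov(traps), 0.2, tolerance = 1e-12)
  # even number of eligible traps: midpoint of the central pair
  expect_equal(observed_sitecov(traps[c(1, 3)]), 0.2, tolerance = 1e-12)
  # singleton traps are skipped, not errors
  expect_equal(observed_sitecov(c(traps[2], list(42))), 0.2)
  # no eligible trap at all
  expect_true(is.na(observed_sitecov(list(41, 52, numeric(0)))))
})

test_that("sessions with fewer than two eligible traps are unsuitable", {
  expect_false(assortment_suitable(list(c(40, 41, 42, 43), 50)))  # one trap
  expect_false(assortment_suitable(list(50, 51, 52)))             # singletons
  expect_true(assortment_suitable(list(c(40, 41), c(50, 51))))
  t <- test_assortment(list(c(40, 41, 42), numeric(0)))
  expect_equal(t$classification, "unsuitable")
})

test_that("randomization preserves the degenerate and enumerable cases", {
  # identical lengths: the null is a point mass at zero
  nulls <- randomize_session(list(rep(50, 3), rep(50, 4)), n_iter = 50,
                             seed = 1)
  expect_equal(nulls, rep(0, 50))

  # two traps of two fish {1,1,9,9}: exactly two support points, P(0) = 1/3
  lens <- list(c(1, 1), c(9, 9))
  exact <- enumerate_null_sitecovs(lens)
  expect_equal(sort(unique(round(exact, 6))), c(0, 1.131371))
  expect_equal(mean(exact == 0), 1 / 3)
  nulls <- randomize_session(lens, n_iter = 4000, seed = 2)
  expect_equal(sort(unique(round(nulls, 6))), c(0, 1.131371))
  expect_lt(abs(mean(nulls == 0) - 1 / 3), 3 * sqrt(2 / 9 / 4000))
})

test_that("the seeding contract makes single draws reproducible", {
  lens <- list(c(10, 20, 30), c(40, 50), c(60, 61, 62))
  one <- randomize_session(lens, n_iter = 1, seed = 99)
  expect_identical(randomize_session(lens, n_iter = 1, seed = 99), one)
  many <- randomize_session(lens, n_iter = 25, seed = 99)
  expect_identical(many[1], one)
})

test_that("quantiles count ties as less-than-or-equal", {
  expect_identical(assortment_quantile(0.1, c(0.2, 0.3, 0.4)), 0)
  expect_identical(assortment_quantile(0.5, rep(0.5, 10)), 1)
  nulls <- (1:10001) / 10001
  expect_equal(assortment_quantile(median(nulls), nulls), 5001 / 10001)
})

test_that("quantile classification uses the two-tailed 0.025/0.975 cutoffs", {
  expect_equal(classify_assortment(0.004), "positive")
  expect_equal(classify_assortment(0.195), "none")
  expect_equal(classify_assortment(0.68), "none")
  expect_equal(classify_assortment(0.99), "negative")
  expect_equal(classify_assortment(0.025), "none")  # boundary: strict <
  expect_equal(classify_assortment(0.975), "none")  # boundary: strict >
  expect_equal(classify_assortment(0.1, lower_alpha = 0.2), "positive")
  expect_error(classify_assortment(0.5, lower_alpha = 0.9, upper_alpha = 0.1))
})

test_that("Monte-Carlo null agrees with exhaustive enumeration on small sessions", {
  shapes <- list(list(c(12, 30), c(25, 26), c(40, 41)),       # (2,2,2)
                 list(c(10, 11, 12), c(30, 31), 50))          # (3,2,1)
  for (lens in shapes) {
    exact <- enumerate_null_sitecovs(lens)
    obs <- observed_sitecov(lens)
    q_exact <- assortment_quantile(obs, exact)
    nulls <- randomize_session(lens, n_iter = 6000, seed = 17)
    q_mc <- assortment_quantile(obs, nulls)
    expect_lt(abs(q_mc - q_exact),
              3 * sqrt(q_exact * (1 - q_exact) / 6000) + 1e-9)
  }
})

test_that("per-session seeds reproduce a session in isolation", {
  dat <- generate_dataset(paper_scale_preset(n_sites = 2L, n_weeks = 4L,
                                             seed = 3), include_env = FALSE)
  sessions <- read_catch_table(dat$catches, dat$lengths)
  res <- assort_sessions(sessions, n_iter = 300, seed = 77)
  expect_identical(assort_sessions(sessions, n_iter = 300, seed = 77), res)
  s <- sessions[[3]]
  alone <- test_assortment(s, n_iter = 300,
                           seed = derive_session_seed(77, s$site_id, s$week))
  i <- which(res$site_id == s$site_id & res$week == s$week)
  expect_equal(alone$quantile, res$quantile[i])
})

test_that("the minimum-catch opt-in marks small sessions unsuitable", {
  dat <- generate_dataset(paper_scale_preset(n_sites = 2L, n_weeks = 5L,
                                             seed = 13), include_env = FALSE)
  sessions <- read_catch_table(dat$catches, dat$lengths)
  res <- assort_sessions(sessions, n_iter = 100, seed = 1, min_catch = 1e6)
  expect_true(all(res$classification == "unsuitable"))
})
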