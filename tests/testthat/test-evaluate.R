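two_met_series <- function(times, a, b, strain = "s1") {
  omics_ts(tibble::tibble(strain = strain, time = times,
                          `met:a` = a, `met:b` = b))
}

test_that("trajectory RMSE is zero for identical series and has the offset closed form", {
  tt <- seq(0, 4, length.out = 9)
  ref <- two_met_series(tt, 1 + tt, 2 + 0.5 * tt)
  expect_equal(trajectory_rmse(ref, ref)$total, 0)
  off <- two_met_series(tt, 1 + tt + 0.3, 2 + 0.5 * tt + 0.3)
  r <- trajectory_rmse(off, ref)
  expect_equal(r$total, 0.3 * sqrt(4), tolerance = 1e-6)
  expect_equal(r$per_metabolite$rmse, rep(0.3 * sqrt(4), 2),
               tolerance = 1e-6)
})

test_that("trajectory RMSE matches a hand-computed piecewise-linear integral", {
  # prediction m(t) = t, reference m(t) = 1 on [0, 2]:
  # integral of (1 - t)^2 dt over [0, 2] equals 2/3
  tt <- seq(0, 2, length.out = 5)
  pred <- omics_ts(tibble::tibble(strain = "s1", time = tt, `met:a` = tt))
  ref <- omics_ts(tibble::tibble(strain = "s1", time = tt,
                                 `met:a` = rep(1, 5)))
  r <- trajectory_rmse(pred, ref, grid_points = 1e4)
  expect_equal(r$total, sqrt(2 / 3), tolerance = 1e-6)
})

test_that("spans must overlap and metabolites must be shared", {
  a <- two_met_series(0:3, 1:4, 1:4)
  b <- two_met_series(5:8, 1:4, 1:4)
  expect_error(trajectory_rmse(a, b),
               class = "pathdyn_incompatibility_error")
})

test_that("percent error is normalised time-averaged absolute error", {
  tt <- seq(0, 6, length.out = 13)
  ref <- two_met_series(tt, 2 + tt, rep(4, 13))
  expect_equal(attr(percent_error(ref, ref), "average"), 0)
  twice <- two_met_series(tt, 2 * (2 + tt), rep(8, 13))
  pe <- percent_error(twice, ref)
  expect_equal(pe$percent_error, c(100, 100), tolerance = 1e-6)
  # hand value: |(2 + 0.5 t) - (2 + t)| averaged / mean(2 + t) = (3/2)/5
  half <- two_met_series(tt, 2 + 0.5 * tt, rep(4, 13))
  pe2 <- percent_error(half, ref)
  expect_equal(pe2$percent_error[1], 100 * (3 / 2) / 5, tolerance = 1e-6)
  # zero-reference metabolites are flagged and excluded
  zref <- two_met_series(tt, 2 + tt, rep(0, 13))
  zpred <- two_met_series(tt, 2 + tt, rep(1, 13))
  pez <- percent_error(zpred, zref)
  expect_false(pez$defined[2])
  expect_equal(attr(pez, "average"), pez$percent_error[1])
})

test_that("experiment tables have the configured shape and reproduce under a seed", {
  pool <- small_pool()
  space <- search_space(list(cand_lm(), cand_ridge(0.01)), seed = 2)
  rk1 <- suppressMessages(
    ranking_experiment(pool, train_sizes = c(2, 3), repeats = 2, triples = 4,
                       space = space, seed = 9, eval_strains = 6,
                       target_points = 20)
  )
  expect_equal(nrow(rk1), 4)
  expect_true(all(rk1$success_rate >= 0 & rk1$success_rate <= 1))
  expect_true(all(rk1$top_failure_rate >= 0 & rk1$top_failure_rate <= 1))
  rk2 <- suppressMessages(
    ranking_experiment(pool, train_sizes = c(2, 3), repeats = 2, triples = 4,
                       space = space, seed = 9, eval_strains = 6,
                       target_points = 20)
  )
  expect_identical(as.data.frame(rk1), as.data.frame(rk2))
  sc <- suppressMessages(
    scaling_experiment(pool, train_sizes = c(2, 3), repeats = 2,
                       space = space, seed = 9, target_points = 20)
  )
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$rmse >= 0, na.rm = TRUE))
  expect_equal(nrow(attr(sc, "summary")), 2)
})

test_that("the random-ranking baseline recovers 1/6", {
  rb <- random_ranking_baseline(4000, seed = 3)
  expect_equal(rb$analytic, 1 / 6)
  expect_lt(abs(rb$rate - 1 / 6), 3 * rb$se)
})
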