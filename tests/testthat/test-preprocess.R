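make_series <- function(times, met_vals, prot_vals = NULL, strain = "s1") {
  df <- tibble::tibble(strain = strain, time = times)
  for (nm in names(met_vals)) df[[paste0("met:", nm)]] <- met_vals[[nm]]
  for (nm in names(prot_vals)) df[[paste0("prot:", nm)]] <- prot_vals[[nm]]
  omics_ts(df)
}

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  tt <- 0:6
  s <- make_series(tt, list(a = rep(2, 7), b = 0.3 * tt^2 + tt + 1))
  sm <- smooth_series(s, window = 7, polyorder = 2)
  expect_equal(sm[["met:a"]], rep(2, 7), tolerance = 1e-12)
  expect_equal(sm[["met:b"]], 0.3 * tt^2 + tt + 1, tolerance = 1e-10)
  expect_identical(sm$time, s$time)
  expect_error(smooth_series(s, window = 9),
               class = "pathdyn_insufficient_points_error")
  expect_error(smooth_series(s, window = 6),
               class = "pathdyn_parameter_error")
})

test_that("smoothing reduces noise around a known quadratic", {
  tt <- seq(0, 14, by = 1)
  truth <- 0.05 * (tt - 7)^2 + 2
  set.seed(11)
  worse <- 0
  for (r in 1:100) {
    noisy <- truth + rnorm(length(tt), sd = 0.1)
    noisy <- pmax(noisy, 0)
    s <- make_series(tt, list(a = noisy))
    sm <- smooth_series(s, window = 7, polyorder = 2)
    if (mean((sm[["met:a"]] - truth)^2) >= mean((noisy - truth)^2)) {
      worse <- worse + 1
    }
  }
  expect_lt(worse, 5)
})

test_that("finite differences recover linear and quadratic slopes", {
  tt <- 0:6
  s <- make_series(tt, list(lin = 3 * tt, quad = tt^2))
  d <- estimate_derivatives(s)
  expect_equal(d[["dmdt:lin"]][2:6], rep(3, 5), tolerance = 1e-12)
  expect_equal(d[["dmdt:quad"]][2:6], 2 * tt[2:6], tolerance = 1e-12)
  # one-sided first-order endpoints are retained
  expect_equal(nrow(d), 7)
  expect_equal(d[["dmdt:lin"]][1], 3, tolerance = 1e-12)
  expect_error(estimate_derivatives(
    tibble::tibble(strain = "s1", time = c(0, 0, 1), `met:a` = 1:3)
  ))
})

test_that("derivative estimates are invariant under time shifts", {
  pool <- small_pool()
  s <- pool$series[[1]]
  shifted <- s
  shifted$time <- shifted$time + 5
  d1 <- estimate_derivatives(s)
  d2 <- estimate_derivatives(omics_ts(shifted))
  expect_equal(d1[grep("^dmdt:", names(d1))], d2[grep("^dmdt:", names(d2))],
               tolerance = 1e-12)
})

test_that("smoothed derivatives track the kinetic right-hand side", {
  model <- ref_model()
  hill <- reference_hill_params()
  s <- simulate_strain(model, hill, times = seq(0, 72, length.out = 150))
  d <- estimate_derivatives(smooth_series(s))
  truth <- true_rhs_matrix(s, hill, model)
  est <- as.matrix(d[paste0("dmdt:", model$metabolites)])
  # interior points with flux well above the numerical noise floor
  j <- which(model$metabolites == "limonene")
  big <- which(abs(truth[, j]) > 0.2 * max(abs(truth[, j])))
  big <- setdiff(big, c(1, 2, 149, 150))
  rel <- abs(est[big, j] - truth[big, j]) / abs(truth[big, j])
  expect_lt(max(rel), 0.05)
})

test_that("augmentation expands 7 points to exactly the target grid", {
  pool <- small_pool()
  s <- pool$series[[1]]
  aug <- augment_series(s, target_points = 200)
  expect_equal(nrow(aug), 200)
  expect_equal(range(aug$time), range(s$time))
  expect_true(all(aug$time >= min(s$time) & aug$time <= max(s$time)))
  expect_true(all(as.matrix(aug[-(1:2)]) >= 0))
  expect_error(augment_series(s, target_points = 3),
               class = "pathdyn_invalid_request_error")
})

test_that("augmentation preserves an already-uniform grid at target = s", {
  tt <- seq(0, 12, by = 2)
  s <- make_series(tt, list(a = 1 + 0.1 * tt))
  aug <- augment_series(s, target_points = length(tt), window = 7)
  expect_equal(aug$time, tt)
})

test_that("interpolation is consistent with the original observations", {
  model <- ref_model()
  s <- simulate_strain(model, reference_hill_params(),
                       times = seq(0, 72, length.out = 150))
  aug <- augment_series(s, target_points = 300)
  for (cl in c("met:limonene", "met:mevalonate")) {
    at_orig <- approx(aug$time, aug[[cl]], xout = s$time)$y
    scale <- max(abs(s[[cl]]))
    expect_lt(max(abs(at_orig - s[[cl]])) / scale, 0.01)
  }
})

test_that("training sets stack one example per retained time point", {
  pool <- small_pool()
  train <- build_training_set(pool$series[1:2], target_points = 200)
  expect_equal(nrow(train), 400)
  expect_equal(length(pathdyn:::feature_cols(train)),
               length(ref_model()$metabolites) + length(ref_model()$proteins))
  train7 <- build_training_set(pool$series[[1]], augment = FALSE)
  expect_equal(nrow(train7), 7)
  # identical inputs give bit-identical training sets
  again <- build_training_set(pool$series[1:2], target_points = 200)
  expect_identical(train, again)
  # inconsistent species names across strains are rejected
  bad <- pool$series[[2]]
  names(bad)[names(bad) == "met:limonene"] <- "met:other"
  expect_error(build_training_set(list(pool$series[[1]], omics_ts(bad))),
               class = "pathdyn_schema_error")
})
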