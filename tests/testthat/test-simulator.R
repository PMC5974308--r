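test_that("leaky Hill profiles follow the closed form and saturate", {
  expect_equal(hill_profile(0, k_f = 2, k_m = 1, k_l = 0.5), 0.5)
  expect_equal(hill_profile(1, k_f = 2, k_m = 1, k_l = 0.5), 1.5)
  tt <- c(0, 10, 100, 1000, 10000)
  p <- hill_profile(tt, k_f = 2, k_m = 1, k_l = 0.5)
  expect_true(all(diff(p) > 0))
  expect_true(all(p < 2.5))
  expect_lt(2.5 - tail(p, 1), 1e-3)
  expect_error(hill_profile(0:3, k_f = 1, k_m = 0, k_l = 0),
               class = "pathdyn_parameter_error")
  expect_error(hill_profile(c(1, 1, 2), k_f = 1, k_m = 1, k_l = 0),
               class = "pathdyn_parameter_error")
})

test_that("zero enzyme expression and supply freezes every metabolite", {
  model <- limonene_pathway_model()
  params <- model$params
  params["v_accoa"] <- 1e-30
  frozen <- limonene_pathway_model(params)
  m0 <- setNames(c(0.5, 0.3, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05, 0.02, 0),
                 model$metabolites)
  s <- simulate_strain(frozen, flat_hill(level = 0), m0 = m0)
  mm <- pathdyn:::met_matrix(s)
  for (j in seq_len(ncol(mm))) {
    expect_equal(mm[, j], rep(m0[[j]], nrow(mm)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("limonene is a nondecreasing terminal sink", {
  s <- simulate_strain(ref_model(), reference_hill_params(),
                       times = seq(0, 72, length.out = 25))
  expect_true(all(diff(s[["met:limonene"]]) > -1e-9))
})

test_that("adaptive RK45 matches a fixed-step RK4 oracle within 0.1%", {
  model <- ref_model()
  hill <- reference_hill_params()
  times <- c(0, 72)
  s <- simulate_strain(model, hill, times = seq(0, 72, length.out = 7))
  final_adaptive <- pathdyn:::met_matrix(s)[7, ]
  # independent fixed-step RK4 at dt = 1e-3 h
  p_of_t <- function(t) setNames(hill$k_f * t / (hill$k_m + t) + hill$k_l,
                                 hill$protein)
  g <- function(t, m) model$rhs(m, p_of_t(t), model$params)
  dt <- 1e-3
  m <- default_initial_metabolites(model)
  t <- 0
  for (i in seq_len(72 / dt)) {
    k1 <- g(t, m)
    k2 <- g(t + dt / 2, m + dt / 2 * k1)
    k3 <- g(t + dt / 2, m + dt / 2 * k2)
    k4 <- g(t + dt, m + dt * k3)
    m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  rel <- abs(final_adaptive - m) / pmax(abs(m), 1e-8)
  expect_lt(max(rel), 1e-3)
})

test_that("doubling an enzyme's level doubles its flux and never less", {
  model <- ref_model()
  m <- setNames(runif(10, 0.1, 1), model$metabolites)
  p1 <- setNames(rep(0.5, 9), model$proteins)
  p2 <- p1
  p2["LS"] <- 1
  d1 <- model$rhs(m, p1, model$params)
  d2 <- model$rhs(m, p2, model$params)
  # limonene production rate is linear in LS
  expect_equal(d2[["limonene"]], 2 * d1[["limonene"]], tolerance = 1e-12)
  expect_gte(d2[["limonene"]], d1[["limonene"]])
})

test_that("virtual strain pools are reproducible and positive", {
  model <- ref_model()
  p1 <- generate_pool(model, 3, seed = 5)
  p2 <- generate_pool(model, 3, seed = 5)
  expect_identical(p1$strains$hill, p2$strains$hill)
  expect_identical(p1$series, p2$series)
  p3 <- generate_pool(model, 1, seed = 6)
  expect_false(identical(p1$strains$hill[[1]], p3$strains$hill[[1]]))
  vals <- unlist(lapply(p1$series, function(s) pathdyn:::met_matrix(s)))
  expect_true(all(vals >= 0))
  expect_equal(nrow(p1$strains), 3)
  expect_equal(p1$strains$final_product,
               unname(vapply(p1$series,
                             function(s) tail(s[["met:limonene"]], 1),
                             numeric(1))))
})

test_that("hill coefficients are drawn inside the sampling ranges", {
  pool <- small_pool()
  rng <- default_hill_ranges()
  for (h in pool$strains$hill) {
    for (cf in rng$coefficient) {
      expect_true(all(h[[cf]] >= rng$lower[rng$coefficient == cf]))
      expect_true(all(h[[cf]] <= rng$upper[rng$coefficient == cf]))
    }
  }
})
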