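# A noise-free linear system: derivatives are an exact linear map of the
# concatenated (m, p) features, split across several pseudo-strains.
make_linear_training <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * 5, 0, 2), n, 5)
    A <- matrix(rnorm(15), 5, 3)
    Y <- X %*% A
    tibble::tibble(
      strain = rep(paste0("s", 1:4), each = n / 4),
      time = rep(seq_len(n / 4), 4),
      `met:a` = X[, 1], `met:b` = X[, 2], `met:c` = X[, 3],
      `prot:P1` = X[, 4], `prot:P2` = X[, 5],
      `dmdt:a` = Y[, 1], `dmdt:b` = Y[, 2], `dmdt:c` = Y[, 3]
    )
  })
}

test_that("a single-candidate space returns that candidate refit on all rows", {
  train <- make_linear_training()
  sm <- select_model(train, "a", search_space(list(cand_ridge(0.01)), seed = 1))
  expect_equal(sm$candidate_id, "ridge(0.01)")
  expect_equal(nrow(sm$scores), 1)
})

test_that("the linear family recovers exact linear dynamics", {
  train <- make_linear_training()
  sm <- select_model(train, "b",
                     search_space(list(cand_lm(), cand_knn(5)), seed = 1))
  expect_equal(sm$candidate_id, "lm")
  expect_lt(sm$cv_rmse, 1e-6)
})

test_that("the generative family wins model selection across seeds", {
  wins <- 0
  for (seed in 1:10) {
    train <- make_linear_training(seed = seed + 100)
    sm <- select_model(train, "a",
                       search_space(list(cand_knn(5), cand_lm()),
                                    seed = seed))
    if (sm$candidate_id == "lm") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("cross-validation folds never split a strain across fold sides", {
  train <- make_linear_training()
  ids <- pathdyn:::fold_ids(train$strain, folds = 10, seed = 3)
  expect_equal(length(unique(tapply(ids, train$strain,
                                    function(x) length(unique(x))))), 1)
  expect_true(all(tapply(ids, train$strain,
                         function(x) length(unique(x))) == 1))
})

test_that("enlarging the search space never worsens the winning CV score", {
  train <- make_linear_training()
  small <- search_space(list(cand_knn(5)), seed = 4)
  big <- search_space(list(cand_knn(5), cand_lm(), cand_ridge(0.01)),
                      seed = 4)
  s1 <- select_model(train, "c", small)
  s2 <- select_model(train, "c", big)
  expect_lte(s2$cv_rmse, s1$cv_rmse)
})

test_that("fit_dynamics builds one sub-model per metabolite, deterministically", {
  pool <- small_pool()
  train <- build_training_set(pool$series[1:3], target_points = 30)
  space <- search_space(list(cand_lm(), cand_ridge(0.01)), seed = 2)
  m1 <- suppressMessages(fit_dynamics(train, space))
  m2 <- suppressMessages(fit_dynamics(train, space))
  expect_equal(length(m1$sub_models), 10)
  expect_identical(tidy(m1), tidy(m2))
  expect_equal(glance(m1)$n_metabolites, 10)
  pred <- predict(m1, pathdyn:::feature_matrix(train))
  expect_equal(dim(pred), c(nrow(train), 10))
  expect_true(all(is.finite(pred)))
})

test_that("all-zero derivative targets produce a near-zero field", {
  train <- make_linear_training()
  for (cl in grep("^dmdt:", names(train), value = TRUE)) train[[cl]] <- 0
  model <- suppressMessages(
    fit_dynamics(train, search_space(list(cand_lm()), seed = 1))
  )
  pred <- predict(model, pathdyn:::feature_matrix(train))
  expect_lt(max(abs(pred)), 1e-10)
})

test_that("empty search spaces are rejected", {
  expect_error(search_space(list()), class = "pathdyn_configuration_error")
})

test_that("shuffle-split assessment reports one row per metabolite and split", {
  train <- make_linear_training()
  model <- suppressMessages(
    fit_dynamics(train, search_space(list(cand_lm()), seed = 1))
  )
  tab <- assess_derivative_fit(model, train, repeats = 10, seed = 2)
  expect_equal(nrow(tab), 30)
  expect_equal(sort(unique(tab$split)), 1:10)
  # noise-free linear system: near-perfect generalisation
  expect_true(all(tab$test_r2 > 0.99))
  # a memorising regressor scores perfectly on its own training split
  knn_model <- suppressMessages(
    fit_dynamics(train, search_space(list(cand_knn(1)), seed = 1))
  )
  tab1 <- assess_derivative_fit(knn_model, train, repeats = 2, seed = 2)
  expect_true(all(tab1$train_r2 > 1 - 1e-9))
})
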