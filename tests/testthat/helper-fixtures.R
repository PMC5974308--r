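# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from the reference kinetic model; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ref_model <- function() fixture("model", limonene_pathway_model)

# Small pool on the experimental 7-point layout, for unit tests.
small_pool <- function() {
  fixture("small_pool", function() {
    generate_pool(ref_model(), 12, seed = 7)
  })
}

# A quick dynamics model (linear/ridge families only) for plumbing tests.
quick_dynamics_model <- function() {
  fixture("quick_model", function() {
    pool <- small_pool()
    train <- build_training_set(pool$series[1:3], target_points = 30)
    suppressMessages(fit_dynamics(
      train, search_space(list(cand_lm(), cand_ridge(0.01)), seed = 2)
    ))
  })
}

# Large pool shared by the ranking and error-scaling experiments.
experiment_pool <- function() {
  fixture("experiment_pool", function() {
    generate_pool(ref_model(), 300, seed = 101)
  })
}

# Hill parameter table with every protein at the same constant level.
flat_hill <- function(level = 0, k_m = 1) {
  tibble::tibble(protein = ref_model()$proteins, k_f = 0, k_m = k_m,
                 k_l = level)
}

# True right-hand side evaluated along a strain's (m, p) table.
true_rhs_matrix <- function(series, hill, model = ref_model()) {
  mm <- pathdyn:::met_matrix(series)
  t(vapply(seq_len(nrow(series)), function(i) {
    p <- setNames(hill$k_f * series$time[i] / (hill$k_m + series$time[i]) +
                    hill$k_l, hill$protein)
    model$rhs(mm[i, ], p, model$params)
  }, numeric(length(model$metabolites))))
}

# Relative L2 trajectory error of one metabolite on a dense common grid.
relative_l2 <- function(predicted, reference, metabolite,
                        grid_points = 601) {
  cg <- pathdyn:::common_grid(predicted, reference, grid_points)
  j <- which(cg$mets == metabolite)
  sqrt(pracma::trapz(cg$grid, (cg$ref[, j] - cg$pred[, j])^2) /
         pracma::trapz(cg$grid, cg$ref[, j]^2))
}
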