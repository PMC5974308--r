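as_met_table <- function(x) {
  d <- if (inherits(x, "trajectory_prediction")) x$data else as_tibble(x)
  d[c("time", grep("^met:", names(d), value = TRUE))]
}

# Interpolate both tables onto a common dense grid over the overlapping span.
common_grid <- function(predicted, reference, grid_points) {
  pd <- as_met_table(predicted)
  rd <- as_met_table(reference)
  mets <- intersect(names(pd), names(rd))
  mets <- grep("^met:", mets, value = TRUE)
  if (length(mets) == 0) {
    abort("No shared metabolites between prediction and reference.",
          class = "pathdyn_incompatibility_error")
  }
  t0 <- max(min(pd$time), min(rd$time))
  tf <- min(max(pd$time), max(rd$time))
  if (tf <= t0) {
    abort("Prediction and reference spans do not overlap.",
          class = "pathdyn_incompatibility_error")
  }
  grid <- seq(t0, tf, length.out = grid_points)
  interp <- function(d) {
    vapply(mets, function(cl) splinefun(d$time, d[[cl]], method = "fmm")(grid),
           numeric(grid_points))
  }
  list(grid = grid, mets = sub("^met:", "", mets),
       pred = interp(pd), ref = interp(rd))
}

#' Trajectory root-mean-squared error
#'
#' Computes the continuous-time trajectory RMSE
#' `sqrt((1/n) * sum_j integral_[t0,tf] (mbar_j(t) - m_j(t))^2 dt)`,
#' where `mbar_j` interpolates the reference series and `m_j` the
#' prediction; the integral is evaluated by the trapezoid rule on a common
#' dense grid over the overlapping time span. Per-metabolite components
#' `sqrt(integral_j)` are returned alongside the total. For a constant
#' offset `c` on every metabolite the total reduces to `c * sqrt(tf - t0)`.
#'
#' @param predicted A `trajectory_prediction` or [omics_ts()] tibble.
#' @param reference The reference [omics_ts()] series.
#' @param grid_points Density of the common evaluation grid.
#' @return A list with `total` (scalar RMSE) and `per_metabolite` (tibble
#'   `metabolite`, `rmse`).
#' @export
trajectory_rmse <- function(predicted, reference, grid_points = 601) {
  cg <- common_grid(predicted, reference, grid_points)
  integrals <- vapply(seq_along(cg$mets), function(j) {
    pracma::trapz(cg$grid, (cg$ref[, j] - cg$pred[, j])^2)
  }, numeric(1))
  list(total = sqrt(mean(integrals)),
       per_metabolite = tibble(metabolite = cg$mets, rmse = sqrt(integrals)))
}

#' Time-averaged percent error per metabolite
#'
#' For every metabolite, the time average of the absolute prediction error
#' is divided by the time average of the absolute reference concentration
#' and expressed in percent (both averages over the overlapping span, by
#' the trapezoid rule on a common dense grid). A prediction equal to twice
#' the reference everywhere therefore scores 100%. Metabolites whose
#' reference is identically zero are flagged undefined and excluded from
#' the average.
#'
#' @inheritParams trajectory_rmse
#' @return A tibble `metabolite`, `percent_error`, `defined`, with the mean
#'   over defined metabolites in attribute `"average"`.
#' @export
percent_error <- function(predicted, reference, grid_points = 601) {
  cg <- common_grid(predicted, reference, grid_points)
  dt <- diff(range(cg$grid))
  out <- list_rbind(lapply(seq_along(cg$mets), function(j) {
    ref_mag <- pracma::trapz(cg$grid, abs(cg$ref[, j])) / dt
    err_mag <- pracma::trapz(cg$grid, abs(cg$ref[, j] - cg$pred[, j])) / dt
    defined <- ref_mag > 1e-12
    tibble(metabolite = cg$mets[j],
           percent_error = if (defined) 100 * err_mag / ref_mag else NA_real_,
           defined = defined)
  }))
  attr(out, "average") <- mean(out$percent_error[out$defined])
  out
}

#' Full-order success probability of a random ranking
#'
#' Monte-Carlo estimate of the probability that a uniformly random ordering
#' of a strain triple matches the true production order; the analytic value
#' is `1/6` (one of `3!` permutations).
#'
#' @param n_triples Number of simulated triples.
#' @param seed Integer seed.
#' @return A list with the Monte-Carlo `rate`, its standard error `se`,
#'   the `analytic` value `1/6`, and `n_triples`.
#' @export
random_ranking_baseline <- function(n_triples = 10000, seed = 1) {
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_triples), function(i) {
      all(sample.int(3) == 1:3)
    }, logical(1)))
  })
  rate <- hits / n_triples
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_triples),
       analytic = 1 / 6, n_triples = n_triples)
}

# Fit a dynamics model on `train_ids` drawn from the pool and predict the
# final product of each strain in `eval_ids`. Divergent or failed
# integrations yield NA (scored as a ranking failure by callers).
pool_fit <- function(pool, train_ids, space, target_points, window, polyorder) {
  train <- build_training_set(pool$series[train_ids],
                              target_points = target_points,
                              window = window, polyorder = polyorder)
  fit_dynamics(train, space)
}

pool_predict_finals <- function(model, pool, eval_ids, rtol = 1e-3,
                                atol = 1e-6) {
  vapply(eval_ids, function(id) {
    tryCatch(final_product(predict_trajectory(model, pool$series[[id]],
                                              rtol = rtol, atol = atol)),
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Production-ranking experiment on a virtual strain pool
#'
#' Measures how reliably a dynamics model trained on a few strains predicts
#' the relative production ranking of strain triples (highest, medium,
#' lowest producer), as a function of training-set size. For every size and
#' repeat, training strains are sampled from the pool, the per-metabolite
#' regressors are fitted, and random triples disjoint from the training set
#' are ranked by the predicted final product obtained from integrating the
#' learned dynamics. A triple scores a success only when all three strains
#' are ordered correctly (a random ranker succeeds with probability 1/6);
#' the failure rate for the predicted top producer is reported as well.
#'
#' To keep the number of trajectory integrations proportional to
#' `eval_strains` rather than `3 * triples`, each repeat samples
#' `eval_strains` candidate strains, predicts each once, and draws the
#' triples from that candidate set.
#'
#' @param pool A [generate_pool()] object.
#' @param train_sizes Training-set sizes to compare.
#' @param repeats Training-set draws per size.
#' @param triples Random triples scored per repeat.
#' @param space A [search_space()] (the compact space by default).
#' @param seed Integer seed.
#' @param eval_strains Held-out candidate strains predicted per repeat.
#' @param target_points,window,polyorder Preprocessing settings for the
#'   training sets.
#' @param rtol,atol Integrator tolerances used for the experiment's many
#'   trajectory predictions (looser than the single-prediction default;
#'   the effect on predicted final product is well below the strain-to-
#'   strain spread).
#' @return A `ranking_experiment` tibble (`train_size`, `rep`,
#'   `success_rate`, `top_failure_rate`) with a per-size summary in
#'   attribute `"summary"`.
#' @export
ranking_experiment <- function(pool, train_sizes = c(2, 10), repeats = 10,
                               triples = 20, space = compact_search_space(),
                               seed = 1, eval_strains = 12,
                               target_points = 50, window = 7, polyorder = 2,
                               rtol = 1e-3, atol = 1e-6) {
  stopifnot(nrow(pool$strains) >= max(train_sizes) + 3)
  ids <- pool$strains$strain
  truth <- setNames(pool$strains$final_product, ids)
  draws <- withr::with_seed(seed, {
    lapply(train_sizes, function(size) {
      lapply(seq_len(repeats), function(r) {
        train_ids <- sample(ids, size)
        cand_ids <- sample(setdiff(ids, train_ids),
                           min(eval_strains, length(ids) - size))
        trip <- replicate(triples, sample(cand_ids, 3), simplify = FALSE)
        list(train = train_ids, cand = cand_ids, triples = trip)
      })
    })
  })
  rows <- list()
  for (i in seq_along(train_sizes)) {
    for (r in seq_len(repeats)) {
      d <- draws[[i]][[r]]
      sp <- space
      sp$seed <- space$seed + 1000 * i + r
      model <- pool_fit(pool, d$train, sp, target_points, window, polyorder)
      finals <- pool_predict_finals(model, pool, d$cand, rtol = rtol,
                                    atol = atol)
      score <- vapply(d$triples, function(tr) {
        pred <- finals[tr]
        if (anyNA(pred)) return(c(success = 0, top_fail = 1))
        c(success = as.numeric(identical(order(pred), order(truth[tr]))),
          top_fail = as.numeric(which.max(pred) != which.max(truth[tr])))
      }, numeric(2))
      rows[[length(rows) + 1]] <- tibble(
        train_size = train_sizes[i], rep = r,
        success_rate = mean(score["success", ]),
        top_failure_rate = mean(score["top_fail", ])
      )
    }
  }
  out <- bind_rows(rows)
  summ <- out |>
    group_by(.data$train_size) |>
    summarise(mean_success = mean(.data$success_rate),
              sd_success = sd(.data$success_rate),
              mean_top_failure = mean(.data$top_failure_rate),
              .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("ranking_experiment", class(out))
  out
}

#' Prediction-error scaling experiment
#'
#' Quantifies how the continuous-time trajectory RMSE on a fixed held-out
#' strain shrinks as the training set grows. For every training-set size
#' and repeat, strains are sampled from the pool (never the held-out
#' strain), the dynamics model is fitted, the held-out strain's trajectory
#' is predicted from its protein series and initial state, and the total
#' RMSE against the simulated reference is recorded. Both the mean RMSE and
#' its spread across repeats are expected to shrink with training-set size.
#'
#' @inheritParams ranking_experiment
#' @param heldout Strain id evaluated in every repeat (defaults to the last
#'   pool strain). Failed integrations yield `NA`.
#' @param rtol,atol Integrator tolerances for the repeated predictions.
#' @return A `scaling_experiment` tibble (`train_size`, `rep`, `rmse`) with
#'   a per-size mean/sd summary in attribute `"summary"`.
#' @export
scaling_experiment <- function(pool, train_sizes = c(2, 10), repeats = 10,
                               space = compact_search_space(), seed = 1,
                               heldout = NULL, target_points = 50,
                               window = 7, polyorder = 2,
                               rtol = 1e-3, atol = 1e-6) {
  ids <- pool$strains$strain
  heldout <- heldout %||% tail(ids, 1)
  avail <- setdiff(ids, heldout)
  stopifnot(length(avail) >= max(train_sizes))
  draws <- withr::with_seed(seed, {
    lapply(train_sizes, function(size) {
      lapply(seq_len(repeats), function(r) sample(avail, size))
    })
  })
  ref <- pool$series[[heldout]]
  rows <- list()
  for (i in seq_along(train_sizes)) {
    for (r in seq_len(repeats)) {
      sp <- space
      sp$seed <- space$seed + 1000 * i + r
      model <- pool_fit(pool, draws[[i]][[r]], sp, target_points, window,
                        polyorder)
      rmse <- tryCatch(
        trajectory_rmse(predict_trajectory(model, ref, rtol = rtol,
                                           atol = atol), ref)$total,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1]] <- tibble(train_size = train_sizes[i],
                                         rep = r, rmse = rmse)
    }
  }
  out <- bind_rows(rows)
  summ <- out |>
    group_by(.data$train_size) |>
    summarise(mean_rmse = mean(.data$rmse, na.rm = TRUE),
              sd_rmse = sd(.data$rmse, na.rm = TRUE),
              n_failed = sum(is.na(.data$rmse)),
              .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("scaling_experiment", class(out))
  out
}

#' @method tidy ranking_experiment
#' @export
tidy.ranking_experiment <- function(x, ...) attr(x, "summary")

#' @method tidy scaling_experiment
#' @export
tidy.scaling_experiment <- function(x, ...) attr(x, "summary")
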