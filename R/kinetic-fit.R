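# Simulate the kinetic model at `params` driving it with an observed
# protein series (interpolated), rather than Hill profiles. Used when
# fitting kinetic constants to strain data.
simulate_with_proteins <- function(model, params, series, rtol = 1e-6,
                                   atol = 1e-9) {
  series <- as_omics_ts(series)
  p_of_t <- interpolate_proteins(series)
  m0 <- met_matrix(series)[1, model$metabolites]
  integrate_rhs(function(t, m) model$rhs(m, p_of_t(t), params),
                m0, series$time, rtol = rtol, atol = atol)
}

# Sum of squared deviations between simulated and observed metabolite
# trajectories, over all strains and observed time points. Failed
# simulations receive a large finite penalty so the optimizer can continue.
kinetic_objective <- function(model, params, strains, penalty = 1e12) {
  total <- 0
  for (s in strains) {
    sim <- tryCatch(simulate_with_proteins(model, params, s),
                    error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim))) return(penalty)
    total <- total + sum((sim - met_matrix(s)[, model$metabolites])^2)
  }
  total
}

# Plain rand/1/bin differential evolution on a box, minimising `fn`, with
# per-generation dithering of the mutation weight (drawn uniformly from
# [f_weight/2, f_weight * 1.25]) to slow premature population collapse.
# Returns the best point, its value and the per-generation best trace.
de_optimize <- function(fn, lower, upper, pop_size = 30, generations = 60,
                        f_weight = 0.8, crossover = 0.9, seed = 1) {
  d <- length(lower)
  withr::with_seed(seed, {
    pop <- matrix(runif(pop_size * d, lower, upper), nrow = pop_size,
                  byrow = TRUE)
    vals <- apply(pop, 1, fn)
    trace <- numeric(generations + 1)
    trace[1] <- min(vals)
    if (generations > 0) {
      for (g in seq_len(generations)) {
        fw <- runif(1, f_weight / 2, f_weight * 1.25)
        for (i in seq_len(pop_size)) {
          idx <- sample(setdiff(seq_len(pop_size), i), 3)
          trial <- pop[idx[1], ] + fw * (pop[idx[2], ] - pop[idx[3], ])
          cross <- runif(d) < crossover
          cross[sample.int(d, 1)] <- TRUE
          trial <- ifelse(cross, trial, pop[i, ])
          trial <- pmin(pmax(trial, lower), upper)
          v <- fn(trial)
          if (v <= vals[i]) {
            pop[i, ] <- trial
            vals[i] <- v
          }
        }
        trace[g + 1] <- min(vals)
      }
    }
    best <- which.min(vals)
    list(par = pop[best, ], value = vals[best], trace = trace)
  })
}

#' Fit the kinetic model's constants to strain data
#'
#' Baseline comparator for the learned dynamics: the kinetic constants of
#' the Michaelis-Menten model are fitted to one or more strains' observed
#' time series by minimising the summed squared deviation between simulated
#' and observed metabolite trajectories. The search uses a
#' differential-evolution population optimizer (rand/1/bin) over the
#' parameter box, followed by an optional local polish (L-BFGS-B) of the
#' population best. Because the default box spans 21 decades
#' (`1e-12`-`1e9`), parameters are sampled and evolved in log10 space.
#' Constants whose lower and upper bounds coincide are held fixed.
#' Candidate parameter sets whose simulation diverges receive a large
#' finite penalty rather than aborting the run.
#'
#' @param model A `kinetic_model`.
#' @param strains A single [omics_ts()] or list of them (the training
#'   strains); protein inputs are interpolated from the observed series.
#' @param bounds Tibble `parameter`, `lower`, `upper` (defaults to
#'   [kinetic_bounds()], i.e. `[1e-12, 1e9]` for every constant).
#' @param control List overriding `pop_size`, `generations`, `f_weight`,
#'   `crossover`, `polish`.
#' @param seed Integer seed (fit is deterministic under a fixed seed).
#' @return A `fit_result`: best-fit `params`, `objective`, per-generation
#'   `trace`, `converged` flag, the `bounds` used and the `model`.
#' @export
fit_kinetic_model <- function(model, strains, bounds = kinetic_bounds(model),
                              control = list(), seed = 1) {
  if (is.data.frame(strains)) strains <- list(strains)
  strains <- lapply(strains, as_omics_ts)
  stopifnot(length(strains) >= 1)
  ctl <- modifyList(list(pop_size = 30, generations = 60, f_weight = 0.8,
                         crossover = 0.9, polish = TRUE), control)
  bounds <- as_tibble(bounds)
  if (!setequal(bounds$parameter, names(model$params))) {
    abort("`bounds` must cover exactly the model's kinetic constants.",
          class = "pathdyn_parameter_error")
  }
  bounds <- bounds[match(names(model$params), bounds$parameter), ]
  if (any(bounds$lower <= 0) || any(bounds$lower > bounds$upper)) {
    abort("Bounds must be positive with lower <= upper.",
          class = "pathdyn_parameter_error")
  }
  free <- which(bounds$lower < bounds$upper)
  fixed_params <- setNames(bounds$lower, bounds$parameter)
  to_params <- function(theta) {
    q <- fixed_params
    q[free] <- 10^theta
    q
  }
  fn <- function(theta) kinetic_objective(model, to_params(theta), strains)
  if (length(free) == 0) {
    val <- kinetic_objective(model, fixed_params, strains)
    de <- list(par = numeric(0), value = val, trace = val)
  } else {
    de <- de_optimize(fn, log10(bounds$lower[free]), log10(bounds$upper[free]),
                      pop_size = ctl$pop_size, generations = ctl$generations,
                      f_weight = ctl$f_weight, crossover = ctl$crossover,
                      seed = seed)
    if (isTRUE(ctl$polish) && de$value < 1e12) {
      lo <- log10(bounds$lower[free])
      hi <- log10(bounds$upper[free])
      fn_boxed <- function(theta) fn(pmin(pmax(theta, lo), hi))
      # Nelder-Mead first: the SSR landscape often has narrow curved
      # valleys (compensating constants) where finite-difference
      # quasi-Newton line searches stall; follow with L-BFGS-B to sharpen.
      pol <- tryCatch({
        nm <- optim(de$par, fn_boxed, method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-12))
        start <- pmin(pmax(nm$par, lo), hi)
        lb <- optim(start, fn, method = "L-BFGS-B", lower = lo, upper = hi)
        if (lb$value <= nm$value) lb else list(par = start, value = nm$value)
      }, error = function(e) NULL)
      if (!is.null(pol) && pol$value <= de$value) {
        de$par <- pmin(pmax(pol$par, lo), hi)
        de$value <- pol$value
        de$trace <- c(de$trace, pol$value)
      }
    }
  }
  if (de$value >= 1e12) {
    abort("All candidate simulations diverged; kinetic fit failed.",
          class = "pathdyn_fit_error")
  }
  structure(
    list(params = to_params(de$par), objective = de$value,
         trace = tibble(generation = seq_along(de$trace) - 1,
                        best_objective = de$trace),
         converged = is.finite(de$value), bounds = bounds, model = model,
         seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective ", signif(x$objective, 6), " after ",
      max(x$trace$generation), " generations\n", sep = "")
  invisible(x)
}

#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) {
  tibble(parameter = names(x$params), value = unname(x$params),
         lower = x$bounds$lower, upper = x$bounds$upper,
         fixed = x$bounds$lower == x$bounds$upper)
}

#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble(objective = x$objective, generations = max(x$trace$generation),
         converged = x$converged, seed = x$seed)
}

#' Compare the learned dynamics with the fitted kinetic model
#'
#' Evaluates both predictors on the same held-out strain: the learned
#' dynamics model predicts the trajectory from the strain's protein series
#' and initial state, the fitted kinetic model simulates it with its
#' best-fit constants, and both are scored by trajectory RMSE and average
#' percent error against the observations.
#'
#' @param ml_model A fitted `dynamics_model`.
#' @param fit A [fit_kinetic_model()] result.
#' @param test_strain The held-out [omics_ts()] series.
#' @return A tibble with one row per predictor (`ml`, `kinetic`) and
#'   columns `total_rmse`, `avg_percent_error`.
#' @export
compare_ml_vs_kinetic <- function(ml_model, fit, test_strain) {
  test_strain <- as_omics_ts(test_strain)
  ml_pred <- predict_trajectory(ml_model, test_strain)
  kin <- simulate_with_proteins(fit$model, fit$params, test_strain)
  colnames(kin) <- paste0("met:", fit$model$metabolites)
  kin_pred <- bind_cols(tibble(time = test_strain$time),
                        as_tibble(pmax(kin, 0)))
  score <- function(pred) {
    tibble(total_rmse = trajectory_rmse(pred, test_strain)$total,
           avg_percent_error = attr(percent_error(pred, test_strain), "average"))
  }
  bind_rows(ml = score(ml_pred), kinetic = score(kin_pred), .id = "predictor")
}
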