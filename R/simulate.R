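#' Simulate one virtual strain's multiomics time series
#'
#' Integrates the kinetic model with adaptive Runge-Kutta 45
#' (Dormand-Prince, via deSolve) from `t = times[1]` to `t = max(times)`,
#' with each enzyme's concentration following its leaky Hill expression
#' profile, and samples metabolite and protein concentrations at the
#' requested observation times (by default 7 evenly spaced points over a
#' 72 h fermentation, mimicking the experimental layout).
#'
#' @param model A `kinetic_model`, see [limonene_pathway_model()].
#' @param hill_params Tibble with columns `protein`, `k_f`, `k_m`, `k_l`,
#'   one row per model enzyme.
#' @param m0 Named nonnegative initial metabolite vector (defaults to the
#'   reference initial state).
#' @param times Observation grid in hours, strictly increasing.
#' @param strain_id Label stored in the output `strain` column.
#' @param rtol,atol Integrator tolerances.
#' @param clip Clip reported metabolite concentrations at zero (tiny
#'   adaptive-step undershoot); the right-hand side always evaluates fluxes
#'   on the zero-clipped state regardless.
#' @return An [omics_ts()] tibble with `met:` and `prot:` columns.
#' @export
simulate_strain <- function(model, hill_params = reference_hill_params(),
                            m0 = default_initial_metabolites(model),
                            times = seq(0, 72, length.out = 7),
                            strain_id = "strain_1",
                            rtol = 1e-6, atol = 1e-9, clip = TRUE) {
  stopifnot(inherits(model, "kinetic_model"))
  hill_params <- validate_hill_params(hill_params, model$proteins)
  m0 <- m0[model$metabolites]
  if (anyNA(m0) || any(m0 < 0)) {
    abort("`m0` must be a nonnegative vector covering all model metabolites.",
          class = "pathdyn_parameter_error")
  }
  p_of_t <- function(t) {
    setNames(hill_params$k_f * t / (hill_params$k_m + t) + hill_params$k_l,
             hill_params$protein)
  }
  mm <- integrate_rhs(
    function(t, m) model$rhs(m, p_of_t(t), model$params),
    m0, times, rtol = rtol, atol = atol
  )
  if (clip) mm <- pmax(mm, 0)
  colnames(mm) <- paste0("met:", model$metabolites)
  pp <- hill_matrix(hill_params, times)
  colnames(pp) <- paste0("prot:", colnames(pp))
  omics_ts(bind_cols(tibble(strain = strain_id, time = times),
                     as_tibble(mm), as_tibble(pp)))
}

# Adaptive RK45 integration of dm/dt = g(t, m); returns the state matrix at
# `times`. Failures (step-size underflow, non-finite states) raise a
# simulation error naming the last time reached.
integrate_rhs <- function(g, m0, times, rtol = 1e-6, atol = 1e-9) {
  fn <- function(t, y, parms) list(unname(g(t, y)))
  sol <- suppressWarnings(
    deSolve::ode(y = m0, times = times, func = fn, parms = NULL,
                 method = "ode45", rtol = rtol, atol = atol)
  )
  mm <- unclass(sol)[, -1, drop = FALSE]
  ok <- stats::complete.cases(mm) & apply(is.finite(mm), 1, all)
  if (nrow(mm) < length(times) || !all(ok)) {
    t_fail <- if (any(ok)) max(times[seq_len(nrow(mm))][ok]) else times[1]
    abort(paste0("Integration failed after t = ", signif(t_fail, 6), " h."),
          class = "pathdyn_simulation_error")
  }
  mm
}

#' Generate a pool of virtual strains
#'
#' Creates `pool_size` virtual strains that share the model's kinetic
#' constants but differ in their protein expression profiles: for every
#' enzyme, the three leaky-Hill coefficients (`k_f`, `k_m`, `k_l`) are
#' drawn independently and log-uniformly from `sampling_ranges`. Each
#' strain's multiomics time series is simulated with [simulate_strain()]
#' and its final product (limonene at the last observation time) recorded
#' for ranking experiments. Reproducible under a fixed seed.
#'
#' @inheritParams simulate_strain
#' @param pool_size Number of strains, `>= 1`.
#' @param sampling_ranges Tibble with columns `coefficient` (`k_f`, `k_m`,
#'   `k_l`), `lower`, `upper`; all positive.
#' @param seed Integer seed controlling coefficient draws.
#' @return A `strain_pool` object: tibble `strains` (columns `strain`,
#'   `final_product`, list-column `hill`), named list `series` of
#'   [omics_ts()] tables, plus the shared model, grid and seed.
#' @export
generate_pool <- function(model, pool_size,
                          sampling_ranges = default_hill_ranges(),
                          seed = 1,
                          m0 = default_initial_metabolites(model),
                          times = seq(0, 72, length.out = 7), ...) {
  stopifnot(pool_size >= 1, all(sampling_ranges$lower > 0),
            all(sampling_ranges$upper >= sampling_ranges$lower))
  rng <- setNames(
    lapply(seq_len(nrow(sampling_ranges)),
           function(i) c(sampling_ranges$lower[i], sampling_ranges$upper[i])),
    sampling_ranges$coefficient
  )
  product_col <- paste0("met:", tail(model$metabolites, 1))
  withr::with_seed(seed, {
    hills <- lapply(seq_len(pool_size), function(i) {
      tibble(
        protein = model$proteins,
        k_f = loguniform(length(model$proteins), rng$k_f),
        k_m = loguniform(length(model$proteins), rng$k_m),
        k_l = loguniform(length(model$proteins), rng$k_l)
      )
    })
  })
  ids <- sprintf("strain_%04d", seq_len(pool_size))
  series <- map2(hills, ids, function(h, id) {
    simulate_strain(model, h, m0 = m0, times = times, strain_id = id, ...)
  })
  names(series) <- ids
  structure(
    list(
      strains = tibble(
        strain = ids,
        final_product = unname(map_dbl(series, ~ tail(.x[[product_col]], 1))),
        hill = hills
      ),
      series = series, model = model, times = times, m0 = m0, seed = seed
    ),
    class = "strain_pool"
  )
}

loguniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' @export
print.strain_pool <- function(x, ...) {
  cat("<strain_pool> ", nrow(x$strains), " strains, final product ",
      signif(min(x$strains$final_product), 3), "-",
      signif(max(x$strains$final_product), 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy strain_pool
#' @export
tidy.strain_pool <- function(x, ...) {
  x$strains[c("strain", "final_product")]
}

# Stack several pool strains into one multi-strain omics_ts.
pool_series <- function(pool, strains) {
  omics_ts(bind_rows(pool$series[strains]))
}
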