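#' Continuous protein interpolant
#'
#' Builds a continuous evaluator `p(t)` from a strain's observed protein
#' time series by per-protein cubic-spline interpolation clipped at zero
#' (the same scheme used for data augmentation). The adaptive integrator
#' queries protein concentrations at arbitrary interior times, so the
#' evaluator is defined on the observed span only; queries outside it raise
#' an extrapolation error.
#'
#' @param series An [omics_ts()] tibble for a single strain with at least 2
#'   time points and at least one `prot:` column.
#' @return A function `p(t)` returning the named protein vector at time
#'   `t`, with attributes `span` and `proteins`.
#' @export
interpolate_proteins <- function(series) {
  series <- as_omics_ts(series)
  stopifnot(length(unique(series$strain)) == 1)
  if (nrow(series) < 2) {
    abort("Need at least 2 time points to interpolate proteins.",
          class = "pathdyn_parameter_error")
  }
  prots <- prot_names(series)
  if (length(prots) == 0) {
    abort("Series has no protein columns.", class = "pathdyn_schema_error")
  }
  span <- range(series$time)
  funs <- lapply(prot_cols(series), function(cl) {
    splinefun(series$time, series[[cl]], method = "fmm")
  })
  names(funs) <- prots
  out <- function(t) {
    if (t < span[1] - 1e-9 || t > span[2] + 1e-9) {
      abort(paste0("Protein series cannot be evaluated at t = ", t,
                   " (span ", span[1], "-", span[2], " h)."),
            class = "pathdyn_extrapolation_error")
    }
    vapply(funs, function(f) max(f(t), 0), numeric(1))
  }
  attr(out, "span") <- span
  attr(out, "proteins") <- prots
  out
}

#' Predict metabolite trajectories with a learned dynamics model
#'
#' Solves the initial value problem `dm/dt = f(m, p(t))`, `m(t0) = m0`,
#' where `f` is the learned vector field and `p(t)` interpolates the
#' strain's protein time series, using adaptive Runge-Kutta 45. The state
#' passed to `f` is clipped at zero (learned regressors are unconstrained),
#' and integration aborts with a divergence error if any metabolite exceeds
#' `ceiling_factor` times its training-data maximum.
#'
#' @param model A fitted `dynamics_model`.
#' @param proteins A single-strain [omics_ts()] protein series, or an
#'   evaluator from [interpolate_proteins()].
#' @param m0 Named initial metabolite vector (defaults to the first
#'   observed row when `proteins` is a series carrying `met:` columns).
#' @param times Output grid, inside the protein series span.
#' @param rtol,atol Integrator tolerances.
#' @param clip Clip the state at zero during integration and in the output.
#' @param ceiling_factor Divergence ceiling multiplier.
#' @return A `trajectory_prediction`: tibble `data` (time + `met:` columns),
#'   `strain`, and integrator `diagnostics` (RHS evaluations, clip events).
#' @export
predict_trajectory <- function(model, proteins, m0 = NULL, times = NULL,
                               rtol = 1e-6, atol = 1e-9, clip = TRUE,
                               ceiling_factor = 1e6) {
  stopifnot(inherits(model, "dynamics_model"))
  strain_id <- "prediction"
  if (!is.function(proteins)) {
    series <- as_omics_ts(proteins)
    strain_id <- series$strain[1]
    if (is.null(m0) && length(met_cols(series)) > 0) {
      m0 <- met_matrix(series)[1, ]
    }
    if (is.null(times)) times <- series$time
    proteins <- interpolate_proteins(series)
  }
  if (is.null(m0) || is.null(times)) {
    abort("`m0` and `times` are required when `proteins` is an evaluator.",
          class = "pathdyn_parameter_error")
  }
  if (!setequal(attr(proteins, "proteins"), model$proteins)) {
    abort("Protein series does not cover the model's proteins.",
          class = "pathdyn_schema_error")
  }
  span <- attr(proteins, "span")
  if (min(times) < span[1] - 1e-9 || max(times) > span[2] + 1e-9) {
    abort("Output grid lies outside the protein series span.",
          class = "pathdyn_extrapolation_error")
  }
  m0 <- m0[model$metabolites]
  if (anyNA(m0)) {
    abort("`m0` must cover all model metabolites.",
          class = "pathdyn_parameter_error")
  }
  ceiling_vec <- pmax(model$state_max, 1) * ceiling_factor
  diag_env <- new.env()
  diag_env$clip_events <- 0L
  diag_env$n_eval <- 0L
  feat_names <- model$feature_names
  rhs <- function(t, m) {
    diag_env$n_eval <- diag_env$n_eval + 1L
    if (any(abs(m) > ceiling_vec)) {
      abort(paste0("Trajectory diverged at t = ", signif(t, 6),
                   " h (state beyond ceiling)."),
            class = "pathdyn_divergence_error")
    }
    if (clip && any(m < 0)) {
      diag_env$clip_events <- diag_env$clip_events + 1L
      m <- pmax(m, 0)
    }
    x <- matrix(c(m, proteins(t)[model$proteins]), nrow = 1,
                dimnames = list(NULL, feat_names))
    drop(predict(model, x))
  }
  mm <- integrate_rhs(rhs, setNames(as.numeric(m0), model$metabolites),
                      times, rtol = rtol, atol = atol)
  if (clip) mm <- pmax(mm, 0)
  colnames(mm) <- paste0("met:", model$metabolites)
  structure(
    list(data = bind_cols(tibble(time = times), as_tibble(mm)),
         strain = strain_id,
         diagnostics = list(n_eval = diag_env$n_eval,
                            clip_events = diag_env$clip_events,
                            rtol = rtol, atol = atol)),
    class = "trajectory_prediction"
  )
}

#' @export
print.trajectory_prediction <- function(x, ...) {
  cat("<trajectory_prediction> strain ", x$strain, ", ",
      nrow(x$data), " time points, ", x$diagnostics$n_eval,
      " RHS evaluations\n", sep = "")
  invisible(x)
}

#' @method tidy trajectory_prediction
#' @export
tidy.trajectory_prediction <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time", names_to = "metabolite",
                      names_prefix = "met:", values_to = "concentration")
}

# The predicted final product: last value of the terminal metabolite.
final_product <- function(prediction) {
  d <- if (inherits(prediction, "trajectory_prediction")) prediction$data else prediction
  tail(d[[tail(grep("^met:", names(d), value = TRUE), 1)]], 1)
}
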