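#' Production-aligned directions in proteomics space (PLS)
#'
#' Projects each strain's final-time proteomics onto the low-dimensional
#' basis found by a two-block partial-least-squares regression of final
#' product titer on the (standardised) protein concentrations. Component 1
#' is the direction in proteomics phase space that best covaries with
#' increasing production; the per-protein loadings on that component rank
#' the candidate over/underexpression targets.
#'
#' @param final_proteomics A tibble with a `strain` column and `prot:`
#'   columns (one row per strain, final-time concentrations), or a plain
#'   numeric matrix with protein column names.
#' @param production Numeric vector of final product titers, one per strain.
#' @param n_components Number of PLS components (needs at least
#'   `n_components + 1` strains).
#' @param scale Standardise protein columns to unit variance before the
#'   regression (enzymes span scales).
#' @return An `insight_result`: `scores` (strain x component tibble),
#'   `loadings` (protein x component tibble, unit-normalised), `ranking`
#'   (proteins ordered by |component-1 loading| with signs), the production
#'   vector and the column centring/scaling used.
#' @export
pls_production_directions <- function(final_proteomics, production,
                                      n_components = 2, scale = TRUE) {
  if (is.data.frame(final_proteomics)) {
    fp <- as_tibble(final_proteomics)
    strains <- if ("strain" %in% names(fp)) fp$strain else
      paste0("strain_", seq_len(nrow(fp)))
    X <- as.matrix(fp[grep("^prot:", names(fp), value = TRUE)])
    colnames(X) <- sub("^prot:", "", colnames(X))
  } else {
    X <- as.matrix(final_proteomics)
    strains <- rownames(X) %||% paste0("strain_", seq_len(nrow(X)))
  }
  if (nrow(X) < n_components + 1) {
    abort("Need at least n_components + 1 strains.",
          class = "pathdyn_parameter_error")
  }
  if (sd(production) < 1e-15) {
    abort("Production vector is constant; PLS response is degenerate.",
          class = "pathdyn_degenerate_response_error")
  }
  ctr <- colMeans(X)
  scl <- if (scale) pmax(apply(X, 2, sd), 1e-12) else rep(1, ncol(X))
  fit <- mixOmics::pls(scale(X, center = ctr, scale = scl),
                       matrix(production, ncol = 1),
                       ncomp = n_components, scale = FALSE,
                       mode = "regression")
  loadings <- fit$loadings$X
  scores <- fit$variates$X
  comp_names <- paste0("comp", seq_len(n_components))
  ld <- bind_cols(tibble(protein = colnames(X)),
                  as_tibble(matrix(loadings, ncol = n_components,
                                   dimnames = list(NULL, comp_names))))
  sc <- bind_cols(tibble(strain = strains),
                  as_tibble(matrix(scores, ncol = n_components,
                                   dimnames = list(NULL, comp_names))))
  ranking <- ld |>
    mutate(loading = .data$comp1,
           direction = ifelse(.data$comp1 >= 0, "overexpress", "underexpress")) |>
    arrange(dplyr::desc(abs(.data$comp1))) |>
    select(all_of(c("protein", "loading", "direction")))
  structure(
    list(scores = sc, loadings = ld, ranking = ranking,
         production = production, center = ctr, scale = scl),
    class = "insight_result"
  )
}

#' @export
print.insight_result <- function(x, ...) {
  cat("<insight_result> ", nrow(x$scores), " strains, ",
      nrow(x$loadings), " proteins\n", sep = "")
  print(x$ranking)
  invisible(x)
}

#' @method tidy insight_result
#' @export
tidy.insight_result <- function(x, ...) x$ranking

#' @method glance insight_result
#' @export
glance.insight_result <- function(x, ...) {
  tibble(n_strains = nrow(x$scores), n_proteins = nrow(x$loadings),
         cor_comp1_production = cor(x$scores$comp1, x$production))
}

# Translate a standardised-space direction back to concentration units.
direction_in_units <- function(insight, component = "comp1") {
  setNames(insight$loadings[[component]] * insight$scale,
           insight$loadings$protein)
}

#' Propose strains along a production direction and predict their dynamics
#'
#' Moves a base strain's final-time protein targets along a direction in
#' proteomics space (for example the component-1 loading of
#' [pls_production_directions()], rescaled to concentration units) at each
#' requested step size, clips the displaced targets at zero, rescales the
#' base strain's leaky-Hill profiles (`k_f` and `k_l` jointly) so each
#' protein hits its displaced final value, and predicts the full metabolite
#' trajectories of every proposed strain.
#'
#' @param model A fitted `dynamics_model`, or a `kinetic_model` (in which
#'   case trajectories come from the ground-truth simulator).
#' @param base_hill Tibble of the base strain's Hill coefficients
#'   (`protein`, `k_f`, `k_m`, `k_l`).
#' @param direction Named numeric displacement per protein, in
#'   concentration units (see [pls_production_directions()]).
#' @param step_sizes Numeric multipliers applied to `direction` (0 keeps
#'   the base strain).
#' @param times Prediction grid (hours).
#' @param m0 Initial metabolite vector.
#' @return A tibble with columns `step`, `final_product` and a list-column
#'   `prediction` holding each proposed strain's trajectory.
#' @export
propose_and_simulate <- function(model, base_hill, direction,
                                 step_sizes = c(0, 0.5, 1),
                                 times = seq(0, 72, length.out = 25),
                                 m0 = NULL) {
  proteins <- if (inherits(model, "kinetic_model")) model$proteins else
    model$proteins
  base_hill <- validate_hill_params(base_hill, proteins)
  if (is.null(names(direction)) || !setequal(names(direction), proteins)) {
    abort("`direction` must be named by the model's proteins.",
          class = "pathdyn_parameter_error")
  }
  direction <- direction[base_hill$protein]
  t_f <- max(times)
  p_final <- with(base_hill, k_f * t_f / (k_m + t_f) + k_l)
  rows <- lapply(step_sizes, function(step) {
    target <- pmax(p_final + step * direction, 0)
    s_fac <- ifelse(p_final > 1e-12, target / p_final, 0)
    hp <- base_hill
    hp$k_f <- hp$k_f * s_fac
    hp$k_l <- hp$k_l * s_fac
    hp$k_l[p_final <= 1e-12] <- target[p_final <= 1e-12]
    if (inherits(model, "kinetic_model")) {
      pred <- simulate_strain(model, hp,
                              m0 = m0 %||% default_initial_metabolites(model),
                              times = times,
                              strain_id = paste0("proposed_step_", step))
      fp <- final_product(pred)
    } else {
      pp <- hill_matrix(hp, times)
      colnames(pp) <- paste0("prot:", colnames(pp))
      prot_series <- omics_ts(bind_cols(
        tibble(strain = paste0("proposed_step_", step), time = times),
        as_tibble(pp)
      ))
      if (is.null(m0)) {
        abort("`m0` is required for dynamics-model predictions.",
              class = "pathdyn_parameter_error")
      }
      pred <- predict_trajectory(model, prot_series, m0 = m0, times = times)
      fp <- final_product(pred)
    }
    tibble(step = step, final_product = fp, prediction = list(pred))
  })
  bind_rows(rows)
}
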