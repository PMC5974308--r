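limonene_metabolites <- c(
  "acetyl_coa", "acetoacetyl_coa", "hmg_coa", "mevalonate", "mevalonate_p",
  "mevalonate_pp", "ipp", "dmapp", "gpp", "limonene"
)

limonene_proteins <- c(
  "AtoB", "HMGS", "HMGR", "MK", "PMK", "PMD", "Idi", "GPPS", "LS"
)

reference_config <- function() {
  yaml::read_yaml(system.file("extdata", "limonene_reference_params.yaml",
                              package = "pathdyn"))
}

#' Ground-truth kinetic model of the limonene-producing mevalonate pathway
#'
#' Builds the 10-state Michaelis-Menten ODE system describing the
#' heterologous mevalonate pathway from acetyl-CoA to limonene in
#' *E. coli*. Every reaction rate has the form
#' `v = kcat * E * S / (K_M + S)`, scaled linearly by the concentration of
#' the catalysing enzyme; acetyl-CoA is replenished by a constant source
#' flux (a proxy for host metabolism); the thiolase AtoB consumes two
#' acetyl-CoA per condensation; Idi is reversible with separate forward and
#' reverse Michaelis-Menten terms; GPPS condenses one IPP with one DMAPP
#' using a product of two saturation factors.
#'
#' The default parameter set is a documented synthetic reference (shipped in
#' `inst/extdata/limonene_reference_params.yaml`), calibrated so that the
#' intermediates display non-monotonic (peak-then-decline) trajectories over
#' a 72 h fermentation.
#'
#' @param params Named numeric vector of kinetic constants; defaults to the
#'   shipped reference set. All constants must be strictly positive.
#' @return A `kinetic_model` object with fields `metabolites`, `proteins`,
#'   `params`, and an `rhs(m, p, params)` evaluator returning `dm/dt`.
#' @examples
#' mod <- limonene_pathway_model()
#' mod$rhs(default_initial_metabolites(mod),
#'         setNames(rep(0.5, 9), mod$proteins), mod$params)
#' @export
limonene_pathway_model <- function(params = NULL) {
  ref <- unlist(reference_config()$kinetic_constants)
  if (is.null(params)) params <- ref
  if (!setequal(names(params), names(ref))) {
    abort("`params` must contain exactly the model's kinetic constants.",
          class = "pathdyn_parameter_error")
  }
  params <- params[names(ref)]
  if (any(params <= 0)) {
    abort("All kinetic constants must be strictly positive.",
          class = "pathdyn_parameter_error")
  }
  structure(
    list(metabolites = limonene_metabolites,
         proteins = limonene_proteins,
         params = params,
         rhs = limonene_rhs),
    class = "kinetic_model"
  )
}

# Michaelis-Menten flux of one enzymatic step.
mm_rate <- function(kcat, enzyme, substrate, km) {
  kcat * enzyme * substrate / (km + substrate)
}

# Right-hand side dm/dt of the 10-state system. States are clipped at zero
# before flux evaluation so that adaptive-step overshoot below zero cannot
# produce negative substrate terms.
limonene_rhs <- function(m, p, q) {
  m <- pmax(m, 0)
  v_atob <- mm_rate(q[["kcat_atob"]], p[["AtoB"]], m[[1]], q[["km_atob"]])
  v_hmgs <- mm_rate(q[["kcat_hmgs"]], p[["HMGS"]], m[[2]], q[["km_hmgs"]])
  v_hmgr <- mm_rate(q[["kcat_hmgr"]], p[["HMGR"]], m[[3]], q[["km_hmgr"]])
  v_mk   <- mm_rate(q[["kcat_mk"]],   p[["MK"]],   m[[4]], q[["km_mk"]])
  v_pmk  <- mm_rate(q[["kcat_pmk"]],  p[["PMK"]],  m[[5]], q[["km_pmk"]])
  v_pmd  <- mm_rate(q[["kcat_pmd"]],  p[["PMD"]],  m[[6]], q[["km_pmd"]])
  v_idif <- mm_rate(q[["kcat_idi_f"]], p[["Idi"]], m[[7]], q[["km_idi_f"]])
  v_idir <- mm_rate(q[["kcat_idi_r"]], p[["Idi"]], m[[8]], q[["km_idi_r"]])
  v_gpps <- q[["kcat_gpps"]] * p[["GPPS"]] *
    (m[[7]] / (q[["km_gpps_ipp"]] + m[[7]])) *
    (m[[8]] / (q[["km_gpps_dmapp"]] + m[[8]]))
  v_ls   <- mm_rate(q[["kcat_ls"]], p[["LS"]], m[[9]], q[["km_ls"]])
  c(acetyl_coa      = q[["v_accoa"]] - 2 * v_atob,
    acetoacetyl_coa = v_atob - v_hmgs,
    hmg_coa         = v_hmgs - v_hmgr,
    mevalonate      = v_hmgr - v_mk,
    mevalonate_p    = v_mk - v_pmk,
    mevalonate_pp   = v_pmk - v_pmd,
    ipp             = v_pmd - v_idif + v_idir - v_gpps,
    dmapp           = v_idif - v_idir - v_gpps,
    gpp             = v_gpps - v_ls,
    limonene        = v_ls)
}

#' Default auxiliary configuration of the reference model
#'
#' `default_initial_metabolites()` returns the reference initial state
#' (carbon enters as acetyl-CoA; all downstream species start at zero).
#' `default_hill_ranges()` returns the log-uniform sampling intervals used
#' to draw virtual-strain Hill coefficients, spanning roughly two orders of
#' magnitude around the reference expression levels.
#' `reference_hill_params()` returns the reference expression profiles.
#' `kinetic_bounds()` returns the per-constant optimisation box used by
#' [fit_kinetic_model()], defaulting to `[1e-12, 1e9]` for every constant.
#'
#' @param model A `kinetic_model`.
#' @export
default_initial_metabolites <- function(model = limonene_pathway_model()) {
  m0 <- unlist(reference_config()$initial_metabolites)
  m0[model$metabolites]
}

#' @rdname default_initial_metabolites
#' @export
default_hill_ranges <- function() {
  rr <- reference_config()$hill_sampling_ranges
  tibble(coefficient = names(rr),
         lower = map_dbl(rr, "lower"),
         upper = map_dbl(rr, "upper"))
}

#' @rdname default_initial_metabolites
#' @export
reference_hill_params <- function() {
  hh <- reference_config()$reference_hill
  tibble(protein = names(hh),
         k_f = map_dbl(hh, "k_f"),
         k_m = map_dbl(hh, "k_m"),
         k_l = map_dbl(hh, "k_l"))
}

#' @rdname default_initial_metabolites
#' @param lower,upper Default box limits applied to every kinetic constant.
#' @export
kinetic_bounds <- function(model = limonene_pathway_model(),
                           lower = 1e-12, upper = 1e9) {
  stopifnot(lower > 0, lower < upper)
  tibble(parameter = names(model$params), lower = lower, upper = upper)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", length(x$metabolites), " metabolites, ",
      length(x$proteins), " enzymes, ", length(x$params),
      " kinetic constants\n", sep = "")
  invisible(x)
}
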