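#' Leaky Hill protein-expression profile
#'
#' Protein expression after induction is modelled as a saturating leaky Hill
#' curve, `p(t) = k_f * t / (k_m + t) + k_l`: expression rises from the leak
#' level `k_l` at induction towards the plateau `k_f + k_l`, reaching half
#' of the inducible amplitude at `t = k_m`.
#'
#' @param times Nonnegative, strictly increasing time grid (hours).
#' @param k_f Saturating amplitude (concentration units), `>= 0`.
#' @param k_m Half-saturation time (hours), `> 0`.
#' @param k_l Leak level (concentration units), `>= 0`.
#' @return Numeric vector of protein concentrations at `times`, in
#'   `[k_l, k_f + k_l)`, strictly increasing whenever `k_f > 0`.
#' @examples
#' hill_profile(c(0, 1, 10), k_f = 2, k_m = 1, k_l = 0.5)
#' @export
hill_profile <- function(times, k_f, k_m, k_l) {
  if (!is.numeric(k_m) || any(k_m <= 0)) {
    abort("`k_m` must be strictly positive.", class = "pathdyn_parameter_error")
  }
  if (any(k_f < 0) || any(k_l < 0)) {
    abort("`k_f` and `k_l` must be nonnegative.", class = "pathdyn_parameter_error")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort("`times` must be nonnegative and strictly increasing.",
          class = "pathdyn_parameter_error")
  }
  k_f * times / (k_m + times) + k_l
}

# Hill coefficients for a set of proteins -> protein matrix at `times`.
# `params` is a tibble with columns protein, k_f, k_m, k_l.
hill_matrix <- function(params, times) {
  out <- vapply(seq_len(nrow(params)), function(i) {
    hill_profile(times, params$k_f[i], params$k_m[i], params$k_l[i])
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  colnames(out) <- params$protein
  out
}

validate_hill_params <- function(params, proteins) {
  params <- as_tibble(params)
  need <- c("protein", "k_f", "k_m", "k_l")
  if (!all(need %in% names(params))) {
    abort("Hill parameters need columns protein, k_f, k_m, k_l.",
          class = "pathdyn_parameter_error")
  }
  if (!setequal(params$protein, proteins)) {
    abort("Hill parameters must cover exactly the model's proteins.",
          class = "pathdyn_parameter_error")
  }
  if (any(params$k_m <= 0) || any(params$k_f < 0) || any(params$k_l < 0)) {
    abort("Require k_f >= 0, k_m > 0, k_l >= 0 for every protein.",
          class = "pathdyn_parameter_error")
  }
  params[match(proteins, params$protein), need]
}
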