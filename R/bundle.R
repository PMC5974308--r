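#' Save or load a dynamics-model bundle
#'
#' A bundle is a directory holding the serialised per-metabolite sub-models
#' (`model.rds`) together with a JSON manifest recording the species
#' registries, the per-metabolite winning candidates and their CV scores,
#' the search seed and a format version, so a saved model is
#' self-describing.
#'
#' @param model A fitted `dynamics_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_dynamics_model()` invisibly returns `dir`;
#'   `load_dynamics_model()` returns the `dynamics_model`.
#' @export
save_dynamics_model <- function(model, dir) {
  stopifnot(inherits(model, "dynamics_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(format_version = "1.0",
         package_version = as.character(packageVersion("pathdyn")),
         metabolites = model$metabolites,
         proteins = model$proteins,
         seed = model$seed,
         sub_models = tidy(model)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(dir)
}

#' @rdname save_dynamics_model
#' @export
load_dynamics_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) {
    abort(paste0("No model bundle at '", dir, "'."),
          class = "pathdyn_schema_error")
  }
  model <- readRDS(path)
  stopifnot(inherits(model, "dynamics_model"))
  model
}
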