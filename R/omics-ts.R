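#' Multiomics time-series tables
#'
#' A multiomics time series is stored as a plain tibble in wide format: one
#' row per observation time, a `strain` identifier column, a `time` column
#' (hours since induction), metabolite concentration columns named
#' `met:<name>` and protein concentration columns named `prot:<name>`.
#' Concentration units are carried implicitly (the method is unit-covariant
#' as long as all strains share the same units). A table may hold several
#' strains stacked on top of each other.
#'
#' `omics_ts()` validates a data frame against this schema and returns it as
#' a tibble of class `omics_ts`:
#' * `strain` and `time` columns are present;
#' * every other column is prefixed `met:` or `prot:`;
#' * times are strictly increasing within each strain;
#' * all concentrations are finite and nonnegative.
#'
#' @param x A data frame in the wide multiomics layout.
#' @return A tibble of class `omics_ts`.
#' @examples
#' omics_ts(tibble::tibble(
#'   strain = "s1", time = c(0, 12, 24),
#'   `met:limonene` = c(0, 1, 2), `prot:LS` = c(0.1, 0.5, 0.8)
#' ))
#' @export
omics_ts <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.", class = "pathdyn_schema_error")
  x <- as_tibble(x)
  if (!all(c("strain", "time") %in% names(x))) {
    abort("An omics time series needs `strain` and `time` columns.",
          class = "pathdyn_schema_error")
  }
  other <- setdiff(names(x), c("strain", "time"))
  bad <- other[!grepl("^(met|prot):", other)]
  if (length(bad) > 0) {
    abort(paste0("Unknown column prefix for: ", paste(bad, collapse = ", "),
                 " (expected `met:<name>` or `prot:<name>`)."),
          class = "pathdyn_schema_error")
  }
  x$strain <- as.character(x$strain)
  for (s in unique(x$strain)) {
    tt <- x$time[x$strain == s]
    if (anyNA(tt) || any(diff(tt) <= 0)) {
      abort(paste0("Times must be strictly increasing within strain '", s, "'."),
            class = "pathdyn_schema_error")
    }
  }
  vals <- as.matrix(x[other])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Concentrations must be finite and non-missing.",
          class = "pathdyn_validation_error")
  }
  if (any(vals < 0)) {
    row <- which(rowSums(vals < 0) > 0)[1]
    abort(paste0("Negative concentration in row ", row, "."),
          class = "pathdyn_validation_error")
  }
  class(x) <- c("omics_ts", class(x))
  x
}

as_omics_ts <- function(x) if (inherits(x, "omics_ts")) x else omics_ts(x)

#' @export
print.omics_ts <- function(x, ...) {
  cat("<omics_ts> ", length(unique(x$strain)), " strain(s), ",
      length(met_names(x)), " metabolites, ", length(prot_names(x)),
      " proteins\n", sep = "")
  NextMethod()
}

met_cols <- function(x) grep("^met:", names(x), value = TRUE)
prot_cols <- function(x) grep("^prot:", names(x), value = TRUE)

#' Species names of a multiomics table
#'
#' @param x An `omics_ts` tibble (or any data frame using the same layout).
#' @return Character vector of metabolite (`met_names`) or protein
#'   (`prot_names`) names, without the column prefix.
#' @export
met_names <- function(x) sub("^met:", "", met_cols(x))

#' @rdname met_names
#' @export
prot_names <- function(x) sub("^prot:", "", prot_cols(x))

met_matrix <- function(x) {
  m <- as.matrix(x[met_cols(x)])
  colnames(m) <- met_names(x)
  m
}

prot_matrix <- function(x) {
  m <- as.matrix(x[prot_cols(x)])
  colnames(m) <- prot_names(x)
  m
}

split_strains <- function(x) {
  split(x, x$strain)[unique(x$strain)]
}

#' Read and write multiomics time-series CSV files
#'
#' The on-disk format mirrors the in-memory layout of [omics_ts()]: columns
#' `strain,time` followed by `met:<name>` and `prot:<name>` columns. Writing
#' orders columns deterministically (metabolites then proteins, each
#' alphabetical) and keeps full double precision, so write/read round-trips
#' are lossless.
#'
#' @param path Path of the CSV file.
#' @return `read_omics_csv()` returns a validated `omics_ts` tibble;
#'   `write_omics_csv()` invisibly returns `path`.
#' @export
read_omics_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  omics_ts(df)
}

#' @rdname read_omics_csv
#' @param series An `omics_ts` tibble.
#' @export
write_omics_csv <- function(series, path) {
  series <- as_omics_ts(series)
  cols <- c("strain", "time", sort(met_cols(series)), sort(prot_cols(series)))
  readr::write_csv(series[cols], path, progress = FALSE)
  invisible(path)
}

#' Write or read a dataset manifest
#'
#' A manifest is a small JSON file listing the strain CSV files of a dataset
#' together with their roles (train/test), the species registries shared by
#' all strains, and a format version.
#'
#' @param strains A tibble with columns `strain`, `file` and optionally
#'   `role` (defaults to `"train"`).
#' @param metabolites,proteins Species name registries.
#' @param path Path of the JSON manifest.
#' @export
write_manifest <- function(strains, metabolites, proteins, path) {
  strains <- as_tibble(strains)
  if (!"role" %in% names(strains)) strains$role <- "train"
  stopifnot(!anyDuplicated(strains$strain))
  jsonlite::write_json(
    list(format_version = "1.0",
         strains = strains[c("strain", "file", "role")],
         metabolites = metabolites, proteins = proteins),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$strains <- as_tibble(man$strains)
  base <- dirname(path)
  missing <- !file.exists(file.path(base, man$strains$file))
  if (any(missing)) {
    abort(paste0("Manifest references missing files: ",
                 paste(man$strains$file[missing], collapse = ", ")),
          class = "pathdyn_schema_error")
  }
  man$dir <- base
  man
}
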