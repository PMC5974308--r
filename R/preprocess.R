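#' Savitzky-Golay smoothing of a multiomics time series
#'
#' Replaces every metabolite and protein column by its Savitzky-Golay
#' least-squares local-polynomial smoothing (window of 7 points and
#' polynomial order 2 by default, the setting used for 7-point fermentation
#' series; with window = series length the filter degenerates to a single
#' global polynomial fit, which is accepted). Smoothed concentrations are
#' clipped at zero. Times are unchanged. Multi-strain tables are smoothed
#' strain by strain.
#'
#' @param series An [omics_ts()] tibble.
#' @param window Odd filter window length, `polyorder < window <= s`.
#' @param polyorder Polynomial order of the local fit.
#' @return The smoothed `omics_ts`.
#' @export
smooth_series <- function(series, window = 7, polyorder = 2) {
  series <- as_omics_ts(series)
  if (window %% 2 != 1 || window <= polyorder) {
    abort("`window` must be odd and greater than `polyorder`.",
          class = "pathdyn_parameter_error")
  }
  parts <- lapply(split_strains(series), function(s) {
    if (window > nrow(s)) {
      abort(paste0("Window (", window, ") exceeds the ", nrow(s),
                   " points of strain '", s$strain[1], "'."),
            class = "pathdyn_insufficient_points_error")
    }
    for (cl in c(met_cols(s), prot_cols(s))) {
      s[[cl]] <- pmax(signal::sgolayfilt(s[[cl]], p = polyorder, n = window), 0)
    }
    s
  })
  omics_ts(bind_rows(parts))
}

#' Estimate metabolite time derivatives by finite differences
#'
#' Interior points use the central difference
#' `(m[i+1] - m[i-1]) / (t[i+1] - t[i-1])` (exact for quadratics on uniform
#' grids, and well defined on non-uniform grids); the two boundary points
#' use first-order one-sided differences so that every observation time
#' yields a training example. Apply to a smoothed series: differentiating
#' raw noisy data amplifies the noise.
#'
#' @param smoothed An [omics_ts()] tibble with at least 3 time points per
#'   strain.
#' @return A tibble with columns `strain`, `time` and one `dmdt:<name>`
#'   column per metabolite.
#' @export
estimate_derivatives <- function(smoothed) {
  smoothed <- as_omics_ts(smoothed)
  parts <- lapply(split_strains(smoothed), function(s) {
    tt <- s$time
    if (length(tt) < 3) {
      abort("Need at least 3 time points to estimate derivatives.",
            class = "pathdyn_parameter_error")
    }
    if (anyDuplicated(tt)) {
      abort("Duplicate time values make the grid degenerate.",
            class = "pathdyn_degenerate_grid_error")
    }
    mm <- met_matrix(s)
    d <- finite_differences(tt, mm)
    colnames(d) <- paste0("dmdt:", colnames(mm))
    bind_cols(tibble(strain = s$strain, time = tt), as_tibble(d))
  })
  bind_rows(parts)
}

finite_differences <- function(tt, mm) {
  s <- length(tt)
  d <- mm
  d[1, ] <- (mm[2, ] - mm[1, ]) / (tt[2] - tt[1])
  d[s, ] <- (mm[s, ] - mm[s - 1, ]) / (tt[s] - tt[s - 1])
  if (s > 2) {
    i <- 2:(s - 1)
    d[i, ] <- (mm[i + 1, , drop = FALSE] - mm[i - 1, , drop = FALSE]) /
      (tt[i + 1] - tt[i - 1])
  }
  d
}

#' Augment a sparse time series by smoothing and interpolation
#'
#' Expands a sparse series (typically 7 fermentation time points) onto a
#' uniform grid of exactly `target_points` points spanning the original
#' time range, by Savitzky-Golay smoothing followed by cubic-spline
#' interpolation over the filtered curve (clipped at zero where the spline
#' overshoots below zero). The default expansion is 7 to 200 points. The
#' first and last grid times equal the original endpoints; augmentation
#' never extrapolates.
#'
#' @inheritParams smooth_series
#' @param target_points Size of the output grid, `>= s`.
#' @return The augmented `omics_ts` on the uniform grid.
#' @export
augment_series <- function(series, target_points = 200, window = 7,
                           polyorder = 2) {
  series <- as_omics_ts(series)
  smoothed <- smooth_series(series, window = window, polyorder = polyorder)
  parts <- lapply(split_strains(smoothed), function(s) {
    if (target_points < nrow(s)) {
      abort("`target_points` must be at least the number of observed points.",
            class = "pathdyn_invalid_request_error")
    }
    grid <- seq(s$time[1], s$time[nrow(s)], length.out = target_points)
    out <- tibble(strain = s$strain[1], time = grid)
    for (cl in c(met_cols(s), prot_cols(s))) {
      fun <- splinefun(s$time, s[[cl]], method = "fmm")
      out[[cl]] <- pmax(fun(grid), 0)
    }
    out
  })
  omics_ts(bind_rows(parts))
}

#' Build a state-derivative training set
#'
#' Turns one or more strains' observed multiomics time series into the
#' training pairs of the supervised dynamics-learning problem: each row
#' pairs the concatenated metabolite and protein concentrations `(m, p)` at
#' one retained time point with the estimated metabolite derivatives
#' `dm/dt` at the same point. By default each strain is first augmented
#' (smoothing + interpolation onto `target_points` points) and derivatives
#' are estimated on the augmented grid, yielding one training example per
#' augmented time point per strain.
#'
#' @param strains An [omics_ts()] tibble (possibly multi-strain) or a list
#'   of such tibbles. All strains must share identical metabolite and
#'   protein name sets.
#' @param target_points Augmented grid size per strain.
#' @param window,polyorder Savitzky-Golay settings.
#' @param augment If `FALSE`, skip augmentation and differentiate the
#'   smoothed series on the original grid.
#' @return A tibble of class `deriv_training_set` with provenance columns
#'   `strain`, `time`, feature columns `met:`/`prot:` and target columns
#'   `dmdt:`.
#' @export
build_training_set <- function(strains, target_points = 200, window = 7,
                               polyorder = 2, augment = TRUE) {
  if (is.data.frame(strains)) strains <- list(strains)
  strains <- lapply(strains, as_omics_ts)
  mets <- met_names(strains[[1]])
  prots <- prot_names(strains[[1]])
  same <- map_lgl(strains, function(s) {
    identical(met_names(s), mets) && identical(prot_names(s), prots)
  })
  if (!all(same)) {
    abort("All strains must share the same metabolite and protein names.",
          class = "pathdyn_schema_error")
  }
  rows <- lapply(strains, function(s) {
    prep <- if (augment) {
      augment_series(s, target_points = target_points, window = window,
                     polyorder = polyorder)
    } else {
      smooth_series(s, window = window, polyorder = polyorder)
    }
    derivs <- estimate_derivatives(prep)
    bind_cols(prep, derivs[grep("^dmdt:", names(derivs), value = TRUE)])
  })
  out <- as_tibble(bind_rows(rows))
  if (any(!is.finite(as.matrix(out[setdiff(names(out), "strain")])))) {
    abort("Training set contains non-finite values.",
          class = "pathdyn_validation_error")
  }
  class(out) <- c("deriv_training_set", setdiff(class(out), "omics_ts"))
  out
}

target_cols <- function(train) grep("^dmdt:", names(train), value = TRUE)

feature_cols <- function(train) {
  c(grep("^met:", names(train), value = TRUE),
    grep("^prot:", names(train), value = TRUE))
}

feature_matrix <- function(train) {
  as.matrix(as_tibble(train)[feature_cols(train)])
}
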