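#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures for the package's
#' result types: multiomics trajectories faceted by species, predicted
#' versus reference trajectories, experiment summaries with spread bars,
#' and the PLS score map sized by production.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name pathdyn-plots
NULL

#' @rdname pathdyn-plots
#' @method autoplot omics_ts
#' @export
autoplot.omics_ts <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -c("strain", "time"),
                              names_to = c("block", "species"),
                              names_sep = ":", values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration")
}

#' @rdname pathdyn-plots
#' @param reference Optional reference [omics_ts()] overlaid as points.
#' @method autoplot trajectory_prediction
#' @export
autoplot.trajectory_prediction <- function(object, reference = NULL, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~ .data$metabolite, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration",
                  title = paste("Predicted trajectories:", object$strain))
  if (!is.null(reference)) {
    ref_long <- tidyr::pivot_longer(
      as_met_table(reference), -"time", names_to = "metabolite",
      names_prefix = "met:", values_to = "concentration"
    )
    ref_long$time <- rep(as_met_table(reference)$time,
                         times = nrow(ref_long) / nrow(as_met_table(reference)))
    p <- p + ggplot2::geom_point(data = ref_long, colour = "darkgreen")
  }
  p
}

#' @rdname pathdyn-plots
#' @method autoplot ranking_experiment
#' @export
autoplot.ranking_experiment <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$train_size),
                                  .data$mean_success)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_success - .data$sd_success,
      ymax = .data$mean_success + .data$sd_success), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed") +
    ggplot2::labs(x = "training strains", y = "ranking success rate")
}

#' @rdname pathdyn-plots
#' @method autoplot scaling_experiment
#' @export
autoplot.scaling_experiment <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$train_size), .data$mean_rmse)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rmse - .data$sd_rmse,
      ymax = .data$mean_rmse + .data$sd_rmse), width = 0.2) +
    ggplot2::labs(x = "training strains", y = "trajectory RMSE")
}

#' @rdname pathdyn-plots
#' @method autoplot insight_result
#' @export
autoplot.insight_result <- function(object, ...) {
  d <- object$scores
  d$production <- object$production
  ggplot2::ggplot(d, ggplot2::aes(.data$comp1, .data$comp2,
                                  size = .data$production,
                                  colour = .data$production)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "component 1 (production-aligned)", y = "component 2")
}
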