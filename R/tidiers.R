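#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
#' @rdname tidy.compartment_fit
#' @param x A fitted object.
#' @param ... Unused.
tidy.compartment_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("K1", "k2", "k3", "vB", "delay_s", names(x$macro)),
         estimate = c(p$K1, p$k2, p$k3, p$vB, p$delay_s, unname(x$macro)))
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row model
#' summary.
#'
#' @name tidy.compartment_fit
#' @exportS3Method generics::glance
glance.compartment_fit <- function(x, ...) {
  tibble(model = x$model, macro = names(x$macro),
         macro_value = unname(x$macro), objective = x$objective,
         converged = x$converged, n_frames_used = x$n_frames_used)
}

#' @exportS3Method generics::tidy
#' @rdname tidy.compartment_fit
tidy.graphical_result <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @exportS3Method generics::glance
#' @rdname tidy.compartment_fit
glance.graphical_result <- function(x, ...) {
  tibble(kind = x$kind, tstar_min = x$tstar_min, macro = names(x$macro),
         macro_value = unname(x$macro), n_points = x$n_points,
         r_squared = x$r_squared)
}

#' Plot a time-activity curve
#'
#' Mean curve with a +/- 1 SD ribbon (spatial spread over the VOI).
#'
#' @param object A `pet_tac`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pet_tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid_s / 60, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (min)", y = object$units[1])
}

#' Plot low-dose experiment bias records
#'
#' Percent bias against dose, faceted by metric and region, coloured by
#' method.
#'
#' @param object A `low_dose_experiment`.
#' @param metrics Metrics to show (default AUC and macro-parameter bias).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.low_dose_experiment <- function(object,
                                         metrics = c("auc_bias", "ki_bias",
                                                     "vt_bias"), ...) {
  df <- dplyr::filter(object$records,
                      .data$metric %in% metrics,
                      .data$reference == "full_dose_non_dn")
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$dose, .data$method, .data$metric),
    value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(1 / .data$dose),
                                   y = .data$value,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ region, scales = "free_y") +
    ggplot2::labs(x = "Dose reduction (1/x)", y = "Percent bias (%)",
                  colour = "Method")
}

#' Plot a parametric map slice
#'
#' @param object A `parametric_map`.
#' @param slice Axial slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.parametric_map <- function(object, slice = NULL, ...) {
  d <- dim(object$slope)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$slope[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = if (object$kind == "patlak") "Ki" else "VT",
                  title = sprintf("%s map, slice %d (t* = %g min)",
                                  object$kind, slice, object$tstar_min))
}
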