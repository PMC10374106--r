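#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy per-cell observables of a run
#'
#' @param x An `rbc_sim`.
#' @param ... Unused.
#' @return A tibble with one row per cell per saved time: summed elastic
#'   force components, center of mass, enclosed area and perimeter.
#' @method tidy rbc_sim
#' @export
tidy.rbc_sim <- function(x, ...) {
  x$observables
}

#' One-row summary of a run
#'
#' @param x An `rbc_sim`.
#' @param ... Unused.
#' @return A tibble with the run end time, cell count, time-averaged lift
#'   and drag magnitudes and fractions, worst-case area and perimeter
#'   drifts (percent of the reference), and the maximum divergence
#'   residual.
#' @method glance rbc_sim
#' @export
glance.rbc_sim <- function(x, ...) {
  ld <- lift_drag(x, transient_frac = 0.2)
  ob <- x$observables
  drift <- function(v, ref) if (length(v)) 100 * max(abs(v - ref[1L]) / ref[1L]) else NA_real_
  area_d <- perim_d <- NA_real_
  if (nrow(ob)) {
    per_cell <- split(ob, ob$cell)
    area_d <- max(vapply(per_cell, function(d) drift(d$area, d$area), numeric(1L)))
    perim_d <- max(vapply(per_cell, function(d) drift(d$perimeter, d$perimeter),
                          numeric(1L)))
  }
  tibble::tibble(
    t_end = max(x$fluid_series$time),
    n_cells = if (nrow(ob)) length(unique(ob$cell)) else 0L,
    mean_lift = attr(ld, "mean_lift"),
    mean_drag = attr(ld, "mean_drag"),
    lift_frac = attr(ld, "lift_frac"),
    drag_frac = attr(ld, "drag_frac"),
    max_area_drift_pct = area_d,
    max_perimeter_drift_pct = perim_d,
    max_divergence = max(x$fluid_series$div_max),
    scaled_down = x$scaled_down)
}

#' Plot the time evolution of a run
#'
#' Cell height above the bottom wall together with the lift and drag
#' series.
#'
#' @param object An `rbc_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbc_sim
#' @export
autoplot.rbc_sim <- function(object, ...) {
  ld <- lift_drag(object)
  d1 <- data.frame(time = ld$time, value = ld$lift, series = "lift")
  d2 <- data.frame(time = ld$time, value = ld$drag, series = "drag")
  dd <- rbind(d1, d2)
  if (nrow(object$observables)) {
    ob <- object$observables
    dd <- rbind(dd, data.frame(time = ob$time, value = ob$comy,
                               series = paste0("com_y cell ", ob$cell)))
  }
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time (model s)", y = NULL)
}

#' Plot a sweep summary
#'
#' Drag and lift fractions of the total force versus the swept parameter.
#'
#' @param object An `rbc_sweep` from [sweep_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbc_sweep
#' @export
autoplot.rbc_sweep <- function(object, ...) {
  dd <- rbind(
    data.frame(value = object$value, frac = object$drag_frac, which = "drag"),
    data.frame(value = object$value, frac = object$lift_frac, which = "lift"))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$value, y = .data$frac,
                                   colour = .data$which)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter), y = "fraction of total force",
                  colour = NULL)
}

#' Plot an occupancy density map
#'
#' @param map Matrix from [density_map()].
#' @param grid The grid it was computed on.
#' @return A ggplot raster of the time-averaged cell occupancy.
#' @export
plot_density_map <- function(map, grid) {
  dd <- expand.grid(x = grid$xp, y = grid$yp)
  dd$density <- as.vector(map)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (model um)", y = "y (model um)",
                  fill = "occupancy")
}
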