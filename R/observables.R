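#' Lift and drag time series from the immersed-boundary forces
#'
#' Lift and drag are obtained by summing the Lagrangian forces at the
#' immersed boundary points at each saved step and taking the opposite
#' sign: `lift(t) = -sum F_y` (force perpendicular to the incoming flow,
#' positive away from the bottom wall) and `drag(t) = -sum F_x` (the
#' wall-induced force opposing motion along the flow). Because a closed
#' membrane's elastic force sums to zero identically, the summed force is
#' carried by the wall structures (tether plus fiber elasticity), which
#' transmit the cell's influence; a symmetric resting configuration in
#' quiescent fluid gives zero for both. Reported magnitudes are absolute
#' time averages.
#'
#' @param x An `rbc_sim` object (uses the recorded whole-boundary force
#'   sums), or a data frame with columns `time`, `fx`, `fy` of summed
#'   boundary forces.
#' @param transient_frac Fraction of the record discarded before
#'   time-averaging.
#' @param sign_lift,sign_drag Sign conventions (exposed for audit; defaults
#'   follow the opposite-sign-of-the-sum rule).
#' @return A tibble `time`, `lift`, `drag` with attributes `mean_lift`,
#'   `mean_drag` (absolute time averages), `drag_frac` and `lift_frac`
#'   (fractions of the total, summing to one).
#' @export
lift_drag <- function(x, transient_frac = 0,
                      sign_lift = -1, sign_drag = -1) {
  tb <- if (inherits(x, "rbc_sim")) {
    data.frame(time = x$fluid_series$time,
               fx = x$fluid_series$wfx, fy = x$fluid_series$wfy)
  } else {
    as.data.frame(x)
  }
  if (!nrow(tb)) stop("empty force history", call. = FALSE)
  out <- tibble::tibble(time = tb$time,
                        lift = sign_lift * tb$fy,
                        drag = sign_drag * tb$fx)
  keep <- out$time >= transient_frac * max(out$time)
  ml <- abs(mean(out$lift[keep]))
  md <- abs(mean(out$drag[keep]))
  attr(out, "mean_lift") <- ml
  attr(out, "mean_drag") <- md
  tot <- ml + md
  attr(out, "lift_frac") <- if (tot > 0) ml / tot else NA_real_
  attr(out, "drag_frac") <- if (tot > 0) md / tot else NA_real_
  out
}

#' Mean and 95% confidence half-width over initial conditions
#'
#' Aggregates per-initial-condition scalars (e.g. time-averaged lift over
#' the four phase offsets) into an arithmetic mean and a Student-t 95%
#' confidence half-width with `n - 1` degrees of freedom.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `mean`, `ci95`, and `n`.
#' @export
average_over_ic <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 initial conditions", call. = FALSE)
  list(mean = mean(values),
       ci95 = stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n),
       n = n)
}

#' Cell-free layer thickness by vertical slices
#'
#' Averages, over evenly spaced x-stations, the vertical gap between the
#' outer edge of the cell core and the wall surface: in each slice the
#' bottom gap is the lowest cell point minus the local bottom-wall height,
#' the top gap the local top-wall height minus the highest cell point.
#' Slices containing no cell point are excluded from the average and
#' counted.
#'
#' @param cell_points List of `n` by 2 point matrices (one per cell), e.g.
#'   a snapshot from an `rbc_sim`, or an `rbc_sim` (steady-state snapshots
#'   past `steady_frac` of the run are pooled).
#' @param wall A `wall_geometry` or `NULL` for a bare channel.
#' @inheritParams body_force
#' @param n_slices Number of x-stations (800 in the reference protocol).
#' @param x_range Length-2 interval of x to scan (defaults to the central
#'   75% of the domain).
#' @param steady_frac When `cell_points` is a run, the fraction of the run
#'   treated as steady state (snapshots with `t >= steady_frac * t_end`).
#' @return A list with `top`, `bottom` (mean gaps), `mean` (their average),
#'   and `n_empty_slices`.
#' @export
cfl_thickness <- function(cell_points, wall, grid, n_slices = 800,
                          x_range = NULL, steady_frac = 0.75) {
  if (inherits(cell_points, "rbc_sim")) {
    sim <- cell_points
    if (!length(sim$snapshots)) stop("run stored no snapshots", call. = FALSE)
    tmax <- max(vapply(sim$snapshots, function(s) s$t, numeric(1L)))
    keep <- vapply(sim$snapshots, function(s) s$t >= steady_frac * tmax,
                   logical(1L))
    cell_points <- unlist(lapply(sim$snapshots[keep], `[[`, "cells"),
                          recursive = FALSE)
  }
  if (!length(cell_points)) stop("no cells to measure", call. = FALSE)
  if (is.null(x_range)) x_range <- c(0.125, 0.875) * grid$lx
  pts <- do.call(rbind, cell_points)
  px <- pts[, 1L] %% grid$lx
  py <- pts[, 2L]
  edges <- seq(x_range[1L], x_range[2L], length.out = n_slices + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  bin <- findInterval(px, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= n_slices
  lo <- tapply(py[inside], factor(bin[inside], levels = seq_len(n_slices)),
               min)
  hi <- tapply(py[inside], factor(bin[inside], levels = seq_len(n_slices)),
               max)
  nonempty <- !is.na(lo)
  if (!any(nonempty)) stop("all slices empty", call. = FALSE)
  wb <- wall_surface(wall, mids, "bottom", grid)
  wt <- wall_surface(wall, mids, "top", grid)
  bottom <- mean(pmax(0, lo[nonempty] - wb[nonempty]))
  top <- mean(pmax(0, wt[nonempty] - hi[nonempty]))
  list(top = top, bottom = bottom, mean = (top + bottom) / 2,
       n_empty_slices = sum(!nonempty))
}

#' Mean streamwise cell velocity
#'
#' Mean over cells of the x-displacement per unit time over a measurement
#' window (periodic x is already unwrapped because cell coordinates are
#' advected continuously), converted to mm/s through the grid's physical
#' length scale.
#'
#' @param x An `rbc_sim` object, or a data frame with columns `time`,
#'   `cell`, `comx`.
#' @inheritParams body_force
#' @param window Length-2 time interval; defaults to the second half of
#'   the record.
#' @return Mean cell velocity in mm/s.
#' @export
mean_rbc_velocity <- function(x, grid, window = NULL) {
  tb <- if (inherits(x, "rbc_sim")) x$observables else as.data.frame(x)
  if (!nrow(tb)) stop("no cell trajectories recorded", call. = FALSE)
  if (is.null(window)) window <- c(max(tb$time) / 2, max(tb$time))
  times <- sort(unique(tb$time))
  if (sum(times >= window[1L] & times <= window[2L]) < 2L) {
    stop("window shorter than one save interval", call. = FALSE)
  }
  vels <- vapply(split(tb, tb$cell), function(d) {
    d <- d[d$time >= window[1L] & d$time <= window[2L], , drop = FALSE]
    (d$comx[nrow(d)] - d$comx[1L]) / (d$time[nrow(d)] - d$time[1L])
  }, numeric(1L))
  mean(vels) * grid$length_scale_um * 1e-3   # model um/s -> mm/s
}

# scanline fill of a closed polygon onto pressure-cell centers;
# increments `acc` by 1 in covered cells (periodic wrap in x)
fill_polygon <- function(acc, poly, grid) {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  jlo <- max(1L, ceiling(min(y) / hy + 0.5))
  jhi <- min(ny, floor(max(y) / hy + 0.5))
  if (jhi < jlo) return(acc)
  for (j in jlo:jhi) {
    yj <- (j - 0.5) * hy
    cross <- ((y <= yj) & (yn > yj)) | ((yn <= yj) & (y > yj))
    if (!any(cross)) next
    xs <- sort(x[cross] + (yj - y[cross]) * (xn[cross] - x[cross]) /
                 (yn[cross] - y[cross]))
    npair <- length(xs) %/% 2L
    for (k in seq_len(npair)) {
      ia <- ceiling(xs[2L * k - 1L] / hx + 0.5)
      ib <- floor(xs[2L * k] / hx + 0.5)
      if (ib < ia) next
      ii <- ((ia:ib - 1L) %% nx) + 1L
      acc[ii, j] <- acc[ii, j] + 1
    }
  }
  acc
}

#' Time-averaged cell occupancy density map
#'
#' Accumulates the interior of every cell polygon on the Eulerian grid over
#' the saved snapshots past a burn-in time, normalized as the fraction of
#' time each grid cell is covered; the map integrates (times the cell
#' area element) to the mean total cell area.
#'
#' @param x An `rbc_sim` with snapshots, or a list of snapshots
#'   (`list(t = , cells = list-of-point-matrices)`).
#' @inheritParams body_force
#' @param burn_in Snapshots with `t < burn_in` are discarded.
#' @param kind Restrict to a cell kind (`"rbc"`, `"leukocyte"`) or `NULL`
#'   for all cells (requires `x` to be an `rbc_sim` for kind lookup).
#' @return An `nx` by `ny` occupancy matrix with attribute `integral`.
#' @export
density_map <- function(x, grid, burn_in = 0, kind = NULL) {
  snaps <- if (inherits(x, "rbc_sim")) x$snapshots else x
  kinds <- NULL
  if (!is.null(kind)) {
    if (!inherits(x, "rbc_sim")) stop("`kind` needs an rbc_sim", call. = FALSE)
    ob <- x$observables
    kinds <- ob$kind[ob$time == ob$time[1L]]
  }
  snaps <- Filter(function(s) s$t >= burn_in, snaps)
  if (!length(snaps)) stop("no snapshots past burn-in", call. = FALSE)
  acc <- matrix(0, grid$nx, grid$ny)
  for (s in snaps) {
    cl <- s$cells
    if (!is.null(kinds)) cl <- cl[kinds == kind]
    for (poly in cl) acc <- fill_polygon(acc, poly, grid)
  }
  acc <- acc / length(snaps)
  attr(acc, "integral") <- sum(acc) * grid$hx * grid$hy
  acc
}
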