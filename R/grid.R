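#' Create a staggered Eulerian grid for a periodic channel
#'
#' The computational domain is a rectangle `[0, lx) x [0, ly]`, periodic in
#' the flow (x) direction with no-slip walls at `y = 0` and `y = ly`.
#' Velocity components live on a MAC (marker-and-cell) staggering:
#' `u` on vertical cell faces, `v` on horizontal cell faces, pressure at
#' cell centers.
#'
#' @param nx,ny Number of grid cells in x and y (at least 8 each).
#' @param lx,ly Domain extents in model length units (1 model unit equals
#'   `length_scale_um` micrometers; default 1 um).
#' @param length_scale_um Physical micrometers per model length unit.
#' @return An object of class `rbc_grid`: a list with counts `nx`, `ny`,
#'   extents `lx`, `ly`, spacings `hx`, `hy`, coordinate vectors
#'   (`xu`, `yu` for u-points, `xv`, `yv` for v-points, `xp`, `yp` for
#'   pressure points) and `length_scale_um`.
#' @examples
#' g <- make_grid(64, 32, 4 * pi, 2 * pi)
#' g$hx
#' @export
make_grid <- function(nx, ny, lx, ly, length_scale_um = 1) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 8 || ny < 8 ||
      nx != round(nx) || ny != round(ny)) {
    stop("`nx` and `ny` must be integer grid counts >= 8", call. = FALSE)
  }
  if (!is.numeric(lx) || !is.numeric(ly) || lx <= 0 || ly <= 0) {
    stop("domain extents `lx` and `ly` must be positive", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  hx <- lx / nx
  hy <- ly / ny
  g <- list(
    nx = nx, ny = ny, lx = lx, ly = ly, hx = hx, hy = hy,
    # u[i, j] at ((i-1) hx, (j-1/2) hy), i = 1..nx, j = 1..ny
    xu = (seq_len(nx) - 1) * hx,
    yu = (seq_len(ny) - 0.5) * hy,
    # v[i, j] at ((i-1/2) hx, (j-1) hy), i = 1..nx, j = 1..(ny+1)
    # (first and last v rows sit on the walls and are identically 0)
    xv = (seq_len(nx) - 0.5) * hx,
    yv = (seq_len(ny + 1L) - 1) * hy,
    xp = (seq_len(nx) - 0.5) * hx,
    yp = (seq_len(ny) - 0.5) * hy,
    length_scale_um = length_scale_um
  )
  class(g) <- "rbc_grid"
  g
}

#' @export
print.rbc_grid <- function(x, ...) {
  cat(sprintf(
    "<rbc_grid> %d x %d cells on [0, %.4g) x [0, %.4g], h = (%.4g, %.4g)\n",
    x$nx, x$ny, x$lx, x$ly, x$hx, x$hy))
  invisible(x)
}

#' Sinusoidal body force driving the channel flow
#'
#' Returns the driving force density `(sin(pi * y / ly), 0)` evaluated at the
#' u-component grid locations; the y-component is identically zero. The
#' wall-normal coordinate is rescaled so the profile is a half-sine across
#' the channel for any height, which establishes a unidirectional flow in
#' the absence of immersed structures.
#'
#' @param grid An [make_grid()] object.
#' @param amplitude Force amplitude in model units (default 1).
#' @return A list with matrices `fu` (`nx` by `ny`) and `fv`
#'   (`nx` by `ny + 1`, all zero).
#' @export
body_force <- function(grid, amplitude = 1) {
  stopifnot(inherits(grid, "rbc_grid"))
  fu <- matrix(rep(amplitude * sin(pi * grid$yu / grid$ly), each = grid$nx),
               grid$nx, grid$ny)
  fv <- matrix(0, grid$nx, grid$ny + 1L)
  list(fu = fu, fv = fv)
}

#' Analytic steady channel-flow profile under the sinusoidal body force
#'
#' Closed-form steady solution of the Stokes equations with forcing
#' `(sin(pi y / ly), 0)` and no-slip walls:
#' `u(y) = (ly / pi)^2 sin(pi y / ly)`, `v = 0`. Used as an independent
#' oracle for the time-stepping solver.
#'
#' @inheritParams body_force
#' @return A list with matrices `u` and `v` on the staggered grid.
#' @export
steady_channel_solution <- function(grid, amplitude = 1) {
  stopifnot(inherits(grid, "rbc_grid"))
  prof <- amplitude * (grid$ly / pi)^2 * sin(pi * grid$yu / grid$ly)
  list(u = matrix(rep(prof, each = grid$nx), grid$nx, grid$ny),
       v = matrix(0, grid$nx, grid$ny + 1L))
}

#' Discrete divergence of a staggered velocity field
#'
#' @param u,v Staggered velocity component matrices (`nx` by `ny` and
#'   `nx` by `ny + 1`).
#' @inheritParams body_force
#' @return An `nx` by `ny` matrix of cell-centered divergence values.
#' @export
divergence <- function(u, v, grid) {
  du <- (u[c(2:grid$nx, 1L), , drop = FALSE] - u) / grid$hx
  dv <- (v[, 2:(grid$ny + 1L), drop = FALSE] -
           v[, 1:grid$ny, drop = FALSE]) / grid$hy
  du + dv
}

#' Initialize a fluid state at rest
#'
#' @inheritParams body_force
#' @return An object of class `rbc_fluid`: list with `u`, `v`, `p`
#'   matrices and time `t`.
#' @export
fluid_rest <- function(grid) {
  st <- list(u = matrix(0, grid$nx, grid$ny),
             v = matrix(0, grid$nx, grid$ny + 1L),
             p = matrix(0, grid$nx, grid$ny),
             t = 0)
  class(st) <- "rbc_fluid"
  st
}
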