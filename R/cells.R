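#' Biconcave red blood cell contour
#'
#' Generates a closed, counter-clockwise biconcave contour from the
#' classical Evans-Fung cross-section profile
#' `T(rho) = sqrt(1 - rho^2) (c0 + c1 rho^2 + c2 rho^4)`, rescaled so the
#' major axis is `8 * scale` and the maximum thickness `2 * scale` model
#' micrometers (the physiological 8 um x 2 um resting dimensions at
#' `scale = 1`). Points are spaced uniformly in arclength, the contour is
#' mirror-symmetric about both principal axes before rotation, and the
#' chain's `dq` equals the point spacing so the undeformed shape is at unit
#' stretch.
#'
#' @param center Length-2 numeric: cell center.
#' @param orientation_deg Rotation of the major axis (degrees,
#'   counter-clockwise; single-cell sweeps start at 30).
#' @param n_points Number of membrane points (>= 16; rounded up to even).
#' @param scale Geometric scale factor (1 = physiological size).
#' @return A [lag_points()] closed chain.
#' @export
biconcave_rbc <- function(center = c(0, 0), orientation_deg = 0,
                          n_points = 128, scale = 1) {
  if (n_points < 16L) stop("`n_points` must be >= 16", call. = FALSE)
  n_points <- 2L * ceiling(n_points / 2)
  c0 <- 0.81; c1 <- 7.83; c2 <- -4.39        # Evans-Fung profile shape
  thick <- function(rho) sqrt(pmax(0, 1 - rho^2)) * (c0 + c1 * rho^2 + c2 * rho^4)
  # fine half-contour (upper branch), cosine-clustered near the tips
  th <- seq(0, pi, length.out = 4001L)
  rho <- cos(th)
  tmax <- max(thick(seq(0, 1, by = 1e-4)))
  xh <- 4 * scale * rho                       # half-diameter 4*scale
  yh <- (scale / tmax) * thick(rho)           # max half-thickness 1*scale
  # uniform-arclength resample of the half contour, then mirror
  s <- c(0, cumsum(sqrt(diff(xh)^2 + diff(yh)^2)))
  m <- n_points %/% 2L
  se <- seq(0, s[length(s)], length.out = m + 1L)
  xs <- stats::approx(s, xh, xout = se)$y
  ys <- stats::approx(s, yh, xout = se)$y
  ys[c(1L, m + 1L)] <- 0
  x <- c(xs, rev(xs[2:m]))
  y <- c(ys, -rev(ys[2:m]))
  # close to uniform spacing around the full loop; use mean spacing as dq
  per <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  a <- orientation_deg * pi / 180
  xr <- x * cos(a) - y * sin(a) + center[1L]
  yr <- x * sin(a) + y * cos(a) + center[2L]
  lag_points(xr, yr, dq = per / n_points, closed = TRUE)
}

#' Circular cell contour (leukocyte or control circle)
#'
#' Regular n-gon approximation of a circle: leukocytes are circles of
#' radius 6 um; a control circle with the same enclosed area as the
#' biconcave cell is used for shape-effect controls.
#'
#' @param center Length-2 numeric: cell center.
#' @param radius Circle radius (> 0).
#' @param n_points Number of boundary points.
#' @return A [lag_points()] closed chain (counter-clockwise).
#' @export
circle_cell <- function(center = c(0, 0), radius = 6, n_points = 128) {
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  x <- center[1L] + radius * cos(th)
  y <- center[2L] + radius * sin(th)
  side <- 2 * radius * sin(pi / n_points)
  lag_points(x, y, dq = side, closed = TRUE)
}

#' Specify a cell for placement
#'
#' @param kind One of `"rbc"`, `"leukocyte"`, `"control_circle"`.
#' @param center,orientation_deg,n_points,scale,radius Geometry of the cell.
#' @param params A [membrane_params()] object; defaults to the RBC constants
#'   for `"rbc"` and the stiffer leukocyte constants (`ks = 30`, `kb = 2`)
#'   otherwise.
#' @return A list of class `cell_spec` with the realized chain in `$pts`.
#' @export
cell_spec <- function(kind = c("rbc", "leukocyte", "control_circle"),
                      center = c(0, 0), orientation_deg = 0, n_points = 128,
                      scale = 1, radius = 6, params = NULL) {
  kind <- match.arg(kind)
  pts <- switch(kind,
    rbc = biconcave_rbc(center, orientation_deg, n_points, scale),
    leukocyte = circle_cell(center, radius, n_points),
    control_circle = circle_cell(center, radius, n_points))
  if (is.null(params)) {
    # bending rigidity carries a length^2 relative to stretching, so a
    # geometrically reduced cell keeps its shape dynamics when kb scales
    # with the square of its linear size
    params <- if (kind == "rbc") {
      membrane_params(ks = 3, kb = 0.2 * scale^2, ka = 185)
    } else {
      membrane_params(ks = 30, kb = 2, ka = 185)
    }
  }
  params$a0 <- polygon_area(pts)
  params$ref_length <- length(pts) * pts$dq
  structure(list(kind = kind, center = center,
                 orientation_deg = orientation_deg, n_points = length(pts),
                 scale = scale, radius = radius, params = params, pts = pts),
            class = "cell_spec")
}

# minimum clearance of a point cloud above/below the wall surfaces
wall_clearance <- function(x, y, wall, grid) {
  if (is.null(wall)) {
    return(min(y, grid$ly - y))
  }
  xs <- x %% grid$lx
  bot <- wall_surface(wall, xs, "bottom", grid)
  top <- wall_surface(wall, xs, "top", grid)
  min(y - bot, top - y)
}

#' Place cells uniformly without overlap
#'
#' Rejection-samples cell centers uniformly over a rectangular region,
#' keeping every membrane point at least `min_gap` away from the wall
#' surfaces and from previously placed cells. Placement is deterministic
#' given `seed`. Leukocytes are placed first (they are larger), with
#' random orientations for the biconcave cells.
#'
#' @param region Numeric length-4: `c(xmin, xmax, ymin, ymax)`.
#' @param n_rbc,n_leuko Cell counts (48 RBCs and 2 leukocytes in the
#'   healthy full-scale reference).
#' @param seed Integer seed controlling the placement.
#' @param min_gap Minimum clearance (model um); at least 4 Eulerian cells
#'   from the walls by default.
#' @param wall A `wall_geometry` or `NULL` for a bare channel.
#' @inheritParams body_force
#' @param rbc_scale,rbc_n_points,leuko_radius,leuko_n_points Cell geometry.
#' @param max_tries Proposal attempts per cell before giving up.
#' @return A list of [cell_spec()] objects.
#' @export
place_cells <- function(region, n_rbc, n_leuko = 0, seed = 1,
                        min_gap = NULL, wall = NULL, grid,
                        rbc_scale = 1, rbc_n_points = 128,
                        leuko_radius = 6, leuko_n_points = 160,
                        max_tries = 400L) {
  stopifnot(inherits(grid, "rbc_grid"))
  if (is.null(min_gap)) min_gap <- 4 * max(grid$hx, grid$hy)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cells <- list()
  kinds <- c(rep("leukocyte", n_leuko), rep("rbc", n_rbc))
  for (ki in seq_along(kinds)) {
    kind <- kinds[ki]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, region[1L], region[2L])
      cy <- stats::runif(1, region[3L], region[4L])
      ang <- stats::runif(1, 0, 180)
      sp <- if (kind == "rbc") {
        cell_spec("rbc", c(cx, cy), ang, rbc_n_points, scale = rbc_scale)
      } else {
        cell_spec("leukocyte", c(cx, cy), 0, leuko_n_points,
                  radius = leuko_radius)
      }
      if (wall_clearance(sp$pts$x, sp$pts$y, wall, grid) < min_gap) next
      ok <- TRUE
      for (other in cells) {
        dx <- outer(sp$pts$x, other$pts$x, `-`)
        dx <- dx - round(dx / grid$lx) * grid$lx
        dy <- outer(sp$pts$y, other$pts$y, `-`)
        if (min(dx^2 + dy^2) < min_gap^2) { ok <- FALSE; break }
      }
      if (ok) { cells[[length(cells) + 1L]] <- sp; placed <- TRUE; break }
    }
    if (!placed) {
      stop(sprintf("cell packing failed: placed %d of %d cells",
                   length(cells), length(kinds)), call. = FALSE)
    }
  }
  cells
}

#' Drop cells that lie outside the wall-bounded region
#'
#' Used to derive low-density scenarios: the initial cell set of a wider
#' (healthy) geometry is reused and cells with any point outside the region
#' enclosed by a narrower wall are removed.
#'
#' @param cells List of [cell_spec()] objects.
#' @param wall A `wall_geometry`.
#' @inheritParams body_force
#' @param margin Extra clearance required inside the wall surfaces.
#' @return The filtered list of cells.
#' @export
filter_cells_inside <- function(cells, wall, grid, margin = 0) {
  keep <- vapply(cells, function(sp) {
    wall_clearance(sp$pts$x, sp$pts$y, wall, grid) >= margin
  }, logical(1L))
  cells[keep]
}

#' Phase offsets for initial-condition averaging
#'
#' Lift and drag are averaged over initial conditions that uniformly sample
#' the wall's spatial period: the gap between neighboring bundle roots for
#' the microscopic model, or one wavelength of the sine for the macroscopic
#' model. The offsets are applied to the cell's initial x-position.
#'
#' @param wall A `wall_geometry`.
#' @param count Number of initial conditions (4 in the reference protocol).
#' @param period Override period for polyline walls (otherwise unsupported).
#' @return Numeric vector of x-offsets.
#' @export
phase_offsets <- function(wall, count = 4, period = NULL) {
  stopifnot(inherits(wall, "wall_geometry"))
  if (is.null(period)) {
    period <- switch(wall$descriptor$model,
      micro = wall$descriptor$root_gap,
      macro = wall$descriptor$wavelength,
      stop("polyline walls have no natural period; supply `period`",
           call. = FALSE))
  }
  period * (seq_len(count) - 1L) / count
}

#' Height of the wall surface at given x stations
#'
#' For the bottom wall, the layer's upper envelope height above the floor;
#' for the top wall, the layer's lower envelope height (absolute y).
#' Macroscopic and polyline walls evaluate the sampled curve; microscopic
#' walls use the bundle thickness as a constant envelope.
#'
#' @param wall A `wall_geometry` or `NULL` (bare channel: surfaces at 0 and
#'   `ly`).
#' @param x X stations (model units, wrapped periodically).
#' @param side `"bottom"` or `"top"`.
#' @inheritParams body_force
#' @return Numeric vector of surface heights.
#' @export
wall_surface <- function(wall, x, side = c("bottom", "top"), grid) {
  side <- match.arg(side)
  if (is.null(wall)) {
    return(rep(if (side == "bottom") 0 else grid$ly, length(x)))
  }
  x <- x %% grid$lx
  if (wall$descriptor$model == "micro") {
    h <- wall$thickness
    return(rep(if (side == "bottom") h else grid$ly - h, length(x)))
  }
  b <- (if (side == "bottom") wall$bottom else wall$top)[[1L]]
  tg <- b$targets
  ord <- order(tg[, 1L])
  xs <- tg[ord, 1L]; ys <- tg[ord, 2L]
  xs <- c(xs, xs[1L] + grid$lx); ys <- c(ys, ys[1L])
  stats::approx(xs, ys, xout = x, rule = 2)$y
}
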