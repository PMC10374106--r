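#' Linear tether force toward static target points
#'
#' Wall structures are anchored by stiff springs to time-independent tether
#' targets: `F = -k_tether (X - Z)` per point.
#'
#' @param pts A [lag_points()] chain.
#' @param targets `n` by 2 matrix of target positions `Z`.
#' @param k_tether Tether spring constant (model units; default 3200).
#' @return An `n` by 2 matrix of force densities.
#' @export
tether_force <- function(pts, targets, k_tether = 3200) {
  targets <- matrix(targets, ncol = 2L)
  if (nrow(targets) != length(pts$x)) {
    stop("`pts` and `targets` lengths differ", call. = FALSE)
  }
  -k_tether * cbind(pts$x - targets[, 1L], pts$y - targets[, 2L])
}

# local stretch ||dX/dq|| per point (centered differences, one-sided at
# open-fiber ends); used as the metric in the Darcy slip
lag_metric <- function(pts) {
  n <- length(pts$x)
  if (pts$closed) {
    xp <- c(pts$x[-1L], pts$x[1L] + pts$xperiod)
    yp <- c(pts$y[-1L], pts$y[1L])
    xm <- c(pts$x[n] - pts$xperiod, pts$x[-n])
    ym <- c(pts$y[n], pts$y[-n])
    sqrt((xp - xm)^2 + (yp - ym)^2) / (2 * pts$dq)
  } else {
    xp <- c(pts$x[2L], pts$x[3:n], pts$x[n])
    xm <- c(pts$x[1L], pts$x[1:(n - 2L)], pts$x[n - 1L])
    yp <- c(pts$y[2L], pts$y[3:n], pts$y[n])
    ym <- c(pts$y[1L], pts$y[1:(n - 2L)], pts$y[n - 1L])
    den <- c(1, rep(2, n - 2L), 1) * pts$dq
    sqrt((xp - xm)^2 + (yp - ym)^2) / den
  }
}

# unit normals of a wall curve, pointing into the channel interior,
# computed from the (static) tether-target polyline by rotating the tangent
curve_normals <- function(targets, side, xperiod = 0) {
  n <- nrow(targets)
  xp <- c(targets[-1L, 1L], targets[1L, 1L] + xperiod)
  xm <- c(targets[n, 1L] - xperiod, targets[-n, 1L])
  yp <- c(targets[-1L, 2L], targets[1L, 2L])
  ym <- c(targets[n, 2L], targets[-n, 2L])
  tx <- xp - xm; ty <- yp - ym
  nn <- sqrt(tx^2 + ty^2)
  if (side == "bottom") cbind(-ty / nn, tx / nn) else cbind(ty / nn, -tx / nn)
}

new_wall_body <- function(pts, targets, tethered, normals, side) {
  list(pts = pts, targets = matrix(targets, ncol = 2L),
       tethered = tethered, normals = normals, side = side)
}

new_wall_geometry <- function(bottom, top, descriptor, thickness, k_tether,
                              ks_esl, kb_esl, kp) {
  structure(list(bottom = bottom, top = top, descriptor = descriptor,
                 thickness = thickness, k_tether = k_tether,
                 ks_esl = ks_esl, kb_esl = kb_esl, kp = kp),
            class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf("<wall_geometry> %s model, thickness %.4g, kp = %g, %d + %d structures\n",
              x$descriptor$model, x$thickness, x$kp,
              length(x$bottom), length(x$top)))
  invisible(x)
}

#' Microscopic fiber-bundle wall (brush-like endothelial surface layer)
#'
#' Builds the microscopic ESL representation: `n_bundles` evenly spaced
#' bundles per wall, each a fan of open elastic fibers sharing a tethered
#' root on the domain boundary, with all fiber tips at the layer height `h`
#' (so the wall thickness equals the maximum bundle height). The top wall
#' mirrors the bottom wall. The bundle-density label is `n_bundles / 2`,
#' matching the convention that 10 bundles correspond to the healthy
#' density 5 and 2 bundles to the septic extreme 1; the geometric inverse
#' root distance is recorded alongside.
#'
#' @param n_bundles Number of bundles per wall (>= 2).
#' @param fibers_per_bundle Fibers in each fan (>= 1; 5 for a healthy ESL).
#' @param h Layer thickness: maximum bundle height (model um; tabled range
#'   0.8464 to 1.7696).
#' @inheritParams body_force
#' @param fan_half_angle_deg Half-opening of the fiber fan (degrees).
#' @param k_tether,ks_esl,kb_esl Wall elastic constants (model units).
#' @param kp Porosity constant (0 for impermeable).
#' @return A `wall_geometry` object.
#' @export
build_micro_wall <- function(n_bundles, fibers_per_bundle, h, grid,
                             fan_half_angle_deg = 30,
                             k_tether = 3200, ks_esl = 0.015, kb_esl = 0.001,
                             kp = 0) {
  stopifnot(inherits(grid, "rbc_grid"))
  if (n_bundles < 2L) stop("`n_bundles` must be >= 2", call. = FALSE)
  if (fibers_per_bundle < 1L) stop("`fibers_per_bundle` must be >= 1", call. = FALSE)
  if (h >= grid$ly / 2) stop("layer thickness `h` >= half channel: walls overlap",
                             call. = FALSE)
  dq <- min(grid$hx, grid$hy) / 2
  roots <- (seq_len(n_bundles) - 0.5) * grid$lx / n_bundles
  angles <- if (fibers_per_bundle == 1L) 0 else
    seq(-fan_half_angle_deg, fan_half_angle_deg,
        length.out = fibers_per_bundle) * pi / 180
  make_side <- function(side) {
    bodies <- list()
    for (rx in roots) {
      for (a in angles) {
        len <- h / cos(a)                  # tip height exactly h
        npts <- max(3L, ceiling(len / dq) + 1L)
        ss <- seq(0, len, length.out = npts)
        if (side == "bottom") {
          pts <- lag_points(rx + ss * sin(a), ss * cos(a),
                            dq = len / (npts - 1L), closed = FALSE)
          nrm <- matrix(rep(c(0, 1), each = npts), npts, 2L)
        } else {
          pts <- lag_points(rx + ss * sin(a), grid$ly - ss * cos(a),
                            dq = len / (npts - 1L), closed = FALSE)
          nrm <- matrix(rep(c(0, -1), each = npts), npts, 2L)
        }
        tg <- cbind(pts$x, pts$y)
        teth <- c(TRUE, rep(FALSE, npts - 1L))   # only the root is tethered
        bodies[[length(bodies) + 1L]] <- new_wall_body(pts, tg, teth, nrm, side)
      }
    }
    bodies
  }
  new_wall_geometry(
    bottom = make_side("bottom"), top = make_side("top"),
    descriptor = list(model = "micro", n_bundles = n_bundles,
                      fibers_per_bundle = fibers_per_bundle, h = h,
                      density_label = n_bundles / 2,
                      inverse_root_distance = n_bundles / grid$lx,
                      root_gap = grid$lx / n_bundles),
    thickness = h, k_tether = k_tether, ks_esl = ks_esl, kb_esl = kb_esl,
    kp = kp)
}

# sample a bottom-wall height function y(x) at the Lagrangian spacing and
# build the tethered periodic curve bodies for both walls
sampled_wall_geometry <- function(yfun, grid, descriptor, thickness,
                                  k_tether, ks_esl, kb_esl, kp,
                                  align = 1L) {
  dq_target <- min(grid$hx, grid$hy) / 2
  xs_fine <- seq(0, grid$lx, length.out = 4096L)
  ys_fine <- yfun(xs_fine)
  arclen <- sum(sqrt(diff(xs_fine)^2 + diff(ys_fine)^2))
  n <- max(8L, ceiling(arclen / dq_target))
  # align the sample count so wave crests are sampled exactly
  if (align > 1L) n <- as.integer(align * ceiling(n / align))
  xs <- (seq_len(n) - 1L) * grid$lx / n
  ys <- yfun(xs)
  dq <- arclen / n
  make_side <- function(side) {
    yy <- if (side == "bottom") ys else grid$ly - ys
    pts <- lag_points(xs, yy, dq = dq, closed = TRUE, xperiod = grid$lx)
    tg <- cbind(xs, yy)
    new_wall_body(pts, tg, rep(TRUE, n), curve_normals(tg, side, grid$lx), side)
  }
  new_wall_geometry(bottom = list(make_side("bottom")),
                    top = list(make_side("top")),
                    descriptor = descriptor, thickness = thickness,
                    k_tether = k_tether, ks_esl = ks_esl, kb_esl = kb_esl,
                    kp = kp)
}

#' Macroscopic sinusoidal wall (coarse-grained endothelial surface layer)
#'
#' Coarse-grains the layer into the continuous wave
#' `y(x) = A sin(a x) + h` with `a = 2 pi frequency_label / lx`, sampled at
#' the Lagrangian spacing measured along arclength. Every wall point is
#' tethered to its initial position. The top wall is the mirror image about
#' the channel centerline, and the wall thickness is `A + h`.
#'
#' @param amplitude Sine amplitude `A` (>= 0; 0.336 in the reference setup).
#' @param frequency_label Integer number of sine periods across the domain
#'   (1 to 10 in the reference sweeps); non-integer values would break the
#'   x-periodicity and are rejected.
#' @param h_offset Vertical offset `h`; the layer thickness is
#'   `amplitude + h_offset`.
#' @inheritParams build_micro_wall
#' @return A `wall_geometry` object.
#' @export
build_macro_wall <- function(amplitude, frequency_label, h_offset, grid,
                             k_tether = 3200, ks_esl = 0.015, kb_esl = 0.001,
                             kp = 0) {
  stopifnot(inherits(grid, "rbc_grid"))
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (abs(frequency_label - round(frequency_label)) > 1e-9) {
    stop("`frequency_label` must be an integer (periodic wall)", call. = FALSE)
  }
  if (amplitude + h_offset >= grid$ly / 2) {
    stop("wall thickness >= half channel: walls overlap", call. = FALSE)
  }
  a <- 2 * pi * round(frequency_label) / grid$lx
  sampled_wall_geometry(
    align = max(1L, 4L * as.integer(round(frequency_label))),
    yfun = function(x) amplitude * sin(a * x) + h_offset,
    grid = grid,
    descriptor = list(model = "macro", amplitude = amplitude,
                      frequency_label = round(frequency_label),
                      h_offset = h_offset, wave_number = a,
                      wavelength = if (frequency_label > 0)
                        grid$lx / round(frequency_label) else Inf),
    thickness = amplitude + h_offset,
    k_tether = k_tether, ks_esl = ks_esl, kb_esl = kb_esl, kp = kp)
}

#' Import wall geometry from two-column polylines
#'
#' Builds walls from user-supplied `(x, y)` polylines (e.g. traced from
#' intravital microscopy images), one per wall. The polylines must be
#' graphs over x: strictly increasing x covering `[0, lx]`, with y inside
#' the channel. Each is resampled at the Lagrangian spacing; the sampled
#' points become the tether targets. If `top` is omitted the bottom wall is
#' mirrored.
#'
#' @param bottom,top Two-column matrices/data frames or paths to CSV files
#'   with columns x and y (model length units).
#' @inheritParams build_micro_wall
#' @return A `wall_geometry` object.
#' @export
load_wall_polyline <- function(bottom, top = NULL, grid,
                               k_tether = 3200, ks_esl = 0.015, kb_esl = 0.001,
                               kp = 0) {
  stopifnot(inherits(grid, "rbc_grid"))
  read_poly <- function(src) {
    if (is.character(src)) src <- utils::read.csv(src)
    m <- as.matrix(src)[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    if (any(diff(m[, 1L]) <= 0)) {
      stop("polyline x must be strictly increasing", call. = FALSE)
    }
    if (m[1L, 1L] > 1e-9 || m[nrow(m), 1L] < grid$lx - 1e-9) {
      stop("polyline must cover [0, lx]", call. = FALSE)
    }
    if (any(m[, 2L] <= 0) || any(m[, 2L] >= grid$ly)) {
      stop("polyline y must lie inside (0, ly)", call. = FALSE)
    }
    m
  }
  pb <- read_poly(bottom)
  fb <- stats::approxfun(pb[, 1L], pb[, 2L], rule = 2)
  if (is.null(top)) {
    yfun_top <- NULL
  } else {
    pt <- read_poly(top)
    # the stored polyline gives the top wall surface height directly
    ft <- stats::approxfun(pt[, 1L], pt[, 2L], rule = 2)
    yfun_top <- function(x) grid$ly - ft(x)   # mirror convention of builder
  }
  w <- sampled_wall_geometry(
    yfun = fb, grid = grid,
    descriptor = list(model = "polyline"),
    thickness = max(pb[, 2L]),
    k_tether = k_tether, ks_esl = ks_esl, kb_esl = kb_esl, kp = kp)
  if (!is.null(yfun_top)) {
    dq_target <- min(grid$hx, grid$hy) / 2
    xs_fine <- seq(0, grid$lx, length.out = 4096L)
    ys_fine <- ft(xs_fine)
    arclen <- sum(sqrt(diff(xs_fine)^2 + diff(ys_fine)^2))
    n <- max(8L, ceiling(arclen / dq_target))
    xs <- (seq_len(n) - 1L) * grid$lx / n
    yy <- ft(xs)
    pts <- lag_points(xs, yy, dq = arclen / n, closed = TRUE, xperiod = grid$lx)
    tg <- cbind(xs, yy)
    w$top <- list(new_wall_body(pts, tg, rep(TRUE, n),
                                curve_normals(tg, "top", grid$lx), "top"))
  }
  w
}

#' Export wall geometry back to polyline tables
#'
#' @param wall A `wall_geometry` object.
#' @return A list with tibbles `bottom` and `top` of the tether-target
#'   polylines (`x`, `y`).
#' @export
wall_polylines <- function(wall) {
  stopifnot(inherits(wall, "wall_geometry"))
  side_tbl <- function(bodies) {
    tg <- do.call(rbind, lapply(bodies, function(b) b$targets))
    tibble::tibble(x = tg[, 1L], y = tg[, 2L])
  }
  list(bottom = side_tbl(wall$bottom), top = side_tbl(wall$top))
}

# elastic + tether force densities on one wall body
wall_body_force <- function(body, wall) {
  pm <- membrane_params(ks = wall$ks_esl, kb = wall$kb_esl, ka = 0, a0 = 1)
  Fel <- stretch_force(body$pts, pm) + bend_force(body$pts, pm)
  Ft <- matrix(0, length(body$pts$x), 2L)
  if (any(body$tethered)) {
    ftt <- tether_force(body$pts, body$targets, wall$k_tether)
    Ft[body$tethered, ] <- ftt[body$tethered, , drop = FALSE]
  }
  list(elastic = Fel, tether = Ft, total = Fel + Ft)
}

#' Elastic and tether force densities on all wall points
#'
#' Microscopic walls carry fiber stretching and bending with the ESL
#' constants plus a tether force at each bundle root; macroscopic and
#' polyline walls carry the curve elasticity plus a tether force at every
#' point.
#'
#' @param wall A `wall_geometry` object.
#' @return A list with elements `bottom` and `top`, each a list (one entry
#'   per wall structure) of lists with `elastic`, `tether` and `total`
#'   `n` by 2 force-density matrices.
#' @export
wall_elastic_force <- function(wall) {
  stopifnot(inherits(wall, "wall_geometry"))
  list(bottom = lapply(wall$bottom, wall_body_force, wall = wall),
       top = lapply(wall$top, wall_body_force, wall = wall))
}

#' Measured thickness of a wall geometry
#'
#' Maximum height of the bottom wall points above the channel floor (and,
#' symmetrically, depth of the top wall below the ceiling); for a freshly
#' built wall this equals the configured thickness.
#'
#' @param wall A `wall_geometry` object.
#' @param grid The grid the wall was built on.
#' @return Named vector with `bottom` and `top` measured thicknesses.
#' @export
wall_measured_thickness <- function(wall, grid) {
  bot <- max(unlist(lapply(wall$bottom, function(b) b$pts$y)))
  top <- grid$ly - min(unlist(lapply(wall$top, function(b) b$pts$y)))
  c(bottom = bot, top = top)
}
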