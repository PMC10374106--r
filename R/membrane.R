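#' Elastic parameters of a cell membrane
#'
#' Model-unit elastic constants for a closed membrane: stretching stiffness
#' `ks` (tabled value 3 for red blood cells, 30 for leukocytes), bending
#' stiffness `kb` (0.2 for RBCs, 2 for leukocytes in the model bending
#' unit), area-penalty constant `ka` (185), target enclosed area `a0`, and
#' reference perimeter `ref_length`. The model unit system is micrometers,
#' seconds and a stretch-stiffness unit of 1 uN/m (see the package
#' vignette for the conversion of the physical constants).
#'
#' @param ks,kb,ka Nonnegative elastic constants (model units).
#' @param a0 Target enclosed area, > 0.
#' @param ref_length Reference perimeter of the undeformed shape.
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(ks = 3, kb = 0.2, ka = 185, a0 = NULL,
                            ref_length = NULL) {
  if (any(c(ks, kb, ka) < 0)) stop("elastic constants must be >= 0", call. = FALSE)
  if (!is.null(a0) && a0 <= 0) stop("`a0` must be > 0", call. = FALSE)
  structure(list(ks = ks, kb = kb, ka = ka, a0 = a0, ref_length = ref_length),
            class = "membrane_params")
}

# Segment vectors X_{i+1} - X_i of a chain; for a closed chain the last
# segment wraps (with the x-period shift for wall curves that span the
# periodic direction). Open chains return n-1 segments.
chain_segments <- function(pts) {
  n <- length(pts$x)
  if (pts$closed) {
    xn <- c(pts$x[-1L], pts$x[1L] + pts$xperiod)
    yn <- c(pts$y[-1L], pts$y[1L])
    cbind(xn - pts$x, yn - pts$y)
  } else {
    cbind(diff(pts$x), diff(pts$y))
  }
}

# Second differences C_i = (X_{i+1} - 2 X_i + X_{i-1}) / dq^2, defined on
# all points of a closed chain and on interior points of an open fiber.
chain_curvature <- function(pts) {
  n <- length(pts$x)
  if (pts$closed) {
    xp <- c(pts$x[-1L], pts$x[1L] + pts$xperiod)
    yp <- c(pts$y[-1L], pts$y[1L])
    xm <- c(pts$x[n] - pts$xperiod, pts$x[-n])
    ym <- c(pts$y[n], pts$y[-n])
    cbind(xp - 2 * pts$x + xm, yp - 2 * pts$y + ym) / pts$dq^2
  } else {
    i <- 2:(n - 1L)
    cbind(pts$x[i + 1L] - 2 * pts$x[i] + pts$x[i - 1L],
          pts$y[i + 1L] - 2 * pts$y[i] + pts$y[i - 1L]) / pts$dq^2
  }
}

#' Discrete elastic energies of a point chain
#'
#' Stretching energy `ks/2 * integral (||dX/dq|| - 1)^2 dq` (springs with
#' unit rest stretch), bending energy `kb/2 * integral ||d2X/dq2||^2 dq`
#' (no reference curvature), and area penalty `ka/2 (A - A0)^2` for closed
#' chains.
#'
#' @param pts A [lag_points()] chain.
#' @param params A [membrane_params()] object.
#' @param term One of `"total"`, `"stretch"`, `"bend"`, `"area"`.
#' @return Scalar energy in model units.
#' @export
cell_energy <- function(pts, params, term = c("total", "stretch", "bend", "area")) {
  term <- match.arg(term)
  e <- 0
  if (term %in% c("total", "stretch")) {
    seg <- chain_segments(pts)
    s <- sqrt(rowSums(seg^2)) / pts$dq - 1
    e <- e + params$ks / 2 * sum(s^2) * pts$dq
  }
  if (term %in% c("total", "bend")) {
    cc <- chain_curvature(pts)
    e <- e + params$kb / 2 * sum(rowSums(cc^2)) * pts$dq
  }
  if (term %in% c("total", "area") && pts$closed && pts$xperiod == 0) {
    a <- polygon_area(pts)
    e <- e + params$ka / 2 * (a - params$a0)^2
  }
  e
}

#' Stretching force density of the membrane springs
#'
#' Minus the gradient of the discrete stretching energy with respect to the
#' point positions, returned as force per unit Lagrangian coordinate.
#' Zero when the chain is everywhere at unit local stretch.
#'
#' @inheritParams cell_energy
#' @return An `n` by 2 matrix of force densities.
#' @export
stretch_force <- function(pts, params) {
  n <- length(pts$x)
  if (pts$closed && n < 4L) stop("need at least 4 points", call. = FALSE)
  seg <- chain_segments(pts)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("coincident adjacent points", call. = FALSE)
  s <- len / pts$dq - 1
  tx <- params$ks * s * seg[, 1L] / len
  ty <- params$ks * s * seg[, 2L] / len
  if (pts$closed) {
    txm <- c(tx[n], tx[-n]); tym <- c(ty[n], ty[-n])
    cbind(tx - txm, ty - tym) / pts$dq
  } else {
    cbind(c(tx, 0) - c(0, tx), c(ty, 0) - c(0, ty)) / pts$dq
  }
}

#' Bending force density of the membrane
#'
#' Minus the gradient of the discrete bending energy (second-difference
#' curvature, no reference curvature). Equally spaced collinear points
#' experience zero bending force.
#'
#' @inheritParams cell_energy
#' @return An `n` by 2 matrix of force densities.
#' @export
bend_force <- function(pts, params) {
  n <- length(pts$x)
  cc <- chain_curvature(pts)
  if (pts$closed) {
    ccp <- cc[c(2:n, 1L), , drop = FALSE]
    ccm <- cc[c(n, 1:(n - 1L)), , drop = FALSE]
    -(params$kb / pts$dq^2) * (ccp - 2 * cc + ccm)
  } else {
    # pad C with zeros at the ends (the energy has no end terms)
    cfull <- rbind(0, cc, 0)
    ccp <- rbind(cfull[-1L, , drop = FALSE], 0)
    ccm <- rbind(0, cfull[-n, , drop = FALSE])
    -(params$kb / pts$dq^2) * (ccp - 2 * cfull + ccm)
  }
}

#' Enclosed (shoelace) area of a closed chain
#'
#' @inheritParams cell_energy
#' @return Positive area; an error is raised for clockwise orientation.
#' @export
polygon_area <- function(pts) {
  if (!pts$closed) stop("area requires a closed chain", call. = FALSE)
  x <- pts$x; y <- pts$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  a <- sum(x * yn - xn * y) / 2
  if (a <= 0) stop("chain must be counter-clockwise (positive area)", call. = FALSE)
  a
}

#' Area-penalty force density
#'
#' Minus the gradient of `ka/2 (A - A0)^2`; restores the enclosed area
#' toward the target `a0`. Vanishes when `A == a0`.
#'
#' @inheritParams cell_energy
#' @return An `n` by 2 matrix of force densities.
#' @export
area_force <- function(pts, params) {
  a <- polygon_area(pts)
  n <- length(pts$x)
  x <- pts$x; y <- pts$y
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  dax <- (y[ip] - y[im]) / 2
  day <- (x[im] - x[ip]) / 2
  -(params$ka / pts$dq) * (a - params$a0) * cbind(dax, day)
}

#' Total elastic force density on a cell membrane
#'
#' Sum of the stretching, bending, and area-penalty force densities; this
#' is the Lagrangian force spread onto the fluid for each cell.
#'
#' @inheritParams cell_energy
#' @return An `n` by 2 matrix of force densities.
#' @export
total_cell_force <- function(pts, params) {
  stretch_force(pts, params) + bend_force(pts, params) +
    area_force(pts, params)
}
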