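#' The 4-point regularized delta kernel
#'
#' One-dimensional Peskin 4-point kernel used to transfer forces and
#' velocities between Lagrangian structure points and the Eulerian grid.
#' It is nonnegative, supported on `|r| < 2`, sums to one over integer
#' translates, and has a vanishing first moment.
#'
#' @param r Dimensionless offset(s) in grid units.
#' @return Kernel weight(s), same length as `r`.
#' @examples
#' peskin_delta(0)       # 0.5
#' peskin_delta(2.3)     # 0
#' @export
peskin_delta <- function(r) {
  a <- abs(r)
  w <- a
  w[] <- 0
  i1 <- a < 1
  w[i1] <- (3 - 2 * a[i1] + sqrt(pmax(0, 1 + 4 * a[i1] - 4 * a[i1]^2))) / 8
  i2 <- a >= 1 & a < 2
  w[i2] <- (5 - 2 * a[i2] - sqrt(pmax(0, -7 + 12 * a[i2] - 4 * a[i2]^2))) / 8
  w
}

#' Create a Lagrangian point chain
#'
#' A chain of immersed-boundary points: a closed loop for a cell membrane or
#' an open fiber for a wall structure. The Lagrangian increment `dq` is the
#' reference spacing between consecutive points; by the spacing rule it is
#' half the Eulerian mesh spacing in default configurations.
#'
#' @param x,y Point coordinates (model length units).
#' @param dq Lagrangian increment per point, > 0.
#' @param closed Logical; `TRUE` for a closed loop (cell), `FALSE` for an
#'   open fiber.
#' @param xperiod Period to apply when the chain wraps the periodic x
#'   direction as a graph over x (used by wall curves); 0 for none.
#' @return An object of class `lag_points`.
#' @export
lag_points <- function(x, y, dq, closed = TRUE, xperiod = 0) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (!is.numeric(dq) || dq <= 0) stop("`dq` must be > 0", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), dq = dq,
                 closed = isTRUE(closed), xperiod = xperiod),
            class = "lag_points")
}

#' @export
print.lag_points <- function(x, ...) {
  cat(sprintf("<lag_points> %d points, dq = %.4g, %s\n", length(x$x), x$dq,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' @export
length.lag_points <- function(x) length(x$x)

# 16-point tensor stencil for one velocity component.
# comp "u": nodes at ((i-1)hx, (j-1/2)hy); comp "v": ((i-1/2)hx, (j-1)hy).
# Returns linear indices into the component matrix, weights, and a validity
# mask (FALSE where the y-stencil leaves the interior: near-wall truncation).
ib_stencil <- function(xp, yp, grid, comp = c("u", "v")) {
  comp <- match.arg(comp)
  nx <- grid$nx; ny <- grid$ny
  if (comp == "u") {
    s <- xp / grid$hx
    t <- yp / grid$hy + 0.5
    jlo <- 1L; jhi <- ny; ncol_f <- ny
  } else {
    s <- xp / grid$hx - 0.5
    t <- yp / grid$hy + 1
    jlo <- 2L; jhi <- ny; ncol_f <- ny + 1L
  }
  offs <- -1:2
  i0 <- floor(s); j0 <- floor(t)
  IX <- outer(i0, offs, `+`)
  WX <- peskin_delta(s - IX)
  IX <- (IX %% nx) + 1L
  JY <- outer(j0, offs, `+`)
  WY <- peskin_delta(t - JY)
  rep4 <- rep(1:4, each = 4); rep4b <- rep(1:4, times = 4)
  W <- WX[, rep4b, drop = FALSE] * WY[, rep4, drop = FALSE]
  COL <- JY[, rep4, drop = FALSE]
  valid <- COL >= jlo & COL <= jhi
  W[!valid] <- 0
  COL[!valid] <- jlo     # clamped; weight already zeroed
  LIN <- IX[, rep4b, drop = FALSE] + (COL - 1L) * nx
  list(lin = LIN, w = W, valid = valid, ncol = ncol_f)
}

# weighted accumulation of `w` over integer keys `lin` into a length-N
# vector (radix sort + cumulative-sum differences; faster than rowsum)
accumulate_field <- function(lin, w, N) {
  o <- order(lin, method = "radix")
  ls <- lin[o]
  ws <- cumsum(w[o])
  last <- which(c(ls[-1L] != ls[-length(ls)], TRUE))
  out <- numeric(N)
  out[ls[last]] <- diff(c(0, ws[last]))
  out
}

spread_component <- function(xp, yp, fq, dq, grid, comp) {
  st <- ib_stencil(xp, yp, grid, comp)
  vals <- fq * st$w * (dq / (grid$hx * grid$hy))
  matrix(accumulate_field(st$lin, vals, grid$nx * st$ncol),
         grid$nx, st$ncol)
}

#' Spread Lagrangian force densities onto the Eulerian grid
#'
#' Computes `f(x) = sum_q F(q) delta_h(x - X(q)) dq` at the staggered
#' velocity locations, with periodic wrap in x. Points within two grid
#' cells of a wall spread only onto interior nodes (the clipped weight is
#' not renormalized).
#'
#' @param F An `n` by 2 matrix of Lagrangian force densities.
#' @param pts A [lag_points()] chain of `n` points.
#' @inheritParams body_force
#' @return A list with force-density matrices `fu`, `fv`.
#' @export
spread <- function(F, pts, grid) {
  stopifnot(inherits(pts, "lag_points"))
  F <- matrix(F, ncol = 2L)
  if (nrow(F) != length(pts$x)) stop("`F` and `pts` lengths differ", call. = FALSE)
  if (any(pts$y < 0 | pts$y > grid$ly)) {
    stop("Lagrangian point outside the domain in y", call. = FALSE)
  }
  list(fu = spread_component(pts$x, pts$y, F[, 1L], pts$dq, grid, "u"),
       fv = spread_component(pts$x, pts$y, F[, 2L], pts$dq, grid, "v"))
}

interp_component <- function(fld, xp, yp, grid, comp) {
  st <- ib_stencil(xp, yp, grid, comp)
  vals <- matrix(fld[st$lin], nrow(st$w), ncol(st$w))
  rowSums(vals * st$w)
}

#' Interpolate grid velocities to Lagrangian points
#'
#' Computes `U(q) = sum_x u(x) delta_h(x - X(q)) hx hy`, the adjoint of
#' [spread()] (same kernel and near-wall truncation).
#'
#' @param ufield List with velocity matrices `u` and `v` (e.g. an
#'   `rbc_fluid` state).
#' @inheritParams spread
#' @return An `n` by 2 matrix of point velocities.
#' @export
interpolate <- function(ufield, pts, grid) {
  stopifnot(inherits(pts, "lag_points"))
  if (any(pts$y < 0 | pts$y > grid$ly)) {
    stop("Lagrangian point outside the domain in y", call. = FALSE)
  }
  cbind(interp_component(ufield$u, pts$x, pts$y, grid, "u"),
        interp_component(ufield$v, pts$x, pts$y, grid, "v"))
}

#' Porosity parameters for a permeable wall
#'
#' @param kp Porosity constant (model um^2); 0 for an impermeable wall.
#'   The physiological range explored is 0 to 0.01.
#' @param normals `n` by 2 matrix of unit wall normals pointing into the
#'   channel interior.
#' @param metric Local stretch `||dX/dq||` per point, > 0.
#' @return A list of class `porosity_params`.
#' @export
porosity_params <- function(kp, normals, metric) {
  if (kp < 0) stop("`kp` must be >= 0", call. = FALSE)
  normals <- matrix(normals, ncol = 2L)
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-8)) stop("normals must be unit vectors", call. = FALSE)
  if (any(metric <= 0)) stop("zero or negative wall metric", call. = FALSE)
  structure(list(kp = kp, normals = normals, metric = as.numeric(metric)),
            class = "porosity_params")
}

#' Darcy-law slip velocity of a permeable wall
#'
#' For a porous layer the wall points no longer move with the local fluid
#' velocity alone: a slip `U_p = -kp (F . n) / ||dX/dq||` normal to the wall
#' is added, so the wall update velocity is `-U_p n` plus the interpolated
#' fluid velocity. With `kp = 0` this reduces to the impermeable case.
#'
#' @param F_wall `n` by 2 matrix of wall (tether) force densities.
#' @param porosity A [porosity_params()] object.
#' @return An `n` by 2 matrix: the `-U_p n` velocity contribution per point.
#' @export
porous_slip <- function(F_wall, porosity) {
  stopifnot(inherits(porosity, "porosity_params"))
  F_wall <- matrix(F_wall, ncol = 2L)
  if (nrow(F_wall) != nrow(porosity$normals)) {
    stop("`F_wall` and porosity lengths differ", call. = FALSE)
  }
  fn <- rowSums(F_wall * porosity$normals)
  up <- -porosity$kp * fn / porosity$metric
  -up * porosity$normals
}
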