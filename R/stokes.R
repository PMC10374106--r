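#' Parameters for the unsteady Stokes solver
#'
#' @param reynolds Reynolds number Re > 0 multiplying the unsteady term
#'   (default 0.01, the capillary-flow value used throughout).
#' @param dt Time step (model seconds), > 0.
#' @param theta Implicit weight of the viscous theta-scheme; 0.5 is
#'   Crank-Nicolson (second order), 1 is backward Euler.
#' @param body_force_on Whether the driving sinusoidal body force is applied.
#' @return A list of class `stokes_params`.
#' @export
stokes_params <- function(reynolds = 0.01, dt = 1e-3, theta = 0.5,
                          body_force_on = TRUE) {
  if (reynolds <= 0) stop("`reynolds` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (theta < 0.5 || theta > 1) stop("`theta` must be in [0.5, 1]", call. = FALSE)
  structure(list(reynolds = reynolds, dt = dt, theta = theta,
                 body_force_on = body_force_on),
            class = "stokes_params")
}

# Laplacian of u (nx x ny) with periodic x and no-slip ghost rows in y
# (ghost value = -first interior value, so the wall value interpolates to 0).
lap_u <- function(u, grid) {
  nx <- grid$nx; ny <- grid$ny
  out <- u[c(2:nx, 1L), , drop = FALSE] + u[c(nx, 1:(nx - 1L)), , drop = FALSE]
  out <- (out - 2 * u) / grid$hx^2
  yy <- matrix(0, nx, ny)
  yy[, 1:(ny - 1L)] <- u[, 2:ny]
  yy[, ny] <- yy[, ny] - u[, ny]
  yy[, 2:ny] <- yy[, 2:ny] + u[, 1:(ny - 1L)]
  yy[, 1L] <- yy[, 1L] - u[, 1L]
  out + (yy - 2 * u) / grid$hy^2
}

# Laplacian of the interior v rows (nx x (ny-1)); the wall rows of v are 0.
lap_v <- function(vint, grid) {
  nx <- grid$nx; ny <- grid$ny
  out <- vint[c(2:nx, 1L), , drop = FALSE] +
    vint[c(nx, 1:(nx - 1L)), , drop = FALSE]
  out <- (out - 2 * vint) / grid$hx^2
  yy <- matrix(0, nx, ny - 1L)
  yy[, 1:(ny - 2L)] <- vint[, 2:(ny - 1L)]
  yy[, 2:(ny - 1L)] <- yy[, 2:(ny - 1L)] + vint[, 1:(ny - 2L)]
  out + (yy - 2 * vint) / grid$hy^2
}

# Assemble one complex wavenumber block of the implicit coupled
# (u, v, p) system. Unknown layout: u 1..ny, v ny+1..2ny-1, p 2ny..3ny-1.
stokes_block <- function(k, grid, beta, theta) {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  th <- 2 * pi * k / nx
  kap2 <- 4 * sin(th / 2)^2 / hx^2
  gx <- (1 - exp(-1i * th)) / hx   # d/dx of p at u-points
  dx <- (exp(1i * th) - 1) / hx    # d/dx of u at cell centers
  m <- 3L * ny - 1L
  A <- matrix(0 + 0i, m, m)
  ip <- function(j) 2L * ny - 1L + j
  # u-momentum rows
  diag_u <- beta + theta * (kap2 + 2 / hy^2)
  for (j in seq_len(ny)) {
    A[j, j] <- diag_u
    if (j > 1L) A[j, j - 1L] <- -theta / hy^2 else A[j, j] <- A[j, j] + theta / hy^2
    if (j < ny) A[j, j + 1L] <- -theta / hy^2 else A[j, j] <- A[j, j] + theta / hy^2
    A[j, ip(j)] <- gx
  }
  # v-momentum rows (interior faces j = 1..ny-1)
  diag_v <- beta + theta * (kap2 + 2 / hy^2)
  for (j in seq_len(ny - 1L)) {
    r <- ny + j
    A[r, r] <- diag_v
    if (j > 1L) A[r, r - 1L] <- -theta / hy^2
    if (j < ny - 1L) A[r, r + 1L] <- -theta / hy^2
    A[r, ip(j + 1L)] <- 1 / hy
    A[r, ip(j)] <- -1 / hy
  }
  # continuity rows (cells j = 1..ny)
  for (j in seq_len(ny)) {
    r <- 2L * ny - 1L + j
    A[r, j] <- dx
    if (j <= ny - 1L) A[r, ny + j] <- 1 / hy
    if (j >= 2L) A[r, ny + j - 1L] <- -1 / hy
  }
  if (k == 0L) {
    # the ny continuity rows are rank-deficient by one and pressure has a
    # constant null mode: pin p_1 = 0 in place of the redundant row
    A[m, ] <- 0 + 0i
    A[m, ip(1L)] <- 1 + 0i
  }
  A
}

dense_to_triplets <- function(A, roff, coff) {
  nz <- which(A != 0, arr.ind = TRUE)
  list(i = nz[, 1L] + roff, j = nz[, 2L] + coff, x = A[nz])
}

#' Build the implicit solver for unsteady Stokes flow in the channel
#'
#' Fourier-transforms the periodic x direction and assembles, for every
#' wavenumber, the fully coupled implicit (velocity, pressure) system on the
#' staggered y-line: theta-scheme viscous terms, new-time pressure gradient,
#' and the discrete divergence constraint. All wavenumber blocks are stored
#' in one block-diagonal sparse matrix (complex blocks doubled to real form)
#' and LU-factorized once, so each [stokes_step()] is a pair of FFTs and one
#' triangular solve. The resulting velocity satisfies the discrete
#' divergence constraint to solver precision.
#'
#' @inheritParams body_force
#' @param params A [stokes_params()] object.
#' @return An object of class `stokes_solver` holding the factorization and
#'   index maps; pass it to [stokes_step()].
#' @export
stokes_solver <- function(grid, params) {
  stopifnot(inherits(grid, "rbc_grid"), inherits(params, "stokes_params"))
  nx <- grid$nx; ny <- grid$ny
  if (nx %% 2L != 0L) stop("`nx` must be even", call. = FALSE)
  m <- 3L * ny - 1L
  beta <- params$reynolds / params$dt
  theta <- params$theta
  khalf <- nx %/% 2L
  nkc <- khalf - 1L                     # complex wavenumbers 1..nx/2-1
  N <- 2L * m + nkc * 2L * m
  ti <- vector("list", khalf + 1L)
  # block offsets: k=0 (real, size m), k=1..khalf-1 (size 2m), k=khalf (m)
  off <- c(0L, m + (seq_len(nkc) - 1L) * 2L * m, m + nkc * 2L * m)
  for (k in 0:khalf) {
    A <- stokes_block(k, grid, beta, theta)
    o <- off[k + 1L]
    if (k == 0L || k == khalf) {
      ti[[k + 1L]] <- dense_to_triplets(Re(A) + 0, o, o)
    } else {
      Ar <- Re(A); Ai <- Im(A)
      t1 <- dense_to_triplets(Ar, o, o)
      t2 <- dense_to_triplets(-Ai, o, o + m)
      t3 <- dense_to_triplets(Ai, o + m, o)
      t4 <- dense_to_triplets(Ar, o + m, o + m)
      ti[[k + 1L]] <- list(i = c(t1$i, t2$i, t3$i, t4$i),
                           j = c(t1$j, t2$j, t3$j, t4$j),
                           x = Re(c(t1$x, t2$x, t3$x, t4$x)))
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(lapply(ti, `[[`, "i")),
                            j = unlist(lapply(ti, `[[`, "j")),
                            x = unlist(lapply(ti, `[[`, "x")),
                            dims = c(N, N))
  fac <- Matrix::lu(M)
  # index maps for packing/unpacking the wavenumber-stacked unknown vector
  idx <- function(o, a, b) o + seq.int(a, b)
  iu0 <- idx(off[1L], 1L, ny); iv0 <- idx(off[1L], ny + 1L, 2L * ny - 1L)
  ip0 <- idx(off[1L], 2L * ny, m)
  iuN <- idx(off[khalf + 1L], 1L, ny)
  ivN <- idx(off[khalf + 1L], ny + 1L, 2L * ny - 1L)
  ipN <- idx(off[khalf + 1L], 2L * ny, m)
  if (nkc > 0L) {
    oc <- off[2:(khalf)]
    IU_re <- outer(oc, 1:ny, `+`)
    IV_re <- outer(oc, (ny + 1L):(2L * ny - 1L), `+`)
    IP_re <- outer(oc, (2L * ny):m, `+`)
    IU_im <- IU_re + m; IV_im <- IV_re + m; IP_im <- IP_re + m
  } else {
    IU_re <- IV_re <- IP_re <- IU_im <- IV_im <- IP_im <- NULL
  }
  structure(list(grid = grid, params = params, fac = fac, N = N, m = m,
                 khalf = khalf, nkc = nkc,
                 iu0 = iu0, iv0 = iv0, ip0 = ip0,
                 iuN = iuN, ivN = ivN, ipN = ipN,
                 IU_re = IU_re, IU_im = IU_im, IV_re = IV_re,
                 IV_im = IV_im, IP_re = IP_re, IP_im = IP_im),
            class = "stokes_solver")
}

#' Advance the fluid by one time step
#'
#' Advances `Re du/dt + grad p = lap u + f`, `div u = 0` by one `dt` with
#' periodic-in-x / no-slip-in-y boundary conditions, using the implicit
#' coupled solve prepared by [stokes_solver()].
#'
#' @param state An `rbc_fluid` state (see [fluid_rest()]).
#' @param f_total List with force-density matrices `fu` (`nx` by `ny`) and
#'   `fv` (`nx` by `ny + 1`), e.g. from [body_force()] plus spread
#'   Lagrangian forces.
#' @param solver A [stokes_solver()] object.
#' @return The advanced `rbc_fluid` state; `$div_max` holds the maximum
#'   absolute discrete divergence of the new velocity.
#' @export
stokes_step <- function(state, f_total, solver) {
  grid <- solver$grid
  nx <- grid$nx; ny <- grid$ny
  beta <- solver$params$reynolds / solver$params$dt
  theta <- solver$params$theta
  u <- state$u; vint <- state$v[, 2:ny, drop = FALSE]
  ru <- beta * u + (1 - theta) * lap_u(u, grid) + f_total$fu
  rv <- beta * vint + (1 - theta) * lap_v(vint, grid) +
    f_total$fv[, 2:ny, drop = FALSE]
  RU <- stats::mvfft(ru)
  RV <- stats::mvfft(rv)
  khalf <- solver$khalf
  rhs <- numeric(solver$N)
  rhs[solver$iu0] <- Re(RU[1L, ]); rhs[solver$iv0] <- Re(RV[1L, ])
  rhs[solver$iuN] <- Re(RU[khalf + 1L, ]); rhs[solver$ivN] <- Re(RV[khalf + 1L, ])
  if (solver$nkc > 0L) {
    sel <- 2:khalf
    RUs <- RU[sel, , drop = FALSE]; RVs <- RV[sel, , drop = FALSE]
    rhs[solver$IU_re] <- Re(RUs)
    rhs[solver$IU_im] <- Im(RUs)
    rhs[solver$IV_re] <- Re(RVs)
    rhs[solver$IV_im] <- Im(RVs)
  }
  x <- as.numeric(Matrix::solve(solver$fac, rhs))
  if (!all(is.finite(x))) {
    stop("Stokes solve produced non-finite values (residual unbounded)",
         call. = FALSE)
  }
  UH <- matrix(0 + 0i, nx, ny)
  VH <- matrix(0 + 0i, nx, ny - 1L)
  PH <- matrix(0 + 0i, nx, ny)
  UH[1L, ] <- x[solver$iu0]; VH[1L, ] <- x[solver$iv0]; PH[1L, ] <- x[solver$ip0]
  UH[khalf + 1L, ] <- x[solver$iuN]; VH[khalf + 1L, ] <- x[solver$ivN]
  PH[khalf + 1L, ] <- x[solver$ipN]
  if (solver$nkc > 0L) {
    sel <- 2:khalf
    UH[sel, ] <- x[solver$IU_re] + 1i * x[solver$IU_im]
    VH[sel, ] <- x[solver$IV_re] + 1i * x[solver$IV_im]
    PH[sel, ] <- x[solver$IP_re] + 1i * x[solver$IP_im]
  }
  hi <- (khalf + 2L):nx
  UH[hi, ] <- Conj(UH[nx - hi + 2L, , drop = FALSE])
  VH[hi, ] <- Conj(VH[nx - hi + 2L, , drop = FALSE])
  PH[hi, ] <- Conj(PH[nx - hi + 2L, , drop = FALSE])
  unew <- Re(stats::mvfft(UH, inverse = TRUE)) / nx
  vnew <- cbind(0, Re(stats::mvfft(VH, inverse = TRUE)) / nx, 0)
  pnew <- Re(stats::mvfft(PH, inverse = TRUE)) / nx
  out <- list(u = unew, v = vnew, p = pnew,
              t = state$t + solver$params$dt,
              div_max = max(abs(divergence(unew, vnew, grid))))
  class(out) <- "rbc_fluid"
  out
}
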