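test_that("the 4-point kernel has the documented pointwise values and support", {
  expect_equal(peskin_delta(0), 0.5)
  expect_equal(peskin_delta(c(-2, 2, 2.7, -5)), rep(0, 4))
  expect_equal(peskin_delta(1), (3 - 2 + sqrt(1 + 4 - 4)) / 8)
  expect_true(all(peskin_delta(seq(-3, 3, by = 0.01)) >= 0))
})

test_that("the kernel is a partition of unity with zero first moment", {
  for (s in c(0, 0.1, 0.25, 0.5, 0.77, 0.999)) {
    j <- -4:5
    w <- peskin_delta(s - j)
    expect_equal(sum(w), 1, tolerance = 1e-14)
    expect_equal(sum((s - j) * w), 0, tolerance = 1e-13)
  }
})

test_that("spreading conserves total force and matches a brute-force oracle", {
  g <- make_grid(16, 16, 2, 2)
  set.seed(7)
  pts <- lag_points(runif(5, 0, 2), runif(5, 0.5, 1.5), dq = 0.07)
  F <- matrix(rnorm(10), 5, 2)

  sp <- spread(F, pts, g)
  expect_equal(sum(sp$fu) * g$hx * g$hy, sum(F[, 1]) * pts$dq,
               tolerance = 1e-14)
  expect_equal(sum(sp$fv) * g$hx * g$hy, sum(F[, 2]) * pts$dq,
               tolerance = 1e-14)

  # zero force spreads to a zero field
  sp0 <- spread(matrix(0, 5, 2), pts, g)
  expect_true(all(sp0$fu == 0) && all(sp0$fv == 0))

  # direct double-loop evaluation (u component, periodic x)
  brute <- matrix(0, g$nx, g$ny)
  for (i in seq_len(g$nx)) for (j in seq_len(g$ny)) {
    for (q in seq_along(pts$x)) {
      dx <- (pts$x[q] - g$xu[i]) / g$hx
      dx <- dx - round(dx / g$nx) * g$nx
      brute[i, j] <- brute[i, j] + F[q, 1] * peskin_delta(dx) *
        peskin_delta((pts$y[q] - g$yu[j]) / g$hy) * pts$dq / (g$hx * g$hy)
    }
  }
  expect_equal(sp$fu, brute, tolerance = 1e-14)

  expect_error(spread(F, lag_points(pts$x, pts$y + 10, dq = 0.07), g),
               "outside")
})

test_that("spread and interpolate are discrete adjoints on random instances", {
  g <- make_grid(16, 16, 2, 2)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:12, 1)
    pts <- lag_points(runif(n, -1, 3), runif(n, 0.4, 1.6), dq = 0.05)
    F <- matrix(rnorm(2 * n), n, 2)
    u <- list(u = matrix(rnorm(g$nx * g$ny), g$nx),
              v = matrix(rnorm(g$nx * (g$ny + 1L)), g$nx))
    sp <- spread(F, pts, g)
    lhs <- (sum(sp$fu * u$u) + sum(sp$fv * u$v)) * g$hx * g$hy
    rhs <- sum(F * interpolate(u, pts, g)) * pts$dq
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("interpolation reproduces constant and linear fields", {
  g <- make_grid(16, 16, 2, 2)
  set.seed(3)
  pts <- lag_points(runif(6, 0, 2), runif(6, 0.5, 1.5), dq = 0.05)
  uc <- list(u = matrix(1.5, g$nx, g$ny), v = matrix(-2.5, g$nx, g$ny + 1L))
  U <- interpolate(uc, pts, g)
  expect_equal(U[, 1], rep(1.5, 6), tolerance = 1e-14)
  expect_equal(U[, 2], rep(-2.5, 6), tolerance = 1e-14)

  # u = y exactly at a point aligned with a u-node height
  p1 <- lag_points(0.777, g$yu[8], dq = 0.05)
  ul <- list(u = matrix(rep(g$yu, each = g$nx), g$nx),
             v = matrix(0, g$nx, g$ny + 1L))
  expect_equal(interpolate(ul, p1, g)[1, 1], g$yu[8], tolerance = 1e-14)
})

test_that("Darcy slip is zero when impermeable and linear in kp", {
  set.seed(11)
  n <- 6
  nrm <- cbind(0, rep(1, n))
  F <- matrix(rnorm(2 * n), n, 2)
  met <- runif(n, 0.8, 1.2)
  s0 <- porous_slip(F, porosity_params(0, nrm, met))
  expect_true(all(s0 == 0))
  s1 <- porous_slip(F, porosity_params(0.005, nrm, met))
  s2 <- porous_slip(F, porosity_params(0.01, nrm, met))
  expect_equal(2 * s1, s2, tolerance = 1e-14)
  # tabled porosity range accepted
  for (kp in c(0, 0.005, 0.01)) {
    expect_s3_class(porosity_params(kp, nrm, met), "porosity_params")
  }
  # slip is along the normal with magnitude kp*(F.n)/metric
  expect_equal(s2[, 1], rep(0, n))
  expect_equal(s2[, 2], 0.01 * F[, 2] / met, tolerance = 1e-14)
  expect_error(porosity_params(0.01, nrm, c(met[-1], 0)), "metric")
})

test_that("points near a wall spread only onto interior nodes (truncation)", {
  g <- make_grid(16, 16, 2, 2)
  pts <- lag_points(1, 0.01, dq = 0.05)   # almost on the bottom wall
  sp <- spread(matrix(c(0, 1), 1), pts, g)
  # weight below the wall is dropped, so the grid total is less than F*dq
  expect_lt(sum(sp$fv) * g$hx * g$hy, pts$dq)
  expect_gt(sum(sp$fv) * g$hx * g$hy, 0)
})
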