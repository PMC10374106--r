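test_that("micro wall has evenly spaced bundles, the labeled density, and exact thickness", {
  g <- small_grid(64, 32)
  w <- build_micro_wall(10, 5, 1.4839, g)
  expect_equal(w$descriptor$density_label, 5)        # healthy ESL
  expect_equal(w$descriptor$root_gap, g$lx / 10)
  expect_equal(length(w$bottom), 50L)                # 10 bundles x 5 fibers
  roots <- sort(unique(vapply(w$bottom, function(b) b$pts$x[1L], numeric(1))))
  expect_equal(diff(roots), rep(g$lx / 10, 9), tolerance = 1e-12)

  th <- wall_measured_thickness(w, g)
  expect_equal(unname(th["bottom"]), 1.4839, tolerance = 1e-12)
  expect_equal(unname(th["top"]), 1.4839, tolerance = 1e-12)

  w2 <- build_micro_wall(2, 5, 1.4839, g)            # septic extreme
  expect_equal(w2$descriptor$density_label, 1)

  expect_error(build_micro_wall(10, 5, g$ly / 2, g), "overlap")
  expect_error(build_micro_wall(1, 5, 1, g), ">= 2")
})

test_that("macro wall is a periodic sine with thickness A + h and mirrored top", {
  g <- small_grid(64, 32)
  A <- 0.336
  w <- build_macro_wall(A, 2, 1.4839 - A, g)
  expect_equal(w$thickness, 1.4839)
  b <- w$bottom[[1L]]
  expect_equal(b$pts$y, A * sin(2 * 2 * pi * b$pts$x / g$lx) + (1.4839 - A),
               tolerance = 1e-12)
  # two full periods across the domain
  expect_equal(w$descriptor$wavelength, g$lx / 2)
  th <- wall_measured_thickness(w, g)
  expect_equal(unname(th["bottom"]), 1.4839, tolerance = 1e-6)

  # mirror symmetry about the centerline
  t_ <- w$top[[1L]]
  expect_equal(g$ly - t_$pts$y, b$pts$y, tolerance = 1e-12)

  # flat degenerate sine
  wf <- build_macro_wall(0, 1, 0.5, g)
  expect_equal(unique(round(wf$bottom[[1L]]$pts$y, 12)), 0.5)

  # eight periods keep the same maximum height
  w8 <- build_macro_wall(A, 8, 1.4839 - A, g)
  expect_equal(unname(wall_measured_thickness(w8, g)["bottom"]), 1.4839,
               tolerance = 1e-6)

  expect_error(build_macro_wall(A, 2.5, 1, g), "integer")
  expect_error(build_macro_wall(A, 2, g$ly / 2, g), "overlap")
})

test_that("wall Lagrangian spacing follows the half-mesh rule", {
  g <- small_grid(64, 32)
  w <- build_macro_wall(0.336, 2, 1.1479, g)
  expect_lte(w$bottom[[1L]]$pts$dq, min(g$hx, g$hy) / 2 * 1.05)
  wm <- build_micro_wall(10, 5, 1.4839, g)
  expect_lte(wm$bottom[[1L]]$pts$dq, min(g$hx, g$hy) / 2 * 1.05)
})

test_that("polyline import reproduces the equivalent built walls", {
  g <- small_grid(64, 32)
  xs <- seq(0, g$lx, length.out = 200)

  # flat polyline == flat macro wall
  flat <- data.frame(x = xs, y = rep(0.8, 200))
  wp <- load_wall_polyline(flat, grid = g)
  wm <- build_macro_wall(0, 1, 0.8, g)
  expect_equal(wp$bottom[[1L]]$pts$y, wm$bottom[[1L]]$pts$y, tolerance = 1e-9)

  # sine polyline -> macro wall within resampling tolerance
  A <- 0.336; h <- 1.1479; a <- 2 * 2 * pi / g$lx
  sine <- data.frame(x = xs, y = A * sin(a * xs) + h)
  wp2 <- load_wall_polyline(sine, grid = g)
  wm2 <- build_macro_wall(A, 2, h, g)
  fpoly <- approxfun(c(wp2$bottom[[1L]]$pts$x, g$lx),
                     c(wp2$bottom[[1L]]$pts$y, wp2$bottom[[1L]]$pts$y[1L]))
  expect_equal(fpoly(wm2$bottom[[1L]]$pts$x), wm2$bottom[[1L]]$pts$y,
               tolerance = 1e-2)

  # non-monotone x rejected
  bad <- data.frame(x = c(0, 2, 1, g$lx), y = rep(1, 4))
  expect_error(load_wall_polyline(bad, grid = g), "increasing")
  out <- data.frame(x = xs, y = rep(g$ly, 200))
  expect_error(load_wall_polyline(out, grid = g), "inside")
})

test_that("tether force is linear with the tabled default constant", {
  pts <- lag_points(c(1, 2, 3), c(0.5, 0.5, 0.5), dq = 0.1, closed = FALSE)
  Z <- cbind(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_true(all(tether_force(pts, Z) == 0))

  d <- cbind(c(0.01, 0, -0.02), c(0, 0.03, 0))
  pts2 <- lag_points(pts$x + d[, 1], pts$y + d[, 2], dq = 0.1, closed = FALSE)
  expect_equal(tether_force(pts2, Z), -3200 * d, tolerance = 1e-12)
  expect_equal(tether_force(pts2, Z, k_tether = 1), -d, tolerance = 1e-12)
  expect_equal(formals(tether_force)$k_tether, 3200)
})

test_that("wall at rest exerts (near) zero force; ESL default constants hold", {
  g <- small_grid(64, 32)
  wf <- build_macro_wall(0, 1, 0.8, g)     # straight wall at natural length
  expect_equal(wf$ks_esl, 0.015)
  F <- wall_elastic_force(wf)
  expect_lt(max(abs(F$bottom[[1L]]$total)), 1e-9)

  wm <- build_micro_wall(4, 3, 1, g)       # straight fibers at natural length
  Fm <- wall_elastic_force(wm)
  expect_lt(max(abs(Fm$bottom[[1L]]$total)), 1e-9)
})

test_that("perturbed wall fiber force matches the energy-gradient oracle", {
  g <- small_grid(64, 32)
  w <- build_micro_wall(4, 3, 1, g)
  b <- w$bottom[[2L]]
  set.seed(5)
  pts <- b$pts
  pts$x <- pts$x + 0.02 * rnorm(length(pts))
  pts$y <- pts$y + 0.02 * abs(rnorm(length(pts)))
  pm <- membrane_params(ks = w$ks_esl, kb = w$kb_esl, ka = 0, a0 = 1)
  F <- stretch_force(pts, pm) + bend_force(pts, pm)
  Fn <- numeric_force(pts, function(p)
    cell_energy(p, pm, "stretch") + cell_energy(p, pm, "bend"))
  expect_lt(max(abs(F - Fn)) / max(abs(F)), 1e-5)
})

test_that("wall normals point into the channel", {
  g <- small_grid(64, 32)
  w <- build_macro_wall(0.336, 2, 1.1479, g)
  expect_true(all(w$bottom[[1L]]$normals[, 2] > 0))
  expect_true(all(w$top[[1L]]$normals[, 2] < 0))
  nn <- unname(sqrt(rowSums(w$bottom[[1L]]$normals^2)))
  expect_equal(nn, rep(1, length(nn)), tolerance = 1e-12)
})
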