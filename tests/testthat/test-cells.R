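test_that("biconcave contour has the resting dimensions and symmetries", {
  p <- biconcave_rbc(c(0, 0), 0, 128, scale = 1)
  expect_equal(max(p$x) - min(p$x), 8, tolerance = 1e-3)
  expect_equal(max(p$y) - min(p$y), 2, tolerance = 2e-2)
  expect_gt(polygon_area(p), 0)

  # reflection symmetry about both axes at orientation 0
  n <- length(p)
  ref_x <- sort(round(p$x, 9)); ref_mx <- sort(round(-p$x, 9))
  expect_equal(ref_x, ref_mx, tolerance = 1e-10)
  ref_y <- sort(round(p$y, 9)); ref_my <- sort(round(-p$y, 9))
  expect_equal(ref_y, ref_my, tolerance = 1e-10)

  # construction is reproducible to machine precision
  p2 <- biconcave_rbc(c(0, 0), 0, 128, scale = 1)
  expect_identical(p$x, p2$x)
  expect_identical(polygon_area(p), polygon_area(p2))

  # area agrees with a high-resolution evaluation of the same profile
  pf <- biconcave_rbc(c(0, 0), 0, 2048, scale = 1)
  expect_equal(polygon_area(p), polygon_area(pf), tolerance = 1e-2)

  # near-uniform arclength spacing at dq
  seg <- sqrt(diff(c(p$x, p$x[1]))^2 + diff(c(p$y, p$y[1]))^2)
  expect_lt(max(abs(seg / p$dq - 1)), 0.05)
})

test_that("rotated contour keeps its centroid and tilts its principal axis", {
  p <- biconcave_rbc(c(2, 3), 30, 128, scale = 1)
  expect_equal(mean(p$x), 2, tolerance = 1e-9)
  expect_equal(mean(p$y), 3, tolerance = 1e-9)
  xc <- p$x - mean(p$x); yc <- p$y - mean(p$y)
  M <- cbind(c(sum(xc^2), sum(xc * yc)), c(sum(xc * yc), sum(yc^2)))
  ev <- eigen(M)$vectors[, 1L]
  ang <- atan2(ev[2L], ev[1L]) * 180 / pi
  expect_equal(abs(((ang - 30) + 90) %% 180 - 90), 0, tolerance = 0.5)
})

test_that("circle cells have the documented polygon areas", {
  sq <- circle_cell(c(0, 0), 1, 4)
  expect_equal(polygon_area(sq), 2, tolerance = 1e-12)

  leuko <- circle_cell(c(10, 10), 6, 160)
  expect_equal(polygon_area(leuko), pi * 36, tolerance = pi * 36 * 1e-3)

  # control circle with the same area as the biconcave cell
  rbc <- biconcave_rbc(c(0, 0), 0, 128)
  a <- polygon_area(rbc)
  ctrl <- circle_cell(c(0, 0), sqrt(a / pi), 256)
  expect_equal(polygon_area(ctrl), a, tolerance = a * 1e-3)
})

test_that("placement is deterministic, gap-respecting, and error-reporting", {
  g <- make_grid(128, 64, 40, 20)
  w <- build_macro_wall(0.336, 2, 1.1479, g)
  cells <- place_cells(c(2, 38, 4, 16), n_rbc = 5, n_leuko = 1, seed = 42,
                       wall = w, grid = g, rbc_n_points = 64,
                       leuko_radius = 3, leuko_n_points = 64)
  expect_length(cells, 6L)

  cells2 <- place_cells(c(2, 38, 4, 16), n_rbc = 5, n_leuko = 1, seed = 42,
                        wall = w, grid = g, rbc_n_points = 64,
                        leuko_radius = 3, leuko_n_points = 64)
  expect_identical(lapply(cells, function(s) s$pts),
                   lapply(cells2, function(s) s$pts))

  # every point at least 4 grid cells from the wall surfaces
  min_gap <- 4 * max(g$hx, g$hy)
  for (sp in cells) {
    bot <- wall_surface(w, sp$pts$x %% g$lx, "bottom", g)
    top <- wall_surface(w, sp$pts$x %% g$lx, "top", g)
    expect_gte(min(sp$pts$y - bot), min_gap - 1e-9)
    expect_gte(min(top - sp$pts$y), min_gap - 1e-9)
  }
  # no cell-cell overlap
  for (i in seq_along(cells)) for (j in seq_len(i - 1L)) {
    d2 <- outer(cells[[i]]$pts$x, cells[[j]]$pts$x, `-`)^2 +
      outer(cells[[i]]$pts$y, cells[[j]]$pts$y, `-`)^2
    expect_gte(sqrt(min(d2)), min_gap - 1e-9)
  }

  expect_error(
    place_cells(c(2, 6, 8, 12), n_rbc = 40, seed = 1, wall = w, grid = g,
                rbc_n_points = 32, max_tries = 5L),
    "placed [0-9]+ of 40")
})

test_that("cells outside a narrowed wall are removed", {
  g <- make_grid(128, 64, 40, 20)
  wide <- build_macro_wall(0, 1, 1, g)
  cells <- place_cells(c(2, 38, 2.5, 17.5), n_rbc = 8, seed = 3,
                       wall = wide, grid = g, rbc_n_points = 48)
  narrow <- build_macro_wall(0, 1, 6, g)
  kept <- filter_cells_inside(cells, narrow, g)
  expect_lt(length(kept), length(cells))
  for (sp in kept) {
    expect_gte(min(sp$pts$y), 6)
    expect_lte(max(sp$pts$y), 14)
  }
})

test_that("phase offsets uniformly sample the wall period", {
  g <- small_grid(64, 32)
  wmac <- build_macro_wall(0.336, 2, 1.1479, g)
  lam <- g$lx / 2
  expect_equal(phase_offsets(wmac, 4), lam * (0:3) / 4)

  wmic <- build_micro_wall(10, 5, 1.4839, g)
  gap <- g$lx / 10
  expect_equal(phase_offsets(wmic, 4), gap * (0:3) / 4)
  expect_equal(eval(formals(phase_offsets)$count), 4)

  xs <- seq(0, g$lx, length.out = 50)
  wpl <- load_wall_polyline(data.frame(x = xs, y = rep(1, 50)), grid = g)
  expect_error(phase_offsets(wpl, 4), "period")
  expect_equal(phase_offsets(wpl, 4, period = 2), 2 * (0:3) / 4)
})

test_that("cell inventories round-trip through CSV", {
  cells <- list(cell_spec("rbc", c(3, 4), 30, 64),
                cell_spec("leukocyte", c(10, 10), 0, 64, radius = 6))
  path <- tempfile(fileext = ".csv")
  write_cell_inventory(cells, path)
  back <- read_cell_inventory(path)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$pts$x, cells[[1L]]$pts$x, tolerance = 1e-12)
  expect_equal(back[[2L]]$kind, "leukocyte")
})
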