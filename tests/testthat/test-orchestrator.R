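test_that("with no structures the orchestrated run matches the channel oracle", {
  g <- small_grid(64, 32)
  cfg <- simulation_config(g, wall = NULL, cells = list(), dt = 0.02,
                           t_end = 1.2, force_amplitude = 1, snapshots = FALSE)
  sim <- run_simulation(cfg)
  ex <- steady_channel_solution(g)
  rel <- sqrt(sum((sim$final_state$fluid$u - ex$u)^2) / sum(ex$u^2))
  expect_lt(rel, 1e-3)
  expect_lt(max(sim$fluid_series$div_max), 1e-10)
})

test_that("runs are bitwise reproducible for identical configurations", {
  cfg <- desk_config(nx = 32, ny = 16, t_end = 0.05)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$observables, s2$observables)
  expect_identical(s1$final_state$fluid$u, s2$final_state$fluid$u)
})

test_that("checkpoint and resume continue bit-identically", {
  cfg <- desk_config(nx = 32, ny = 16, t_end = 0.06, save_every = 3)
  full <- run_simulation(cfg)
  path <- tempfile(fileext = ".rds")
  # interrupt halfway by checkpointing every 9 steps (n_steps ~ 18)
  half <- run_simulation(cfg, checkpoint_path = path,
                         checkpoint_every = ceiling(cfg$n_steps / 2))
  expect_true(file.exists(path))
  resumed <- resume_simulation(path)
  expect_identical(resumed$observables, full$observables)
  expect_identical(resumed$final_state$fluid$u, full$final_state$fluid$u)
  expect_identical(resumed$fluid_series, full$fluid_series)
})

test_that("impermeable wall points track targets within one grid spacing", {
  cfg <- desk_config(nx = 32, ny = 16, t_end = 0.2, kp = 0)
  sim <- run_simulation(cfg)
  drift <- 0
  for (b in sim$final_state$bodies) {
    if (is.null(b$targets)) next
    drift <- max(drift, abs(b$pts$x - b$targets[, 1]),
                 abs(b$pts$y - b$targets[, 2]))
  }
  expect_lt(drift, cfg$grid$hy)
})

test_that("kp = 0 reduces the wall update to pure fluid advection", {
  # identical runs with kp = 0 and the slip term forcibly at kp = 0 must agree;
  # kp > 0 must differ (the slip is active)
  cfg0 <- desk_config(nx = 32, ny = 16, t_end = 0.04)
  s0 <- run_simulation(cfg0)
  cfgp <- desk_config(nx = 32, ny = 16, t_end = 0.04, kp = 0.01)
  sp_ <- run_simulation(cfgp)
  expect_false(identical(s0$final_state$bodies, sp_$final_state$bodies))
})

test_that("elastic energy decays monotonically in force-free relaxation", {
  g <- small_grid(32, 16)
  # perturbed cell in quiescent fluid (no body force, no wall)
  base <- biconcave_rbc(c(2 * pi, pi), 0, 64, scale = 0.375)
  set.seed(2)
  pts <- lag_points(base$x * (1 + 0.05), base$y * (1 - 0.06), dq = base$dq)
  sp <- cell_spec("rbc", c(2 * pi, pi), 0, 64, scale = 0.375)
  sp$pts <- pts
  cfg <- simulation_config(g, wall = NULL, cells = list(sp), t_end = 0.3,
                           body_force_on = FALSE, save_every = 5)
  sim <- run_simulation(cfg)
  e <- sim$fluid_series$energy
  expect_gt(e[1L], e[length(e)])
  expect_true(all(diff(e) < 1e-10))
})

test_that("instability is detected and aborts with a diagnostic", {
  cfg <- desk_config(nx = 32, ny = 16, t_end = 1, dt = 0.05,
                     force_amplitude = 1)   # far beyond the stability bound
  expect_error(run_simulation(cfg), "instability|counter-clockwise|domain")
})

test_that("grid refinement leaves time-averaged lift and drag consistent", {
  lds <- lapply(c(32, 64), function(nx) {
    cfg <- desk_config(nx = nx, ny = nx / 2, t_end = 0.4, save_every = 10)
    lift_drag(run_simulation(cfg), transient_frac = 0.25)
  })
  d1 <- attr(lds[[1]], "mean_drag"); d2 <- attr(lds[[2]], "mean_drag")
  expect_lt(abs(d1 - d2) / d2, 0.05)
})

test_that("configs round-trip through YAML and respect tabled defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "grid: {nx: 32, ny: 16, lx: 12.566, ly: 6.283}",
    "fluid: {reynolds: 0.01, force_amplitude: 0.02}",
    "wall: {model: macro, amplitude: 0.336, frequency_label: 2, h_offset: 1.1479}",
    "cells:",
    "  - {kind: rbc, center: [3.0, 2.1], orientation: 30, n_points: 72, scale: 0.375}",
    "run: {t_end: 0.5, seed: 7}"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$reynolds, 0.01)
  expect_equal(cfg$wall$k_tether, 3200)
  expect_equal(cfg$wall$thickness, 1.4839, tolerance = 1e-6)
  expect_equal(cfg$cells[[1]]$orientation_deg, 30)
  expect_equal(cfg$seed, 7)
  expect_gt(cfg$dt, 0)
})

test_that("tidy/glance/autoplot provide the standard result surfaces", {
  cfg <- desk_config(nx = 32, ny = 16, t_end = 0.05, save_every = 2)
  sim <- run_simulation(cfg)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "cell", "fx", "fy", "area", "perimeter") %in%
                    names(td)))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$lift_frac + gl$drag_frac, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(sim), "ggplot")
  m <- density_map(sim, cfg$grid)
  expect_s3_class(plot_density_map(m, cfg$grid), "ggplot")
})
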