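# shared small fixtures, built in code

small_grid <- function(nx = 32, ny = 16, lx = 4 * pi, ly = 2 * pi) {
  make_grid(nx, ny, lx, ly)
}

# random closed loop that is safely non-degenerate
random_loop <- function(n = 8, seed = 1, r = 1, jitter = 0.1) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  lag_points(r * cos(th) + jitter * rnorm(n),
             r * sin(th) + jitter * rnorm(n), dq = 2 * pi * r / n)
}

# central-difference gradient of a chain energy, as force density
numeric_force <- function(pts, energy_fn, eps = 1e-6) {
  n <- length(pts$x)
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      pp <- pts; pm <- pts
      if (d == 1L) {
        pp$x[i] <- pp$x[i] + eps; pm$x[i] <- pm$x[i] - eps
      } else {
        pp$y[i] <- pp$y[i] + eps; pm$y[i] <- pm$y[i] - eps
      }
      out[i, d] <- -(energy_fn(pp) - energy_fn(pm)) / (2 * eps) / pts$dq
    }
  }
  out
}

# reduced single-RBC experiment near a macroscopic sinusoidal wall
desk_config <- function(nx = 64, ny = 32, kp = 0, t_end = 0.5,
                        thickness = 1.4839, frequency = 2,
                        amplitude = 0.336, orientation = 30,
                        x0 = 3, y0 = 2.9, force_amplitude = 0.02, ...) {
  g <- make_grid(nx, ny, 4 * pi, 2 * pi)
  w <- build_macro_wall(amplitude, frequency, thickness - amplitude, g, kp = kp)
  sp <- cell_spec("rbc", c(x0, y0), orientation,
                  n_points = if (nx >= 128) 120 else 72, scale = 0.3)
  simulation_config(g, w, list(sp), t_end = t_end,
                    force_amplitude = force_amplitude, ...)
}
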