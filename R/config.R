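#' Read a simulation configuration from a YAML file
#'
#' The file describes the experiment in plain sections: `grid`
#' (`nx, ny, lx, ly`), `fluid` (`reynolds, dt, theta, force_amplitude`),
#' `wall` (`model: micro|macro|polyline|none` plus the builder arguments),
#' `cells` (a list of cell entries with `kind, center, orientation,
#' n_points, scale/radius`, or a `place` block with `region, n_rbc,
#' n_leuko, seed`), and `run` (`t_end, save_every, seed, scale`).
#'
#' @param path YAML file path.
#' @return A [simulation_config()] object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  gy <- y$grid
  grid <- make_grid(gy$nx, gy$ny, gy$lx, gy$ly,
                    length_scale_um = gy$length_scale_um %||% 1)
  wall <- NULL
  wy <- y$wall
  if (!is.null(wy) && !identical(wy$model, "none")) {
    wall <- switch(wy$model,
      micro = build_micro_wall(wy$n_bundles, wy$fibers_per_bundle, wy$h, grid,
                               k_tether = wy$k_tether %||% 3200,
                               ks_esl = wy$ks_esl %||% 0.015,
                               kb_esl = wy$kb_esl %||% 0.001,
                               kp = wy$kp %||% 0),
      macro = build_macro_wall(wy$amplitude %||% 0.336, wy$frequency_label,
                               wy$h_offset, grid,
                               k_tether = wy$k_tether %||% 3200,
                               ks_esl = wy$ks_esl %||% 0.015,
                               kb_esl = wy$kb_esl %||% 0.001,
                               kp = wy$kp %||% 0),
      polyline = load_wall_polyline(wy$bottom, wy$top, grid,
                                    k_tether = wy$k_tether %||% 3200,
                                    ks_esl = wy$ks_esl %||% 0.015,
                                    kb_esl = wy$kb_esl %||% 0.001,
                                    kp = wy$kp %||% 0),
      stop("unknown wall model: ", wy$model, call. = FALSE))
  }
  cells <- list()
  cy <- y$cells
  if (!is.null(cy$place)) {
    pl <- cy$place
    cells <- place_cells(unlist(pl$region), pl$n_rbc, pl$n_leuko %||% 0,
                         seed = pl$seed %||% 1, wall = wall, grid = grid,
                         rbc_scale = pl$rbc_scale %||% 1,
                         rbc_n_points = pl$rbc_n_points %||% 128,
                         leuko_radius = pl$leuko_radius %||% 6)
  } else if (length(cy)) {
    cells <- lapply(cy, function(cc) {
      cell_spec(cc$kind %||% "rbc", unlist(cc$center),
                cc$orientation %||% 0, cc$n_points %||% 128,
                scale = cc$scale %||% 1, radius = cc$radius %||% 6)
    })
  }
  fy <- y$fluid %||% list()
  ry <- y$run %||% list()
  simulation_config(grid, wall, cells,
                    reynolds = fy$reynolds %||% 0.01,
                    dt = fy$dt,
                    theta = fy$theta %||% 0.5,
                    force_amplitude = fy$force_amplitude %||% 0.02,
                    t_end = ry$t_end %||% 1,
                    save_every = ry$save_every,
                    seed = ry$seed %||% 1,
                    scale = ry$scale %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write run observables to CSV (and a JSON summary)
#'
#' Writes `cells.csv` (per-cell observable records), `fluid.csv`
#' (force sums, divergence residuals, energy) and, when the jsonlite
#' package is available, `summary.json` with the [glance.rbc_sim()] row.
#'
#' @param sim An `rbc_sim`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_observables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(sim$observables)) {
    utils::write.csv(sim$observables, file.path(dir, "cells.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(sim$fluid_series, file.path(dir, "fluid.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(glance(sim)),
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write or read a cell inventory as CSV
#'
#' The inventory records `kind, center_x, center_y, orientation, n_points,
#' scale, radius` so that placements can be reproduced or restarted.
#'
#' @param cells List of [cell_spec()] objects.
#' @param path CSV file path.
#' @return `write_cell_inventory()` returns the path invisibly;
#'   `read_cell_inventory()` returns a list of [cell_spec()] objects.
#' @export
write_cell_inventory <- function(cells, path) {
  df <- do.call(rbind, lapply(cells, function(sp) {
    data.frame(kind = sp$kind, center_x = sp$center[1L],
               center_y = sp$center[2L], orientation = sp$orientation_deg,
               n_points = sp$n_points, scale = sp$scale, radius = sp$radius)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_inventory
#' @export
read_cell_inventory <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    cell_spec(df$kind[i], c(df$center_x[i], df$center_y[i]),
              df$orientation[i], df$n_points[i],
              scale = df$scale[i], radius = df$radius[i])
  })
}
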