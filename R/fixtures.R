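# Seeded generators for cell maps and synthetic hunting traces, so every
# module is testable without external data.

#' Generate a synthetic cell map
#'
#' Emulates user cell selection for one slice experiment: 8-10 healthy cells
#' spread across roughly a 200 x 200 um field, 20-100 um below the slice
#' surface. Cells are placed by uniform rejection sampling honoring a
#' minimum pairwise separation; deterministic under `seed`.
#'
#' @param n_cells Number of cells; default 9.
#' @param field_um x and y extent of the selection field (um); default
#'   c(200, 200).
#' @param depth_band_um Depth range below the slice surface (um); default
#'   c(20, 100).
#' @param min_separation_um Minimum pairwise 3D distance between somata;
#'   default 15 um (about one soma diameter).
#' @param seed Integer seed.
#' @param max_draws Rejection-sampling cap before declaring the packing
#'   infeasible; default 10000.
#' @return A data frame with columns `id`, `x_um`, `y_um`, `z_um`.
#' @export
generate_cell_map <- function(n_cells = 9L, field_um = c(200, 200),
                              depth_band_um = c(20, 100),
                              min_separation_um = 15, seed = 1L,
                              max_draws = 10000L) {
  n_cells <- check_count(n_cells, "n_cells", min = 1L)
  set.seed(seed)
  pts <- matrix(NA_real_, nrow = 0, ncol = 3)
  draws <- 0L
  while (nrow(pts) < n_cells) {
    draws <- draws + 1L
    if (draws > max_draws) {
      stop_domain(sprintf(
        "could not place %d cells with min separation %g um in %d draws",
        n_cells, min_separation_um, max_draws
      ))
    }
    cand <- c(
      stats::runif(1, 0, field_um[1]),
      stats::runif(1, 0, field_um[2]),
      stats::runif(1, depth_band_um[1], depth_band_um[2])
    )
    ok <- nrow(pts) == 0 ||
      all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 3, byrow = TRUE))^2)) >=
            min_separation_um)
    if (ok) pts <- rbind(pts, cand)
  }
  data.frame(
    id = seq_len(n_cells),
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
    row.names = NULL
  )
}

#' Default pipette home positions
#'
#' Two pipettes approach from opposite edges of the selection field, giving
#' each a natural half-field of nearby cells.
#'
#' @param field_um Field extent (um); default c(200, 200).
#' @return A named list of xyz positions for pipettes `a` and `b`.
#' @export
default_home_positions <- function(field_um = c(200, 200)) {
  list(
    a = c(x_um = 0, y_um = field_um[2] / 2, z_um = 0),
    b = c(x_um = field_um[1], y_um = field_um[2] / 2, z_um = 0)
  )
}

#' Generate a synthetic neuron-hunting resistance trace
#'
#' Produces a descending-step resistance trace for testing
#' [detect_neuron()]. With `has_cell`, the tip resistance ramps up once the
#' pipette passes `contact_depth_um`, firing the 0.2 MOhm / 5-step
#' criterion; otherwise the trace is baseline plus noise.
#'
#' @param has_cell Logical: is a cell present?
#' @param start_depth_um Depth of the first step (um); default 80.
#' @param contact_depth_um Depth at which cell contact begins; default 70.
#' @param n_steps Number of 0.1 um descending steps; the default descends
#'   3 um past the contact depth.
#' @param baseline_mohm Open-tip resistance (MOhm); default 5.
#' @param ramp_mohm_per_step Resistance rise per step after contact; default
#'   0.1.
#' @param noise_sd_mohm Gaussian measurement noise SD; default 0.
#' @param seed Optional integer seed.
#' @return A [hunt_trace()].
#' @export
generate_hunt_trace <- function(has_cell, start_depth_um = 80,
                                contact_depth_um = 70,
                                n_steps = round((start_depth_um - contact_depth_um) / 0.1) + 30L,
                                baseline_mohm = 5,
                                ramp_mohm_per_step = 0.1,
                                noise_sd_mohm = 0, seed = NULL) {
  if (noise_sd_mohm < 0) stop_domain("`noise_sd_mohm` must be >= 0")
  pos <- start_depth_um - 0.1 * (seq_len(n_steps) - 1)
  r <- rep(baseline_mohm, n_steps)
  if (isTRUE(has_cell)) {
    past <- pmax(0, round((contact_depth_um - pos) / 0.1))
    r <- r + ramp_mohm_per_step * past
  }
  if (noise_sd_mohm > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + stats::rnorm(n_steps, sd = noise_sd_mohm)
    r[r <= 0] <- 0.01
  }
  hunt_trace(pos, r)
}
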