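#' Simulate a confined trajectory (reflected Brownian motion in a sphere)
#'
#' The locus performs Brownian motion with per-axis step variance
#' `2 * D * dt` inside a hard sphere of radius `confinement_radius` about
#' `center`; steps leaving the sphere are mirror-reflected at the surface
#' (the radial excess is folded back, iterated until the point is inside).
#' Each frame interval is integrated in `cfg$n_substeps` sub-steps so the
#' per-substep RMS step stays small relative to the radius. The walk starts
#' from the stationary distribution, which for a hard reflecting sphere is
#' uniform in the ball; this is the test hook: the long-run per-axis
#' variance of positions equals `R^2 / 5`, the second moment of a uniform
#' ball.
#'
#' @param cfg A [sim_config()]. `confinement_radius = Inf` disables
#'   reflection (free diffusion, started at `center`).
#' @param center 3-vector, um: center of the confining sphere.
#' @return Matrix `n_frames x 3` of positions in um (columns x, y, z),
#'   sampled at the frame times.
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 50, seed = 7)
#' tr <- simulate_confined_track(cfg)
#' max(sqrt(rowSums(tr^2)))  # never exceeds the confinement radius
simulate_confined_track <- function(cfg, center = c(0, 0, 0)) {
  cfg <- validate_sim_config(cfg)
  stopifnot(length(center) == 3, all(is.finite(center)))
  with_rng(cfg$seed, confined_track_impl(cfg, center))
}

# Unseeded core; callers own the RNG stream.
confined_track_impl <- function(cfg, center = c(0, 0, 0)) {
  R <- cfg$confinement_radius
  dt <- cfg$frame_interval / cfg$n_substeps
  step_sd <- sqrt(2 * cfg$diffusion_coeff * dt)
  n <- cfg$n_frames
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  p <- if (is.finite(R)) center + runif_ball(R) else center
  out[1, ] <- p
  if (n == 1) return(out)
  nsub <- cfg$n_substeps
  steps <- matrix(rnorm(3 * (n - 1) * nsub, sd = step_sd),
                  (n - 1) * nsub, 3)
  row <- 1L
  for (i in 2:n) {
    for (s in seq_len(nsub)) {
      p <- p + steps[row, ]
      row <- row + 1L
      if (is.finite(R)) p <- reflect_into_sphere(p, center, R)
    }
    out[i, ] <- p
  }
  out
}

# One point uniform in the ball of radius R (rejection-free: direction x
# radius with cube-root law).
runif_ball <- function(R) {
  d <- rnorm(3)
  d <- d / sqrt(sum(d^2))
  d * R * runif(1)^(1 / 3)
}

# Fold the radial excess of a point back across the sphere surface,
# iterating for steps longer than the diameter.
reflect_into_sphere <- function(p, center, R) {
  v <- p - center
  r <- sqrt(sum(v^2))
  if (r <= R) return(p)
  d <- r
  while (d > R) d <- abs(2 * R - d)
  center + v * (d / r)
}

#' Simulate one cell: paired DSB and SPB tracks with shared drift
#'
#' Emulates the fiducial design of a DSB-mobility experiment: the broken
#' locus (focus channel) diffuses inside its confinement sphere while the
#' spindle-pole body (fiducial channel) sits at a fixed offset; both ride on
#' the same Gaussian random-walk drift representing whole-nucleus and cell
#' motion. Because the drift is shared bit-exactly, the difference
#' focus - fiducial recovers the confined motion, which is exactly what the
#' fiducial correction downstream must achieve.
#'
#' @param cfg A [sim_config()].
#' @param cell_id Identifier carried into the track table.
#' @return A list with
#'   \describe{
#'     \item{tracks}{tibble in the standard track schema (`cell_id`,
#'       `frame` (0-based), `t_s`, `channel` in `focus`/`fiducial`, `x_px`,
#'       `y_px`, `z_slice`, `intensity`) in pixel/slice units.}
#'     \item{truth}{list: `confinement_radius` (um), `dsb_um` and `spb_um`
#'       (n_frames x 3 matrices, drift-free um positions), `drift_um`
#'       (shared drift path), `center_um`.}
#'   }
#' @export
simulate_cell <- function(cfg, cell_id = "cell_1") {
  cfg <- validate_sim_config(cfg)
  with_rng(cfg$seed, cell_impl(cfg, cell_id))
}

cell_impl <- function(cfg, cell_id) {
  center <- volume_center_um(cfg)
  dsb <- confined_track_impl(cfg, center)
  spb <- matrix(rep(center + cfg$spb_offset, each = cfg$n_frames),
                cfg$n_frames, 3, dimnames = list(NULL, c("x", "y", "z")))
  drift <- apply(matrix(rnorm(3 * cfg$n_frames, sd = cfg$drift_sd),
                        cfg$n_frames, 3), 2, cumsum)
  drift <- sweep(drift, 2, drift[1, ])  # drift 0 at t = 0
  obs_dsb <- dsb + drift
  obs_spb <- spb + drift
  tracks <- dplyr::bind_rows(
    um_to_track_tbl(obs_dsb, cfg, cell_id, "focus", intensity = 1000),
    um_to_track_tbl(obs_spb, cfg, cell_id, "fiducial", intensity = 800))
  if (cfg$loc_noise_sd > 0) {
    n <- nrow(tracks)
    tracks$x_px <- tracks$x_px + rnorm(n, sd = cfg$loc_noise_sd)
    tracks$y_px <- tracks$y_px + rnorm(n, sd = cfg$loc_noise_sd)
    tracks$z_slice <- tracks$z_slice + rnorm(n, sd = cfg$loc_noise_sd)
  }
  list(tracks = tracks,
       truth = list(confinement_radius = cfg$confinement_radius,
                    dsb_um = dsb, spb_um = spb, drift_um = drift,
                    center_um = center))
}

# Geometric center of the rendered volume, um (0-based voxel centers).
volume_center_um <- function(cfg) {
  c((cfg$img_size - 1) / 2 * cfg$pixel_size / 1000,
    (cfg$img_size - 1) / 2 * cfg$pixel_size / 1000,
    (cfg$n_slices - 1) / 2 * cfg$z_step / 1000)
}

um_to_track_tbl <- function(pos_um, cfg, cell_id, channel, intensity) {
  n <- nrow(pos_um)
  tibble::tibble(
    cell_id = cell_id,
    frame = seq_len(n) - 1L,
    t_s = (seq_len(n) - 1) * cfg$frame_interval,
    channel = channel,
    x_px = pos_um[, 1] * 1000 / cfg$pixel_size,
    y_px = pos_um[, 2] * 1000 / cfg$pixel_size,
    z_slice = pos_um[, 3] * 1000 / cfg$z_step,
    intensity = intensity)
}

#' Simulate a cohort of cells under one condition
#'
#' Draws `cfg$n_cells` independent cells from one seeded generator.
#'
#' @param cfg A [sim_config()].
#' @param condition Condition label carried into the track table.
#' @return List with `tracks` (one tibble, cells stacked, extra `condition`
#'   column) and `truth` (list of per-cell truth records, named by cell id).
#' @export
simulate_cohort <- function(cfg, condition = "cond") {
  cfg <- validate_sim_config(cfg)
  with_rng(cfg$seed, {
    cells <- lapply(seq_len(cfg$n_cells), function(i) {
      cell_impl(cfg, sprintf("%s_cell_%02d", condition, i))
    })
    tracks <- dplyr::bind_rows(lapply(cells, `[[`, "tracks"))
    tracks$condition <- condition
    truth <- lapply(cells, `[[`, "truth")
    names(truth) <- vapply(cells, function(c) c$tracks$cell_id[1], "")
    list(tracks = tracks, truth = truth)
  })
}
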