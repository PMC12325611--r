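#' Render a two-channel 3D time-lapse from simulated tracks
#'
#' Emulates spinning-disk acquisition of the two fluorophores: each spot is
#' a 3D Gaussian (lateral sigma `psf_sigma[1]` pixels, axial `psf_sigma[2]`
#' slices) with peak expectation `noise_model$photon_scale` over a uniform
#' `background`, corrupted by Poisson photon noise and Gaussian read noise
#' of sd `read_sd`. With `noise = FALSE` the expected (noiseless) image is
#' returned, which is the ground-truth hook for localization tests.
#'
#' Voxel coordinates are 0-based voxel centers, so a spot at integer
#' coordinates peaks exactly in that voxel.
#'
#' @param tracks Track tibble in the standard schema for one cell (both
#'   channels), pixel/slice units.
#' @param cfg A [sim_config()].
#' @param noise Add Poisson + read noise? (default `TRUE`).
#' @param seed Seed for the noise draws; defaults to `cfg$seed`. Give each
#'   cell its own seed when rendering a cohort.
#' @return 5D numeric array with dimensions (time, channel, z, y, x);
#'   channel 1 = focus, 2 = fiducial. Attributes: `axes = "tczyx"`,
#'   `channels`, and `clipped`, a data frame of (frame, channel) whose spot
#'   center fell outside the rendered volume (rendered clipped, flagged).
#' @export
render_stack <- function(tracks, cfg, noise = TRUE, seed = cfg$seed) {
  cfg <- validate_sim_config(cfg)
  chans <- c("focus", "fiducial")
  nt <- cfg$n_frames
  dims <- c(nt, length(chans), cfg$n_slices, cfg$img_size, cfg$img_size)
  clipped <- list()
  with_rng(seed, {
    stack <- array(0, dims)
    for (ci in seq_along(chans)) {
      tr <- tracks[tracks$channel == chans[ci], ]
      for (row in seq_len(nrow(tr))) {
        t <- tr$frame[row] + 1L
        if (t < 1 || t > nt) next
        pos <- c(tr$x_px[row], tr$y_px[row], tr$z_slice[row])
        inside <- pos[1] >= 0 && pos[1] <= cfg$img_size - 1 &&
          pos[2] >= 0 && pos[2] <= cfg$img_size - 1 &&
          pos[3] >= 0 && pos[3] <= cfg$n_slices - 1
        if (!inside) {
          warning(sprintf(
            "spot outside volume at frame %d channel %s; rendering clipped",
            tr$frame[row], chans[ci]), call. = FALSE)
          clipped[[length(clipped) + 1]] <-
            data.frame(frame = tr$frame[row], channel = chans[ci])
        }
        stack[t, ci, , , ] <- stack[t, ci, , , ] +
          gaussian_spot(pos, cfg$img_size, cfg$n_slices, cfg$psf_sigma,
                        cfg$noise_model$photon_scale)
      }
    }
    stack <- stack + cfg$noise_model$background
    if (noise) {
      n <- length(stack)
      stack[] <- rpois(n, lambda = pmax(stack, 0)) +
        rnorm(n, sd = cfg$noise_model$read_sd)
    }
    attr(stack, "axes") <- "tczyx"
    attr(stack, "channels") <- chans
    attr(stack, "clipped") <- if (length(clipped))
      do.call(rbind, clipped) else
      data.frame(frame = integer(), channel = character())
    stack
  })
}

# Expected-intensity volume (z, y, x) of one Gaussian spot; pos = (x, y, z)
# in 0-based pixel/slice coordinates.
gaussian_spot <- function(pos, img_size, n_slices, psf_sigma, amplitude) {
  gx <- exp(-((0:(img_size - 1)) - pos[1])^2 / (2 * psf_sigma[1]^2))
  gy <- exp(-((0:(img_size - 1)) - pos[2])^2 / (2 * psf_sigma[1]^2))
  gz <- exp(-((0:(n_slices - 1)) - pos[3])^2 / (2 * psf_sigma[2]^2))
  amplitude * outer(gz, outer(gy, gx))
}
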