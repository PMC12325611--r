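#' Simulation configuration for synthetic DSB-mobility experiments
#'
#' Bundles every knob of the synthetic experiment: the confined-diffusion
#' model of the tracked locus, the shared nuclear drift, the acquisition
#' geometry of the microscope, and the camera noise model. Defaults emulate
#' a typical spinning-disk acquisition of a yeast nucleus: 15 optical slices
#' at a 0.3 um z-step, one two-channel stack every 30 s for 20 min (41
#' frames including t = 0).
#'
#' @param confinement_radius Radius of the hard confining sphere, um.
#'   Reported radii of confinement for yeast chromosomal loci span roughly
#'   0.5--1.1 um; the default 0.8 um sits mid-range.
#' @param diffusion_coeff Short-time diffusion coefficient of the locus,
#'   um^2/s. The default 1e-3 um^2/s gives 30-s MSD steps of the order
#'   0.1 um^2, as seen for tagged yeast loci.
#' @param frame_interval Time between acquired frames, s.
#' @param n_frames Number of frames including t = 0 (41 = 20 min at 30 s).
#' @param n_cells Number of cells in a simulated cohort.
#' @param drift_sd Per-frame standard deviation, um, of the Gaussian
#'   random-walk drift shared bit-exactly by both channels (whole-nucleus
#'   motion that the fiducial subtraction must cancel).
#' @param spb_offset 3-vector, um: fixed offset of the spindle-pole body
#'   from the confinement center.
#' @param pixel_size Lateral pixel size, nm/pixel (106.7 nm: 16-um EMCCD
#'   pixels behind a 150x effective magnification).
#' @param z_step Axial slice spacing, nm.
#' @param n_slices Number of optical slices per stack.
#' @param psf_sigma Length-2 vector: Gaussian PSF sigma laterally (pixels)
#'   and axially (slices).
#' @param noise_model List with `photon_scale` (expected photons at the spot
#'   peak), `read_sd` (Gaussian read noise, counts) and `background`
#'   (uniform background level, counts).
#' @param img_size Lateral image size in pixels (square field).
#' @param n_substeps Brownian sub-steps integrated per frame interval.
#'   More sub-steps make the reflected walk a better approximation of
#'   continuous reflected Brownian motion (the per-substep RMS step should
#'   be small relative to `confinement_radius`).
#' @param loc_noise_sd Optional localization noise added to observed track
#'   coordinates, pixels (0 disables; rendering + detection is the realistic
#'   noise path).
#' @param seed Integer seed; a fixed seed makes every simulate_* output
#'   bit-identical.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(confinement_radius = 0.6, n_cells = 5, seed = 1)
#' cfg$n_frames
sim_config <- function(confinement_radius = 0.8,
                       diffusion_coeff = 1e-3,
                       frame_interval = 30,
                       n_frames = 41,
                       n_cells = 10,
                       drift_sd = 0.05,
                       spb_offset = c(0.9, 0.9, 0.3),
                       pixel_size = 106.7,
                       z_step = 300,
                       n_slices = 15,
                       psf_sigma = c(1.3, 1.0),
                       noise_model = list(photon_scale = 200,
                                          read_sd = 2,
                                          background = 10),
                       img_size = 48,
                       n_substeps = 10,
                       loc_noise_sd = 0,
                       seed = 1L) {
  cfg <- list(confinement_radius = confinement_radius,
              diffusion_coeff = diffusion_coeff,
              frame_interval = frame_interval,
              n_frames = n_frames,
              n_cells = n_cells,
              drift_sd = drift_sd,
              spb_offset = spb_offset,
              pixel_size = pixel_size,
              z_step = z_step,
              n_slices = n_slices,
              psf_sigma = psf_sigma,
              noise_model = noise_model,
              img_size = img_size,
              n_substeps = n_substeps,
              loc_noise_sd = loc_noise_sd,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (!is.numeric(cfg$confinement_radius) ||
      length(cfg$confinement_radius) != 1 ||
      is.na(cfg$confinement_radius) || cfg$confinement_radius <= 0)
    stop("`confinement_radius` must be positive (Inf = unconfined)",
         call. = FALSE)
  if (!is.numeric(cfg$diffusion_coeff) || cfg$diffusion_coeff < 0)
    stop("`diffusion_coeff` must be >= 0", call. = FALSE)
  pos(cfg$frame_interval, "frame_interval")
  pos(cfg$pixel_size, "pixel_size")
  pos(cfg$z_step, "z_step")
  if (cfg$n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  if (cfg$n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (cfg$n_slices < 1) stop("`n_slices` must be >= 1", call. = FALSE)
  if (cfg$n_substeps < 1) stop("`n_substeps` must be >= 1", call. = FALSE)
  if (cfg$drift_sd < 0) stop("`drift_sd` must be >= 0", call. = FALSE)
  if (cfg$loc_noise_sd < 0) stop("`loc_noise_sd` must be >= 0", call. = FALSE)
  if (length(cfg$spb_offset) != 3)
    stop("`spb_offset` must be a 3-vector (um)", call. = FALSE)
  if (length(cfg$psf_sigma) != 2 || any(cfg$psf_sigma <= 0))
    stop("`psf_sigma` must be c(lateral_px, axial_slices), both > 0",
         call. = FALSE)
  nm <- cfg$noise_model
  if (!is.list(nm) ||
      !all(c("photon_scale", "read_sd", "background") %in% names(nm)))
    stop("`noise_model` needs photon_scale, read_sd, background",
         call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  confinement R: %.3g um, D: %.3g um^2/s\n",
              x$confinement_radius, x$diffusion_coeff))
  cat(sprintf("  %d frames @ %g s, %d cells, drift sd %.3g um/frame\n",
              x$n_frames, x$frame_interval, x$n_cells, x$drift_sd))
  cat(sprintf("  volume: %dx%d px (%.4g nm/px), %d slices @ %g nm\n",
              x$img_size, x$img_size, x$pixel_size, x$n_slices, x$z_step))
  invisible(x)
}
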