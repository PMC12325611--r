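#' Fiducial correction and unit conversion of a paired track
#'
#' Converts pixel/slice coordinates to micrometres, subtracts the fiducial
#' (spindle-pole body) position from the focus position frame by frame to
#' cancel whole-cell and nuclear motion, and then subtracts the per-axis
#' mean of the corrected coordinates so the track is centered on its own
#' mean position. The result is the object all mobility mathematics
#' consume.
#'
#' The z coordinate is converted via `z_step` and carried along, but the
#' default confinement analysis is two-dimensional (see
#' [radius_of_confinement()]); axial localization is typically several-fold
#' worse than lateral, so z is retained for optional 3D MSD only.
#'
#' @param paired Paired tibble from [pair_channels()] or
#'   [pair_from_tracks()].
#' @param pixel_size Lateral pixel size, nm.
#' @param z_step Axial slice spacing, nm.
#' @param frame_interval Frame interval, s (to attach `t_s`).
#' @param cell_id Cell identifier carried through.
#' @return A `relative_track` tibble: `cell_id`, `frame`, `t_s`, `x`, `y`,
#'   `z` in um, mean-centered per axis. Attributes record `pixel_size` and
#'   `z_step`.
#' @export
correct_coordinates <- function(paired, pixel_size, z_step,
                                frame_interval = 30, cell_id = "cell") {
  stopifnot(pixel_size > 0, z_step > 0)
  if (is.null(paired) || nrow(paired) < 2)
    stop("cell rejected: fewer than 2 shared frames", call. = FALSE)
  if (is.unsorted(paired$frame, strictly = TRUE))
    stop("paired frames must be strictly increasing", call. = FALSE)
  x <- (paired$x_focus - paired$x_fiducial) * pixel_size / 1000
  y <- (paired$y_focus - paired$y_fiducial) * pixel_size / 1000
  z <- (paired$z_focus - paired$z_fiducial) * z_step / 1000
  out <- tibble::tibble(
    cell_id = cell_id,
    frame = as.integer(paired$frame),
    t_s = paired$frame * frame_interval,
    x = x - mean(x), y = y - mean(y), z = z - mean(z))
  attr(out, "pixel_size") <- pixel_size
  attr(out, "z_step") <- z_step
  class(out) <- c("relative_track", class(out))
  out
}

# Internal constructor for tracks already in centered um coordinates.
relative_track_from_um <- function(pos_um, frame_interval = 30,
                                   cell_id = "cell",
                                   frames = seq_len(nrow(pos_um)) - 1L) {
  out <- tibble::tibble(
    cell_id = cell_id, frame = as.integer(frames),
    t_s = frames * frame_interval,
    x = pos_um[, 1] - mean(pos_um[, 1]),
    y = pos_um[, 2] - mean(pos_um[, 2]),
    z = if (ncol(pos_um) >= 3) pos_um[, 3] - mean(pos_um[, 3]) else 0)
  class(out) <- c("relative_track", class(out))
  out
}

#' Time-averaged mean-squared displacement of one track
#'
#' For each lag of `k` frame intervals, averages the squared displacement
#' over every overlapping window of `k + 1` consecutive observed frames.
#' A pair only contributes when all frames it spans are present, so gaps
#' are never bridged (and the number of contributing pairs is
#' non-increasing in lag). Displacements use the x,y axes by default
#' (`dims = 2`); `dims = 3` includes z.
#'
#' @param track A `relative_track` from [correct_coordinates()].
#' @param max_lag_frames Largest lag, in frame intervals; truncated with a
#'   warning if it exceeds the track span.
#' @param dims 2 (x,y) or 3 (x,y,z).
#' @param overlapping Use all overlapping windows (default); `FALSE` uses
#'   disjoint windows only (sensitivity analysis).
#' @return An `msd_curve` tibble: `cell_id`, `lag_s`, `msd` (um^2),
#'   `n_pairs`. Lags with no eligible pairs are dropped.
#' @export
compute_msd <- function(track, max_lag_frames = NULL, dims = 2,
                        overlapping = TRUE) {
  stopifnot(dims %in% c(2, 3))
  if (nrow(track) < 2) stop("track needs >= 2 frames", call. = FALSE)
  frames <- track$frame
  dt <- infer_frame_interval(track)
  span <- max(frames) - min(frames)
  if (is.null(max_lag_frames)) max_lag_frames <- span
  if (max_lag_frames > span) {
    warning("max_lag exceeds track span; curve truncated", call. = FALSE)
    max_lag_frames <- span
  }
  pos <- as.matrix(track[, c("x", "y", "z")[seq_len(dims)]])
  # index positions on the full frame grid; gaps are NA rows
  grid <- min(frames):max(frames)
  full <- matrix(NA_real_, length(grid), dims)
  full[match(frames, grid), ] <- pos
  present <- !is.na(full[, 1])
  run <- cumsum(!present)  # pairs are gap-free iff run id matches
  res <- lapply(seq_len(max_lag_frames), function(k) {
    i <- seq_len(length(grid) - k)
    starts <- if (overlapping) i else i[(i - 1) %% k == 0]
    ok <- present[starts] & present[starts + k] &
      run[starts] == run[starts + k]
    starts <- starts[ok]
    if (!length(starts)) return(NULL)
    d2 <- rowSums((full[starts + k, , drop = FALSE] -
                   full[starts, , drop = FALSE])^2)
    data.frame(lag_s = k * dt, msd = mean(d2), n_pairs = length(starts))
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out))
    return(tibble::tibble(cell_id = character(), lag_s = double(),
                          msd = double(), n_pairs = integer()))
  tibble::tibble(cell_id = track$cell_id[1], lag_s = out$lag_s,
                 msd = out$msd, n_pairs = as.integer(out$n_pairs))
}

infer_frame_interval <- function(track) {
  df <- diff(track$frame)
  dts <- diff(track$t_s)
  dt <- unique(round(dts / df, 9))
  if (length(dt) != 1) stop("inconsistent frame interval", call. = FALSE)
  dt
}

#' Ensemble (across-cell) mean MSD with SEM
#'
#' Per lag, the unweighted mean over cells and the standard error of that
#' mean (`sd / sqrt(n_cells)`) over the cells contributing the lag. A lag
#' contributed by a single cell gets `sem = 0` and is flagged.
#'
#' @param curves List of `msd_curve` tibbles from [compute_msd()].
#' @return Tibble: `lag_s`, `mean_msd`, `sem`, `n_cells`, `sem_defined`.
#' @export
ensemble_msd <- function(curves) {
  if (!length(curves)) stop("no MSD curves supplied", call. = FALSE)
  all <- dplyr::bind_rows(curves)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$lag_s),
    mean_msd = mean(.data$msd),
    sem = if (dplyr::n() > 1) stats::sd(.data$msd) / sqrt(dplyr::n()) else 0,
    n_cells = dplyr::n(), .groups = "drop")
  out$sem_defined <- out$n_cells > 1
  dplyr::arrange(out, .data$lag_s)
}

#' Radius of confinement from position statistics
#'
#' Summarizes the territory a locus explores in a single scalar. Per-axis
#' normal fits of the mean-centered x and y positions give variances
#' `sigma_x^2`, `sigma_y^2` with the unbiased (n - 1) denominator; their
#' mean is `sigma^2`. The average squared deviation from the mean position,
#' `dr0^2 = dx0^2 + dy0^2`, uses the population (n) denominator. The radius
#' of confinement is then
#' \deqn{R_c = \sqrt{\tfrac{5}{4}\,(2\sigma^2 + \Delta r_0^2)}}
#' which equals the sphere radius exactly when positions are uniform in a
#' 3D ball (per-axis variance `R^2/5`). Only x and y enter; axial
#' localization is too coarse to help.
#'
#' @param track A `relative_track` (at least 3 frames).
#' @return A `confinement_result`: one-row tibble with `cell_id`,
#'   `n_frames`, `sigma2` (um^2), `dr0_2` (um^2), `rc` (um), `degenerate`
#'   (all positions identical).
#' @export
#' @examples
#' pos <- cbind(c(1, -1, 1, -1), 0)
#' tr <- dsbmotion:::relative_track_from_um(pos)
#' radius_of_confinement(tr)  # sigma2 2/3, dr0_2 1, rc 1.7078
radius_of_confinement <- function(track) {
  n <- nrow(track)
  if (n < 3) stop("radius of confinement needs >= 3 frames", call. = FALSE)
  x <- track$x - mean(track$x)
  y <- track$y - mean(track$y)
  sigma2 <- mean(c(stats::var(x), stats::var(y)))      # n - 1 denominator
  dr0_2 <- mean(x^2) + mean(y^2)                       # n denominator
  degenerate <- sigma2 == 0 && dr0_2 == 0
  tibble::tibble(cell_id = track$cell_id[1], n_frames = n,
                 sigma2 = sigma2, dr0_2 = dr0_2,
                 rc = sqrt(5 / 4 * (2 * sigma2 + dr0_2)),
                 degenerate = degenerate)
}

#' Analyze one experimental condition end to end
#'
#' Runs [correct_coordinates()], [compute_msd()] and
#' [radius_of_confinement()] for every cell of a condition and aggregates:
#' per-cell confinement results, the ensemble MSD, and a one-row summary.
#' Warns when fewer than `min_cells` cells are accepted, the conventional
#' floor for reporting a condition.
#'
#' @param cells Named list of paired-track tibbles (one per cell), or a
#'   standard track tibble with a `cell_id` column covering both channels.
#' @param pixel_size,z_step nm, as in [correct_coordinates()].
#' @param frame_interval s.
#' @param dims Dimensionality of the MSD (2 or 3).
#' @param max_lag_frames Largest MSD lag (frames); default half the track.
#' @param min_cells Floor below which a warning is emitted (default 10).
#' @param batch Optional day/batch label copied into the per-cell table for
#'   day-paired comparisons downstream.
#' @return List: `per_cell` (confinement results), `ensemble`
#'   (ensemble MSD), `summary` (one-row tibble with mean/SEM of Rc),
#'   `rejected` (named character vector of per-cell rejection reasons).
#' @export
analyze_condition <- function(cells, pixel_size, z_step,
                              frame_interval = 30, dims = 2,
                              max_lag_frames = NULL, min_cells = 10,
                              batch = NA_character_) {
  if (is.data.frame(cells)) {
    cells <- lapply(split(cells, cells$cell_id), pair_from_tracks)
  }
  if (!length(cells)) stop("no cells supplied", call. = FALSE)
  if (is.null(names(cells)) || any(names(cells) == ""))
    names(cells) <- sprintf("cell_%02d", seq_along(cells))
  rejected <- character()
  per_cell <- list()
  curves <- list()
  for (id in names(cells)) {
    rel <- tryCatch(
      correct_coordinates(cells[[id]], pixel_size, z_step,
                          frame_interval, cell_id = id),
      error = function(e) conditionMessage(e))
    if (is.character(rel)) { rejected[id] <- rel; next }
    if (nrow(rel) < 3) { rejected[id] <- "fewer than 3 frames"; next }
    ml <- if (is.null(max_lag_frames))
      max(1L, (max(rel$frame) - min(rel$frame)) %/% 2L) else max_lag_frames
    curves[[id]] <- compute_msd(rel, max_lag_frames = ml, dims = dims)
    per_cell[[id]] <- radius_of_confinement(rel)
  }
  if (!length(per_cell)) {
    stop("no accepted cells; rejections: ",
         paste(names(rejected), rejected, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  if (length(per_cell) < min_cells)
    warning(sprintf("only %d accepted cells (floor is %d)",
                    length(per_cell), min_cells), call. = FALSE)
  per_cell <- dplyr::bind_rows(per_cell)
  per_cell$batch <- batch
  summary <- tibble::tibble(
    n_cells = nrow(per_cell),
    mean_rc = mean(per_cell$rc),
    sem_rc = if (nrow(per_cell) > 1)
      stats::sd(per_cell$rc) / sqrt(nrow(per_cell)) else 0,
    mean_sigma2 = mean(per_cell$sigma2),
    mean_dr0_2 = mean(per_cell$dr0_2))
  list(per_cell = per_cell, ensemble = ensemble_msd(curves),
       summary = summary, rejected = rejected)
}
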