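# Independent oracles and small fixture builders used across test files.

# Brute-force all-pairs time-averaged MSD: double loop over observed frame
# pairs, a pair at lag k contributing only when every frame it spans is
# observed. Deliberately naive and independent of compute_msd().
msd_brute <- function(track, max_lag, dims = 2) {
  frames <- track$frame
  pos <- as.matrix(track[, c("x", "y", "z")[seq_len(dims)]])
  dt <- (track$t_s[2] - track$t_s[1]) / (track$frame[2] - track$frame[1])
  rows <- list()
  for (k in seq_len(max_lag)) {
    vals <- c()
    for (i in seq_along(frames)) {
      j <- match(frames[i] + k, frames)
      if (is.na(j)) next
      if (!all(frames[i]:(frames[i] + k) %in% frames)) next
      vals <- c(vals, sum((pos[j, ] - pos[i, ])^2))
    }
    if (length(vals))
      rows[[length(rows) + 1]] <- data.frame(
        lag_s = k * dt, msd = mean(vals), n_pairs = length(vals))
  }
  do.call(rbind, rows)
}

# Uniform samples in a 3D ball by rejection from the cube (independent of
# the package's direction-times-radius sampler).
runif_ball_reject <- function(n, R) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(runif(3 * n, -R, R), ncol = 3)
    cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), ]
}

runif_disk <- function(n, R) {
  th <- runif(n, 0, 2 * pi)
  r <- R * sqrt(runif(n))
  cbind(r * cos(th), r * sin(th))
}

# Centered relative track straight from a um coordinate matrix.
rel_track <- function(pos_um, dt = 30, cell_id = "cell",
                      frames = seq_len(nrow(pos_um)) - 1L) {
  dsbmotion:::relative_track_from_um(pos_um, frame_interval = dt,
                                     cell_id = cell_id, frames = frames)
}

# A random track with optional missing frames, for oracle-equivalence
# sweeps.
random_gappy_track <- function(n_frames = 50, drop = 0, dt = 30) {
  pos <- cbind(cumsum(rnorm(n_frames, sd = 0.1)),
               cumsum(rnorm(n_frames, sd = 0.1)),
               cumsum(rnorm(n_frames, sd = 0.1)))
  keep <- sort(c(1, n_frames,
                 sample(2:(n_frames - 1), n_frames - 2 - drop)))
  rel_track(pos[keep, , drop = FALSE], dt = dt, frames = keep - 1L)
}

# Track tibble in the standard schema for hand-placed spots.
spot_tracks_tbl <- function(frames, x, y, z, channel = "focus",
                            cell_id = "c", dt = 30, intensity = 1) {
  tibble::tibble(cell_id = cell_id, frame = as.integer(frames),
                 t_s = frames * dt, channel = channel,
                 x_px = x, y_px = y, z_slice = z, intensity = intensity)
}

empty_tracks_tbl <- function() {
  spot_tracks_tbl(integer(), double(), double(), double())[0, ]
}
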