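#' Link detections over time into tracks
#'
#' Greedy nearest-neighbor frame-to-frame assignment: at each frame, open
#' track ends and new detections are matched in order of increasing
#' distance; links longer than `max_displacement` are rejected, unmatched
#' detections seed new tracks, and a track missing more than `max_gap`
#' consecutive frames is closed. Missing frames stay missing — there is no
#' interpolation. Ties (two candidates at exactly equal distance) are broken
#' by higher detection intensity, then lower row index, so linking is
#' deterministic.
#'
#' @param detections Tibble from [detect_spots()] (one cell, one channel).
#' @param max_displacement Maximum link distance, pixels (z in slices).
#' @param max_gap Maximum number of consecutive missing frames tolerated
#'   within a track.
#' @param n_frames Total frames in the movie (for coverage); defaults to
#'   `max(frame) + 1`.
#' @return Tibble of track points: `track_id`, `frame`, `x`, `y`, `z`,
#'   `intensity`, `quality`, with a `coverage` attribute (named vector of
#'   per-track frame-coverage fractions). No detections give a zero-row
#'   tibble.
#' @export
link_tracks <- function(detections, max_displacement = 5, max_gap = 2,
                        n_frames = NULL) {
  empty <- tibble::tibble(track_id = integer(), frame = integer(),
                          x = double(), y = double(), z = double(),
                          intensity = double(), quality = double())
  if (is.null(detections) || !nrow(detections)) {
    attr(empty, "coverage") <- numeric()
    return(empty)
  }
  det <- as.data.frame(detections)
  det <- det[order(det$frame), ]
  if (is.null(n_frames)) n_frames <- max(det$frame) + 1L
  tracks <- list()   # each: list(points = df rows, last = c(x,y,z), last_frame)
  closed <- list()
  for (f in sort(unique(det$frame))) {
    rows <- det[det$frame == f, , drop = FALSE]
    # close stale tracks
    if (length(tracks)) {
      stale <- vapply(tracks, function(tr) f - tr$last_frame > max_gap + 1,
                      TRUE)
      closed <- c(closed, tracks[stale])
      tracks <- tracks[!stale]
    }
    assigned_det <- rep(FALSE, nrow(rows))
    assigned_trk <- rep(FALSE, length(tracks))
    if (length(tracks) && nrow(rows)) {
      dmat <- outer(seq_along(tracks), seq_len(nrow(rows)),
                    Vectorize(function(i, j) {
                      p <- tracks[[i]]$last
                      sqrt((p[1] - rows$x[j])^2 + (p[2] - rows$y[j])^2 +
                           (p[3] - rows$z[j])^2)
                    }))
      repeat {
        dmat2 <- dmat
        dmat2[assigned_trk, ] <- Inf
        dmat2[, assigned_det] <- Inf
        mn <- min(dmat2)
        if (!is.finite(mn) || mn > max_displacement) break
        cand <- which(dmat2 == mn, arr.ind = TRUE)
        if (nrow(cand) > 1) {  # tie: higher intensity, then lower index
          ints <- rows$intensity[cand[, 2]]
          cand <- cand[order(-ints, cand[, 1], cand[, 2]), , drop = FALSE]
        }
        i <- cand[1, 1]; j <- cand[1, 2]
        tracks[[i]]$points <- rbind(tracks[[i]]$points, rows[j, ])
        tracks[[i]]$last <- c(rows$x[j], rows$y[j], rows$z[j])
        tracks[[i]]$last_frame <- f
        assigned_trk[i] <- TRUE
        assigned_det[j] <- TRUE
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(
        points = rows[j, , drop = FALSE],
        last = c(rows$x[j], rows$y[j], rows$z[j]),
        last_frame = f)
      assigned_trk <- c(assigned_trk, TRUE)
    }
  }
  closed <- c(closed, tracks)
  if (!length(closed)) {
    attr(empty, "coverage") <- numeric()
    return(empty)
  }
  # longest tracks first, stable
  ord <- order(-vapply(closed, function(tr) nrow(tr$points), 1L))
  closed <- closed[ord]
  pts <- dplyr::bind_rows(lapply(seq_along(closed), function(i) {
    p <- closed[[i]]$points
    p$track_id <- i
    p
  }))
  out <- tibble::as_tibble(pts[, c("track_id", "frame", "x", "y", "z",
                                   "intensity", "quality")])
  cov <- vapply(split(out$frame, out$track_id),
                function(fr) length(unique(fr)) / n_frames, 1.0)
  attr(out, "coverage") <- cov
  out
}

#' Pair the focus track with its fiducial track
#'
#' Selects, among the fiducial-channel tracks, the one sharing the most
#' frames with the focus track (ties broken by smaller mean xy distance —
#' with two spindle-pole bodies in view, the one nearer the focus wins) and
#' emits only the frames present in both tracks. Cells whose shared-frame
#' coverage falls below `min_coverage` are rejected with a reason, since a
#' sparse fiducial makes the drift correction unreliable.
#'
#' @param focus_tracks Track tibble from [link_tracks()] for the focus
#'   channel; the longest track is used if several exist.
#' @param fiducial_tracks Track tibble from [link_tracks()] for the
#'   fiducial channel.
#' @param n_frames Total frames in the movie.
#' @param min_coverage Minimum fraction of `n_frames` that must be present
#'   in both tracks (default 0.8).
#' @return A list: `ok` (logical), `paired` (tibble with `frame`, focus and
#'   fiducial coordinates, or `NULL`), `reason` (string when rejected).
#' @export
pair_channels <- function(focus_tracks, fiducial_tracks, n_frames,
                          min_coverage = 0.8) {
  if (!nrow(focus_tracks))
    return(list(ok = FALSE, paired = NULL, reason = "no focus track"))
  if (!nrow(fiducial_tracks))
    return(list(ok = FALSE, paired = NULL, reason = "no fiducial track"))
  foc_ids <- unique(focus_tracks$track_id)
  foc_len <- vapply(foc_ids, function(id)
    sum(focus_tracks$track_id == id), 1L)
  foc <- focus_tracks[focus_tracks$track_id == foc_ids[which.max(foc_len)], ]
  fid_ids <- unique(fiducial_tracks$track_id)
  score <- vapply(fid_ids, function(id) {
    fid <- fiducial_tracks[fiducial_tracks$track_id == id, ]
    shared <- intersect(foc$frame, fid$frame)
    prox <- if (length(shared)) {
      a <- foc[match(shared, foc$frame), ]
      b <- fid[match(shared, fid$frame), ]
      mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
    } else Inf
    c(n = length(shared), prox = prox)
  }, c(n = 0, prox = 0))
  best <- order(-score["n", ], score["prox", ])[1]
  fid <- fiducial_tracks[fiducial_tracks$track_id == fid_ids[best], ]
  shared <- sort(intersect(foc$frame, fid$frame))
  if (length(shared) / n_frames < min_coverage) {
    return(list(ok = FALSE, paired = NULL,
                reason = sprintf("paired coverage %.2f below %.2f",
                                 length(shared) / n_frames, min_coverage)))
  }
  a <- foc[match(shared, foc$frame), ]
  b <- fid[match(shared, fid$frame), ]
  paired <- tibble::tibble(
    frame = shared,
    x_focus = a$x, y_focus = a$y, z_focus = a$z,
    x_fiducial = b$x, y_fiducial = b$y, z_fiducial = b$z)
  list(ok = TRUE, paired = paired, reason = NULL)
}

#' Build the paired-track table directly from a standard track tibble
#'
#' Convenience for simulated or re-read tracks that already carry channel
#' labels in the standard CSV schema: frames with both a `focus` and a
#' `fiducial` row are paired.
#'
#' @param tracks Tibble in the standard track schema (one cell).
#' @return Paired tibble as produced by [pair_channels()].
#' @export
pair_from_tracks <- function(tracks) {
  foc <- tracks[tracks$channel == "focus", ]
  fid <- tracks[tracks$channel == "fiducial", ]
  shared <- sort(intersect(foc$frame, fid$frame))
  a <- foc[match(shared, foc$frame), ]
  b <- fid[match(shared, fid$frame), ]
  tibble::tibble(
    frame = shared,
    x_focus = a$x_px, y_focus = a$y_px, z_focus = a$z_slice,
    x_fiducial = b$x_px, y_fiducial = b$y_px, z_fiducial = b$z_slice)
}
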