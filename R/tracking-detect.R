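#' Detect fluorescent spots in one channel of a stack
#'
#' A documented, auditable detector standing in for interactive trackers:
#' each frame's volume is band-pass filtered with a difference of Gaussians
#' (sigmas `dog_sigma` and `2 * dog_sigma`), local maxima over the full
#' 26-voxel neighborhood exceeding `median + threshold * MAD` of the
#' filtered volume are kept, spots closer than `min_separation` are merged
#' into the brighter one, and each surviving peak is refined to
#' subpixel/subslice position by the intensity-weighted centroid of the
#' background-subtracted raw volume in a fixed window.
#'
#' @param stack 5D array (time, channel, z, y, x) as from [render_stack()]
#'   or [read_stack()].
#' @param channel Channel name (matched against the `channels` attribute)
#'   or index.
#' @param threshold Peak threshold in robust-noise (MAD) units.
#' @param dog_sigma Lateral sigma, pixels, of the narrow Gaussian; the axial
#'   sigma is scaled by `axial_ratio`.
#' @param axial_ratio Axial-to-lateral sigma ratio (slices per pixel-sigma).
#' @param min_separation Minimum distance, pixels (z in slices), between
#'   reported spots.
#' @param centroid_halfwidth Integer half-width (pixels) of the lateral
#'   centroid window; axial half-width is half of it (min 1 slice).
#' @return Tibble of detections: `frame` (0-based), `channel`, `x`, `y`
#'   (subpixel, 0-based), `z` (subslice), `intensity` (raw peak), `quality`
#'   (filtered peak in MAD units). Empty frames simply contribute no rows.
#' @export
detect_spots <- function(stack, channel, threshold = 5, dog_sigma = 1.3,
                         axial_ratio = 0.8, min_separation = 4,
                         centroid_halfwidth = 4L) {
  chans <- attr(stack, "channels")
  ci <- if (is.character(channel)) match(channel, chans) else as.integer(channel)
  if (is.na(ci) || ci < 1 || ci > dim(stack)[2])
    stop("unknown channel: ", channel, call. = FALSE)
  ch_name <- if (!is.null(chans)) chans[ci] else as.character(ci)
  nt <- dim(stack)[1]
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    vol <- array(stack[t, ci, , , ], dim(stack)[3:5])  # (z, y, x)
    det <- detect_in_volume(vol, threshold, dog_sigma, axial_ratio,
                            min_separation, centroid_halfwidth)
    if (nrow(det)) {
      det$frame <- t - 1L
      det$channel <- ch_name
      out[[t]] <- det
    }
  }
  det <- dplyr::bind_rows(out)
  if (!nrow(det))
    return(tibble::tibble(frame = integer(), channel = character(),
                          x = double(), y = double(), z = double(),
                          intensity = double(), quality = double()))
  det <- det[order(det$frame, -det$quality), ]
  tibble::as_tibble(det[, c("frame", "channel", "x", "y", "z",
                            "intensity", "quality")])
}

detect_in_volume <- function(vol, threshold, dog_sigma, axial_ratio,
                             min_separation, centroid_halfwidth) {
  filt <- gauss_blur3(vol, dog_sigma * axial_ratio, dog_sigma, dog_sigma) -
    gauss_blur3(vol, 2 * dog_sigma * axial_ratio, 2 * dog_sigma,
                2 * dog_sigma)
  noise <- stats::mad(filt)
  if (noise == 0) noise <- stats::sd(filt)
  if (is.na(noise) || noise == 0) noise <- .Machine$double.eps
  thr <- stats::median(filt) + threshold * noise
  maxima <- local_maxima3(filt) & filt > thr
  # border voxels only compete with interior neighbors and ride on filter
  # edge effects; restrict detections to the interior
  d <- dim(maxima)
  maxima[c(1, d[1]), , ] <- FALSE
  maxima[, c(1, d[2]), ] <- FALSE
  maxima[, , c(1, d[3])] <- FALSE
  peaks <- which(maxima, arr.ind = TRUE)
  if (!nrow(peaks)) {
    return(data.frame(x = double(), y = double(), z = double(),
                      intensity = double(), quality = double()))
  }
  quality <- (filt[peaks] - stats::median(filt)) / noise
  ord <- order(-quality)
  peaks <- peaks[ord, , drop = FALSE]
  quality <- quality[ord]
  # merge peaks closer than min_separation, keeping the strongest
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1):nrow(peaks)
      d <- sqrt((peaks[later, 3] - peaks[i, 3])^2 +
                (peaks[later, 2] - peaks[i, 2])^2 +
                (peaks[later, 1] - peaks[i, 1])^2)
      keep[later][d < min_separation] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  quality <- quality[keep]
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    ctr <- refine_centroid(vol, peaks[i, ], centroid_halfwidth)
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               intensity = vol[peaks[i, 1], peaks[i, 2], peaks[i, 3]],
               quality = quality[i])
  })
  do.call(rbind, res)
}

# Intensity-weighted centroid around an integer peak (z, y, x index,
# 1-based) on the background-subtracted raw volume. Background is the
# median of the window shell. Returns (x, y, z) 0-based.
refine_centroid <- function(vol, peak, hw) {
  hz <- max(1L, hw %/% 2L)
  zr <- max(1, peak[1] - hz):min(dim(vol)[1], peak[1] + hz)
  yr <- max(1, peak[2] - hw):min(dim(vol)[2], peak[2] + hw)
  xr <- max(1, peak[3] - hw):min(dim(vol)[3], peak[3] + hw)
  w <- vol[zr, yr, xr, drop = FALSE]
  edge <- c(w[1, , ], w[length(zr), , ], w[, 1, ], w[, length(yr), ],
            w[, , 1], w[, , length(xr)])
  w <- pmax(w - stats::median(edge), 0)
  tot <- sum(w)
  if (tot <= 0) return(c(peak[3], peak[2], peak[1]) - 1)
  wz <- apply(w, 1, sum); wy <- apply(w, 2, sum); wx <- apply(w, 3, sum)
  c(sum((xr - 1) * wx), sum((yr - 1) * wy), sum((zr - 1) * wz)) / tot
}

# Separable Gaussian blur of a (z, y, x) volume with replicate padding.
gauss_blur3 <- function(vol, sz, sy, sx) {
  vol <- blur_dim(vol, 1, sz)
  vol <- blur_dim(vol, 2, sy)
  blur_dim(vol, 3, sx)
}

blur_dim <- function(a, dim_i, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  perm <- c(dim_i, setdiff(1:3, dim_i))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, d[1], d[2] * d[3])
  n <- nrow(m)
  pad <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1), , drop = FALSE]
  ap <- array(out, d)
  aperm(ap, order(perm))
}

# Logical array: strict local maxima over the 26-neighborhood (ties lose).
local_maxima3 <- function(a) {
  d <- dim(a)
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  res <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pad[(2 + dz):(d[1] + 1 + dz),
              (2 + dy):(d[2] + 1 + dy),
              (2 + dx):(d[3] + 1 + dx)]
    res <- res & (a > nb)
  }
  res
}
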