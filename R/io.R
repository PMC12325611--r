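TRACK_COLS <- c(cell_id = "character", frame = "integer", t_s = "double",
                channel = "character", x_px = "double", y_px = "double",
                z_slice = "double", intensity = "double")
CQ_COLS <- c(sample = "character", timepoint_h = "double",
             site = "character", treatment = "character",
             replicate = "integer", cq = "double")

#' Read / write the standard tracks CSV
#'
#' The interchange dialect between stages: columns `cell_id`, `frame`
#' (0-based), `t_s`, `channel` (`focus`/`fiducial`), `x_px`, `y_px`,
#' `z_slice`, `intensity`, with an optional `condition` column. Reading
#' validates the schema and reports offending rows by line number;
#' writing then reading is lossless.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_tracks_csv <- function(path) {
  tab <- read_checked_csv(path, TRACK_COLS, optional = c(condition = "character"))
  bad <- which(!is.finite(tab$x_px) | !is.finite(tab$y_px) |
               !is.finite(tab$z_slice) | tab$frame < 0)
  if (length(bad))
    stop(sprintf("%s: malformed track rows at line(s) %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  tab
}

#' @rdname read_tracks_csv
#' @param tracks Tibble in the track schema.
#' @export
write_tracks_csv <- function(tracks, path) {
  miss <- setdiff(names(TRACK_COLS), names(tracks))
  if (length(miss))
    stop("tracks table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  readr::write_csv(tracks, path)
  invisible(path)
}

#' Read / write the standard Cq CSV
#'
#' Columns `sample`, `timepoint_h`, `site`, `treatment` (`mock`/`digest`),
#' `replicate`, `cq`; extra columns (QC flags) pass through.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_cq_csv <- function(path) {
  tab <- read_checked_csv(path, CQ_COLS,
                          optional = c(flag_ceiling = "logical"))
  bad <- which(!is.finite(tab$cq) | tab$cq <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive or missing cq at line(s) %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  tab
}

#' @rdname read_cq_csv
#' @param cq_table Tibble in the Cq schema.
#' @export
write_cq_csv <- function(cq_table, path) {
  miss <- setdiff(names(CQ_COLS), names(cq_table))
  if (length(miss))
    stop("cq table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  readr::write_csv(cq_table, path)
  invisible(path)
}

read_checked_csv <- function(path, schema, optional = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(names(schema), names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (nm in names(schema)) {
    tab[[nm]] <- switch(schema[[nm]],
                        character = as.character(tab[[nm]]),
                        integer = as.integer(tab[[nm]]),
                        double = as.numeric(tab[[nm]]),
                        logical = as.logical(tab[[nm]]))
  }
  tibble::as_tibble(tab)
}

#' Write / read a multi-dimensional image stack as TIFF
#'
#' Stacks are 5D arrays with axis order (time, channel, z, y, x). Pages are
#' flattened in that order (z fastest) into a multi-page 32-bit TIFF;
#' intensities are affinely mapped into \[0, 1\] for storage and the axis
#' order, dimensions, channel names and the affine scale are recorded in a
#' JSON sidecar (`<path>.json`), so reading restores the array exactly up
#' to float-32 rounding. Readers of stacks without the sidecar must supply
#' the dimensions via `override`.
#'
#' @param stack 5D array as from [render_stack()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) == 5)
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  meta <- list(axes = "tczyx", dim = d,
               channels = attr(stack, "channels"),
               offset = lo, scale = scale)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[i]] <- (matrix(stack[t, ch, z, , ], d[4], d[5]) - lo) / scale
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param override Optional list with `dim` (length-5), `channels`,
#'   `offset`, `scale` when the file lacks the metadata tag or it must be
#'   overridden.
#' @export
read_stack <- function(path, override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF %s: %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  meta <- override
  if (is.null(meta)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("stack has no metadata sidecar; pass `override`", call. = FALSE)
    meta <- jsonlite::fromJSON(sidecar)
  }
  d <- as.integer(meta$dim)
  if (length(d) != 5 || prod(d[1:3]) != length(pages))
    stop("stack dimensions do not match page count", call. = FALSE)
  offset <- if (is.null(meta$offset)) 0 else meta$offset
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  stack <- array(0, d)
  i <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    stack[t, ch, z, , ] <- pages[[i]] * scale + offset
    i <- i + 1L
  }
  attr(stack, "axes") <- "tczyx"
  attr(stack, "channels") <- meta$channels
  stack
}
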