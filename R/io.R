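#' Write and read cell tracks as CSV
#'
#' The track CSV schema has one row per sample: `cell_id`, `frame` (0-based),
#' `t_min`, `x_um`, `y_um`, `region`.
#'
#' @param tracks A `cell_track` or list of them.
#' @param path CSV path.
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns a list of `cell_track` objects.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop(sprintf("track CSV must contain columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    cell_track(times = d$t_min, x = d$x_um, y = d$y_um,
               cell_id = d$cell_id[1],
               region = if ("region" %in% names(d)) d$region[1]
                        else NA_character_)
  })
}

#' Write and read nucleus tables as CSV
#'
#' Schema: `nucleus_id`, `x_um`, `y_um`, `major_um`, `minor_um`,
#' `orientation_rad`, plus any marker flag columns (logical).
#'
#' @param nuclei A `nucleus_table` data frame.
#' @param path CSV path.
#' @return `write_nuclei_csv` returns `path` invisibly; `read_nuclei_csv`
#'   returns a `nucleus_table`.
#' @export
write_nuclei_csv <- function(nuclei, path) {
  utils::write.csv(as.data.frame(nuclei), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop(sprintf("nuclei CSV must contain columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  class(df) <- c("nucleus_table", "data.frame")
  df
}

#' Write and read image stacks as multi-page TIFF
#'
#' Frames are rescaled to `[0, 1]` on write by `scale_max` (default 255,
#' matching the 8-bit-like intensity scale of the synthetic generator) and
#' rescaled back on read. Frame rate and pixel size are not stored in the
#' TIFF and must be supplied when reading.
#'
#' @param stack An [image_stack()].
#' @param path TIFF path.
#' @param scale_max Intensity corresponding to 1.0 in the file.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an `image_stack`.
#' @export
write_stack_tiff <- function(stack, path, scale_max = 255) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f)
    pmin(pmax(f / scale_max, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param frame_rate,pixel_size Acquisition parameters for the stack read
#'   back from disk.
#' @export
read_stack_tiff <- function(path, frame_rate, pixel_size = 1,
                            scale_max = 255) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f * scale_max
  })
  image_stack(frames, frame_rate = frame_rate, pixel_size = pixel_size)
}

#' Export a density map as CSV
#'
#' @param map A `density_map`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Export a motion waveform as CSV
#'
#' @param waveform A `motion_waveform`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "motion_waveform"))
  utils::write.csv(as.data.frame(waveform), path, row.names = FALSE)
  invisible(path)
}
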