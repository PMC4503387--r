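#' Construct a single-cell track
#'
#' A `cell_track` holds one cell's sampled positions over time in the
#' pattern's coordinate frame (um), sampled at a uniform interval.
#'
#' @param times Sample times in minutes, uniformly spaced.
#' @param x,y Coordinates in um.
#' @param cell_id Identifier.
#' @param region Optional `"centre"` or `"perimeter"` label (usually set by
#'   [assign_region()]).
#' @return A `cell_track` object.
#' @export
cell_track <- function(times, x, y, cell_id = "cell_1", region = NA_character_) {
  if (length(times) < 2L) stop("a track needs at least 2 samples", call. = FALSE)
  if (length(x) != length(times) || length(y) != length(times))
    stop("times, x and y must have equal length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("track coordinates and times must be finite", call. = FALSE)
  dts <- diff(times)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt))
    stop("track sampling must be uniform", call. = FALSE)
  structure(list(cell_id = as.character(cell_id),
                 t = as.numeric(times), x = as.numeric(x), y = as.numeric(y),
                 dt = dt, region = region),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track %s: %d samples, dt = %g min, region = %s>\n",
              x$cell_id, length(x$t), x$dt, x$region))
  invisible(x)
}

#' @export
as.data.frame.cell_track <- function(x, ...) {
  data.frame(cell_id = x$cell_id, frame = seq_along(x$t) - 1L,
             t_min = x$t, x_um = x$x, y_um = x$y, region = x$region,
             stringsAsFactors = FALSE)
}

#' Region assignment rule for circular patterns
#'
#' Cells (and annuli) are split into `centre` and `perimeter` by the radial
#' distance from the pattern centre: strictly greater than `radial_threshold`
#' is perimeter. The default threshold of 100 um corresponds to half the
#' radius of a 400-um pattern.
#'
#' @param centre Pattern centre `c(x, y)` in um.
#' @param radial_threshold Threshold radius in um (default 100).
#' @return A `region_rule` object.
#' @export
region_rule <- function(centre = c(0, 0), radial_threshold = 100) {
  check_config(list(
    centre = is.numeric(centre) && length(centre) == 2L && all(is.finite(centre)),
    radial_threshold = is_pos(radial_threshold)
  ), "region rule")
  structure(list(centre = as.numeric(centre),
                 radial_threshold = radial_threshold),
            class = "region_rule")
}

#' Circular pattern geometry
#'
#' @param centre Pattern centre `c(x, y)` in um.
#' @param diameter Pattern diameter in um (typical values 200, 400, 600).
#' @param annulus_width Width of the concentric annuli used for density maps,
#'   in um (default 15).
#' @return A `pattern_geometry` object.
#' @export
pattern_geometry <- function(centre = c(0, 0), diameter = 400,
                             annulus_width = 15) {
  check_config(list(
    centre = is.numeric(centre) && length(centre) == 2L && all(is.finite(centre)),
    diameter = is_pos(diameter),
    annulus_width = is_pos(annulus_width) && annulus_width <= diameter / 2
  ), "pattern geometry")
  structure(list(centre = as.numeric(centre), diameter = diameter,
                 annulus_width = annulus_width),
            class = "pattern_geometry")
}

#' Grayscale image stack
#'
#' @param frames List of numeric matrices of identical dimension.
#' @param frame_rate Frames per second.
#' @param pixel_size Pixel size in um/pixel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, frame_rate, pixel_size = 1) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("an image stack needs at least 2 frames", call. = FALSE)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of equal dimension",
                     call. = FALSE)
  check_config(list(frame_rate = is_pos(frame_rate),
                    pixel_size = is_pos(pixel_size)), "image stack")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack: %d frames of %dx%d px, %g fps, %g um/px>\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$pixel_size))
  invisible(x)
}
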