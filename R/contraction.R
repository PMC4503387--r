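#' Block-matching motion estimation on an image stack
#'
#' Estimates tissue motion between every pair of consecutive frames by
#' exhaustive block matching: for each block on a regular grid, the integer
#' displacement within `search_radius` that minimizes the dissimilarity cost,
#' refined to subpixel precision by quadratic interpolation of the cost
#' surface along each axis. The default cost is the sum of squared
#' differences (SSD), whose cost surface is locally quadratic so the parabola
#' refinement is unbiased; sum of absolute differences (SAD) is available but
#' its V-shaped cost surface makes subpixel estimates conservative.
#'
#' A block is flagged non-confident when it is featureless (intensity s.d. at
#' or below `var_floor`), its cost minimum is not unique, or the minimum lies
#' on the search border; non-confident vectors are reported but excluded from
#' downstream waveform averaging.
#'
#' @param stack An [image_stack()].
#' @param block_size Block side in pixels (default 16).
#' @param search_radius Search radius in pixels (default 8).
#' @param step Grid step between block origins in pixels (default 8).
#' @param cost `"ssd"` (default) or `"sad"`.
#' @param var_floor Minimum block intensity s.d. for a confident vector
#'   (default 5, above typical sensor noise and well below tissue texture
#'   contrast).
#' @return A `motion_field`: arrays `dx`, `dy` (um, dims blocks-rows x
#'   blocks-cols x frame pairs), `confident` (logical, same dims), block
#'   centre coordinates `bx`, `by` (pixels), plus the parameters,
#'   `frame_rate` and `pixel_size`.
#' @export
block_match_motion <- function(stack, block_size = 16, search_radius = 8,
                               step = 8, cost = c("ssd", "sad"),
                               var_floor = 5) {
  stopifnot(inherits(stack, "image_stack"))
  cost <- match.arg(cost)
  check_config(list(
    block_size = is_count(block_size, min = 4),
    search_radius = is_count(search_radius, min = 1),
    step = is_count(step, min = 1),
    var_floor = is_nonneg(var_floor)
  ), "block matching")

  n_pairs <- length(stack$frames) - 1L
  first <- .block_match_pair(stack$frames[[1]], stack$frames[[2]],
                             block_size, search_radius, step, var_floor,
                             cost == "sad")
  nbr <- nrow(first$dx); nbc <- ncol(first$dx)
  dx <- array(NA_real_, c(nbr, nbc, n_pairs))
  dy <- array(NA_real_, c(nbr, nbc, n_pairs))
  confident <- array(FALSE, c(nbr, nbc, n_pairs))
  px <- stack$pixel_size
  dx[, , 1] <- first$dx * px; dy[, , 1] <- first$dy * px
  confident[, , 1] <- first$confident
  if (n_pairs > 1L) {
    for (k in 2:n_pairs) {
      m <- .block_match_pair(stack$frames[[k]], stack$frames[[k + 1]],
                             block_size, search_radius, step, var_floor,
                             cost == "sad")
      dx[, , k] <- m$dx * px; dy[, , k] <- m$dy * px
      confident[, , k] <- m$confident
    }
  }
  structure(list(dx = dx, dy = dy, confident = confident,
                 bx = first$bx, by = first$by,
                 block_size = block_size, search_radius = search_radius,
                 step = step, cost = cost, var_floor = var_floor,
                 frame_rate = stack$frame_rate, pixel_size = px),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  d <- dim(x$dx)
  cat(sprintf(
    "<motion_field: %dx%d blocks x %d frame pairs (block %d, search %d, step %d, %s)>\n",
    d[1], d[2], d[3], x$block_size, x$search_radius, x$step, x$cost))
  invisible(x)
}

#' Motion waveform from a motion field
#'
#' The mean speed at each inter-frame midpoint is the spatial mean of the
#' displacement magnitudes over confident blocks, converted to um/s by the
#' frame rate. Intervals in which no block is confident are flagged missing
#' (`NA` speed).
#'
#' @param field A `motion_field` from [block_match_motion()].
#' @param frame_rate Frames per second; defaults to the field's own.
#' @return A `motion_waveform` data frame: `time_s` (inter-frame midpoints),
#'   `mean_speed` (um/s), `n_confident`.
#' @export
motion_waveform <- function(field, frame_rate = field$frame_rate) {
  stopifnot(inherits(field, "motion_field"))
  n_pairs <- dim(field$dx)[3]
  speed <- sqrt(field$dx^2 + field$dy^2) * frame_rate
  mean_speed <- numeric(n_pairs); n_conf <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    cf <- field$confident[, , k]
    n_conf[k] <- sum(cf)
    mean_speed[k] <- if (n_conf[k] > 0) mean(speed[, , k][cf]) else NA_real_
  }
  out <- data.frame(time_s = (seq_len(n_pairs) - 0.5) / frame_rate,
                    mean_speed = mean_speed, n_confident = n_conf)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("motion_waveform", "data.frame")
  out
}

# prominence of each local maximum: height above the higher of the two
# lowest points separating it from higher terrain (or the series ends)
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- min_before_higher(y, p, -1L)
    right <- min_before_higher(y, p, +1L)
    h - max(left, right)
  }, numeric(1))
}

# lowest point between a peak and the nearest strictly higher sample in the
# given direction (or the series end, whichever comes first)
min_before_higher <- function(y, p, dir) {
  i <- p + dir
  lo <- y[p]
  while (i >= 1L && i <= length(y) && y[i] <= y[p]) {
    lo <- min(lo, y[i])
    i <- i + dir
  }
  lo
}

#' Detect beats in a motion waveform
#'
#' The speed waveform of beating tissue shows two humps per beat cycle
#' (contraction and relaxation). Peaks are found by prominence-based
#' detection (prominence at least `min_prominence` of the waveform maximum,
#' at least `min_separation` apart); alternate peaks are then labelled
#' contraction/relaxation, starting from the larger of the first two peaks
#' (first wins when they differ by less than 10%). Beat frequency is
#' estimated from the span of the contraction peaks:
#' `(n_contraction - 1) / (t_last - t_first)`; the maximal contraction
#' velocity is the largest contraction-peak speed.
#'
#' A waveform whose speed variation is indistinguishable from a flat noise
#' floor (interquartile range below 20% of the median) is flagged quiescent:
#' 0 Hz, no peaks.
#'
#' @param waveform A `motion_waveform`.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   waveform maximum (default 0.3).
#' @param min_separation Minimum time between successive peaks in seconds
#'   (default 0.2).
#' @return A `beat_summary` list: `beat_frequency` (Hz),
#'   `max_contraction_velocity` (um/s), `peaks` (data frame `time_s`,
#'   `speed`, `phase`), `quiescent`, and the input `waveform`.
#' @export
detect_beats <- function(waveform, min_prominence = 0.3,
                         min_separation = 0.2) {
  stopifnot(inherits(waveform, "motion_waveform"))
  check_config(list(min_prominence = is_prob(min_prominence),
                    min_separation = is_nonneg(min_separation)),
               "beat detection")
  y <- waveform$mean_speed
  tt <- waveform$time_s
  if (max(tt) - min(tt) < 2)
    stop("beat detection needs at least 2 s of waveform", call. = FALSE)
  ok <- is.finite(y)
  y2 <- y[ok]; t2 <- tt[ok]

  quiescent_out <- function() {
    structure(list(beat_frequency = 0, max_contraction_velocity = 0,
                   peaks = data.frame(time_s = numeric(0), speed = numeric(0),
                                      phase = character(0)),
                   quiescent = TRUE, waveform = waveform),
              class = "beat_summary")
  }
  if (length(y2) < 5L) return(quiescent_out())
  med <- stats::median(y2)
  if (stats::IQR(y2) < 0.2 * med) return(quiescent_out())

  # interior local maxima
  n <- length(y2)
  is_peak <- which(diff(sign(diff(y2))) < 0) + 1L
  if (!length(is_peak)) return(quiescent_out())
  prom <- peak_prominences(y2, is_peak)
  keep <- prom >= min_prominence * max(y2)
  pk <- is_peak[keep]
  if (!length(pk)) return(quiescent_out())

  # enforce minimum separation, keeping the higher peak
  ord <- pk[order(y2[pk], decreasing = TRUE)]
  sel <- integer(0)
  for (p in ord)
    if (!length(sel) ||
        all(abs(t2[p] - t2[sel]) >= min_separation - 1e-9))
      sel <- c(sel, p)
  pk <- sort(sel)
  if (!length(pk)) return(quiescent_out())

  # alternate contraction / relaxation labels, starting from the larger of
  # the first two peaks (ties within 10% go to the first)
  start <- 1L
  if (length(pk) >= 2L) {
    h1 <- y2[pk[1]]; h2 <- y2[pk[2]]
    if (h2 > h1 && abs(h1 - h2) > 0.1 * max(h1, h2)) start <- 2L
  }
  phase <- ifelse((seq_along(pk) - start) %% 2L == 0L,
                  "contraction", "relaxation")
  peaks <- data.frame(time_s = t2[pk], speed = y2[pk], phase = phase,
                      stringsAsFactors = FALSE)
  ctr <- peaks[peaks$phase == "contraction", ]
  bf <- if (nrow(ctr) >= 2L)
    (nrow(ctr) - 1) / (max(ctr$time_s) - min(ctr$time_s)) else 0
  structure(list(beat_frequency = bf,
                 max_contraction_velocity = if (nrow(ctr)) max(ctr$speed) else 0,
                 peaks = peaks, quiescent = FALSE, waveform = waveform),
            class = "beat_summary")
}

#' @export
print.beat_summary <- function(x, ...) {
  cat(sprintf(
    "<beat_summary: %.3g Hz, max contraction velocity %.3g um/s, %d peaks%s>\n",
    x$beat_frequency, x$max_contraction_velocity, nrow(x$peaks),
    if (x$quiescent) ", quiescent" else ""))
  invisible(x)
}

#' Contraction heatmap
#'
#' Per-block maximum speed over the recording, on the block grid: the spatial
#' signature of where the tissue beats. Non-confident vectors are ignored;
#' blocks never confident map to 0.
#'
#' @param field A `motion_field`.
#' @return A `contraction_heatmap`: list with `matrix` (um/s, blocks-rows x
#'   blocks-cols), block centres `bx`, `by` (pixels) and `pixel_size`.
#' @export
contraction_heatmap <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  speed <- sqrt(field$dx^2 + field$dy^2) * field$frame_rate
  speed[!field$confident] <- 0
  m <- apply(speed, c(1, 2), max)
  structure(list(matrix = m, bx = field$bx, by = field$by,
                 pixel_size = field$pixel_size),
            class = "contraction_heatmap")
}

#' Render a contraction heatmap to a PNG file
#'
#' @param heatmap A `contraction_heatmap`.
#' @param path Output PNG path.
#' @param palette Colour ramp function (default heat colours).
#' @return Invisibly, `path`.
#' @export
write_heatmap_png <- function(heatmap, path,
                              palette = grDevices::colorRampPalette(
                                c("black", "darkred", "red", "orange", "yellow"))) {
  stopifnot(inherits(heatmap, "contraction_heatmap"))
  m <- heatmap$matrix
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  cols <- palette(256)
  idx <- pmin(255L, as.integer(scaled * 255)) + 1L
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  img <- array(0, c(nrow(m), ncol(m), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(m)); img[, , 2] <- matrix(rgb[2, ], nrow(m))
  img[, , 3] <- matrix(rgb[3, ], nrow(m))
  png::writePNG(img, path)
  invisible(path)
}

#' Compare beat metrics between two experimental conditions
#'
#' Given per-chamber beat summaries (and optional externally measured chamber
#' metrics such as height or half-width-half-maximum), reports per-metric
#' group mean, s.d. and a two-sided Student's t-test p-value. Degenerate
#' (zero-variance) metrics are reported as exact-equality comparisons
#' (p = 1 when equal, 0 otherwise) rather than raising.
#'
#' @param a,b Lists of `beat_summary` objects, or data frames with columns
#'   `beat_frequency` and `max_contraction_velocity` (plus any extra numeric
#'   metric columns, which are compared too).
#' @param labels Group labels, length 2.
#' @return A `condition_comparison` data frame: one row per metric with group
#'   means, s.d.s and `p_value`.
#' @export
compare_conditions <- function(a, b, labels = c("control", "treated")) {
  to_df <- function(g, nm) {
    if (is.data.frame(g)) return(g)
    if (is.list(g) && all(vapply(g, inherits, logical(1), "beat_summary")))
      return(data.frame(
        beat_frequency = vapply(g, `[[`, numeric(1), "beat_frequency"),
        max_contraction_velocity =
          vapply(g, `[[`, numeric(1), "max_contraction_velocity")))
    stop(sprintf("group '%s' must be a data frame or list of beat summaries",
                 nm), call. = FALSE)
  }
  da <- to_df(a, labels[1]); db <- to_df(b, labels[2])
  if (nrow(da) < 2L) stop(sprintf("group '%s' needs n >= 2", labels[1]),
                          call. = FALSE)
  if (nrow(db) < 2L) stop(sprintf("group '%s' needs n >= 2", labels[2]),
                          call. = FALSE)
  metrics <- intersect(names(da), names(db))
  metrics <- metrics[vapply(da[metrics], is.numeric, logical(1))]
  out <- do.call(rbind, lapply(metrics, function(m) {
    va <- da[[m]]; vb <- db[[m]]
    data.frame(metric = m,
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               p_value = safe_t_test(va, vb),
               stringsAsFactors = FALSE)
  }))
  names(out)[2:5] <- c(paste0("mean_", labels[1]), paste0("sd_", labels[1]),
                       paste0("mean_", labels[2]), paste0("sd_", labels[2]))
  class(out) <- c("condition_comparison", "data.frame")
  out
}
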