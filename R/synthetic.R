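#' Simulate a persistent-random-walk cell track
#'
#' Generates a single-cell trajectory whose velocity is a stationary
#' two-dimensional Ornstein--Uhlenbeck process with correlation (persistence)
#' time `persistence_time` and root-mean-square speed `speed`, so the expected
#' mean-square displacement follows the persistent-random-walk closed form
#' \deqn{MSD(t) = 2 S^2 P [t - P(1 - e^{-t/P})].}
#'
#' The velocity and the displacement over each sampling interval are drawn
#' jointly from their exact conditional Gaussian distribution (exact
#' discretization, not an Euler scheme), so the closed form holds at the
#' sampled lags for any `dt`, not only in the small-step limit.
#'
#' @param persistence_time Persistence time P in minutes (> 0).
#' @param speed Root-mean-square cell speed S in um/min (>= 0).
#' @param dt Sampling interval in minutes (default 30, matching 30-min
#'   time-lapse imaging).
#' @param n_frames Number of sampled positions (default 49, i.e. 24 h at
#'   30-min intervals).
#' @param origin Starting position `c(x, y)` in um.
#' @param cell_id Identifier stored on the track.
#' @param seed Optional integer; fixed seed gives a bit-identical track.
#' @return A `cell_track` object (see [cell_track()]).
#' @examples
#' tr <- simulate_prw_track(60, 0.5, seed = 1)
#' plot(tr$x, tr$y, type = "l", asp = 1)
#' @export
simulate_prw_track <- function(persistence_time, speed, dt = 30, n_frames = 49,
                               origin = c(0, 0), cell_id = "cell_1",
                               seed = NULL) {
  check_config(list(
    persistence_time = is_pos(persistence_time),
    speed = is_nonneg(speed),
    dt = is_pos(dt),
    n_frames = is_count(n_frames, min = 2),
    origin = is.numeric(origin) && length(origin) == 2L && all(is.finite(origin))
  ), "synthetic track")

  P <- persistence_time
  n_steps <- n_frames - 1L
  times <- (seq_len(n_frames) - 1L) * dt

  if (speed == 0) {
    return(cell_track(times = times,
                      x = rep(origin[1], n_frames),
                      y = rep(origin[2], n_frames),
                      cell_id = cell_id))
  }

  sig2 <- speed^2 / 2          # stationary variance per velocity component
  th <- dt / P
  e1 <- exp(-th)

  # Exact conditional moments of (v(t+dt), integral of v over dt) given v(t)
  # for a stationary OU process; the 3-4e+e^2 combination is evaluated via
  # expm1 to stay accurate when dt << P.
  var_v <- sig2 * max(0, -expm1(-2 * th))           # sig2 (1 - e^2)
  g <- 3 - 4 * e1 + e1 * e1                          # -> 2*th - (2/3) th^3
  if (th < 1e-4) g <- 2 * th - (2 / 3) * th^3        # series guard
  var_x <- sig2 * max(0, P^2 * (2 * th - g))
  cov_xv <- sig2 * P * (-expm1(-th))^2               # sig2 P (1-e)^2

  # Cholesky of [[var_x, cov_xv], [cov_xv, var_v]] (guard tiny negatives)
  l11 <- sqrt(var_x)
  l21 <- if (l11 > 0) cov_xv / l11 else 0
  l22 <- sqrt(max(0, var_v - l21^2))

  with_seed(seed, function() {
    vx <- stats::rnorm(1, 0, sqrt(sig2))
    vy <- stats::rnorm(1, 0, sqrt(sig2))
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- origin[1]; y[1] <- origin[2]
    zx <- matrix(stats::rnorm(2 * n_steps), ncol = 2)
    zy <- matrix(stats::rnorm(2 * n_steps), ncol = 2)
    mean_fac <- P * (-expm1(-th))                    # E[dx | v] = v P (1-e)
    for (k in seq_len(n_steps)) {
      dx <- vx * mean_fac + l11 * zx[k, 1]
      dy <- vy * mean_fac + l11 * zy[k, 1]
      vx <- vx * e1 + l21 * zx[k, 1] + l22 * zx[k, 2]
      vy <- vy * e1 + l21 * zy[k, 1] + l22 * zy[k, 2]
      x[k + 1] <- x[k] + dx
      y[k + 1] <- y[k] + dy
    }
    cell_track(times = times, x = x, y = y, cell_id = cell_id)
  })
}

#' Simulate a cohort of PRW tracks
#'
#' Convenience wrapper drawing `n_tracks` independent tracks with common
#' parameters; track seeds are derived from `seed` so the cohort is
#' reproducible as a whole.
#'
#' @inheritParams simulate_prw_track
#' @param n_tracks Number of tracks.
#' @param origins Optional 2-column matrix of starting positions (recycled).
#' @param id_prefix Prefix for generated cell ids.
#' @return List of `cell_track` objects.
#' @export
simulate_prw_cohort <- function(n_tracks, persistence_time, speed, dt = 30,
                                n_frames = 49, origins = NULL,
                                id_prefix = "cell", seed = NULL) {
  stopifnot(is_count(n_tracks))
  if (is.null(origins)) origins <- matrix(0, n_tracks, 2)
  origins <- matrix(rep(t(origins), length.out = 2 * n_tracks),
                    ncol = 2, byrow = TRUE)
  seeds <- if (is.null(seed)) rep(list(NULL), n_tracks)
           else as.list(seed + seq_len(n_tracks))
  lapply(seq_len(n_tracks), function(i)
    simulate_prw_track(persistence_time, speed, dt, n_frames,
                       origin = origins[i, ],
                       cell_id = sprintf("%s_%03d", id_prefix, i),
                       seed = seeds[[i]]))
}

#' Simulate a circular colony of nuclei with an annular high-density band
#'
#' Samples nucleus centroids on a circular pattern with a piecewise-constant
#' radial density: a band `[band_inner_radius, band_outer_radius)` is
#' `band_density_multiplier` times denser than the rest of the pattern. Marker
#' positivity is drawn per nucleus with a band-specific probability, and
#' nucleus major/minor axes follow a region-specific axis ratio, band nuclei
#' oriented tangentially. This emulates the condensation phenotype of confined
#' colonies: a dense, marker-positive, elongated-nucleus annulus near the
#' pattern perimeter.
#'
#' @param pattern_diameter Pattern diameter in um (default 400).
#' @param n_cells Number of nuclei (default 2000, a dense epithelial
#'   monolayer on a 400-um pattern).
#' @param band_inner_radius,band_outer_radius Radial extent of the dense band
#'   in um (defaults 150 and 200).
#' @param band_density_multiplier Density of the band relative to the rest of
#'   the pattern (>= 1; default 3).
#' @param marker_prob_band,marker_prob_elsewhere Probability that a nucleus is
#'   marker-positive inside / outside the band (defaults 0.9 and 0.1).
#' @param nucleus_axis_ratio_band,nucleus_axis_ratio_centre Mean major/minor
#'   axis ratio for band and non-band nuclei (defaults 2.0 and 1.2).
#' @param nucleus_diameter_um Geometric-mean nucleus axis length in um
#'   (default 10).
#' @param marker_name Name of the logical marker column (default `"OCT4"`).
#' @param centre Pattern centre `c(x, y)` in um.
#' @param seed Optional integer seed.
#' @return A `nucleus_table` data frame with columns `nucleus_id`, `x_um`,
#'   `y_um`, `major_um`, `minor_um`, `orientation_rad`, `region` and one
#'   logical marker column. Attribute `"geometry"` holds the matching
#'   [pattern_geometry()].
#' @export
simulate_colony <- function(pattern_diameter = 400, n_cells = 2000,
                            band_inner_radius = 150, band_outer_radius = 200,
                            band_density_multiplier = 3,
                            marker_prob_band = 0.9,
                            marker_prob_elsewhere = 0.1,
                            nucleus_axis_ratio_band = 2.0,
                            nucleus_axis_ratio_centre = 1.2,
                            nucleus_diameter_um = 10,
                            marker_name = "OCT4",
                            centre = c(0, 0), seed = NULL) {
  R <- pattern_diameter / 2
  check_config(list(
    pattern_diameter = is_pos(pattern_diameter),
    n_cells = is_count(n_cells),
    band_inner_radius = is_nonneg(band_inner_radius),
    band_outer_radius = is_pos(band_outer_radius) &&
      band_outer_radius > band_inner_radius && band_outer_radius <= R,
    band_density_multiplier = is.numeric(band_density_multiplier) &&
      band_density_multiplier >= 1,
    marker_prob_band = is_prob(marker_prob_band),
    marker_prob_elsewhere = is_prob(marker_prob_elsewhere),
    nucleus_axis_ratio_band = is.numeric(nucleus_axis_ratio_band) &&
      nucleus_axis_ratio_band >= 1,
    nucleus_axis_ratio_centre = is.numeric(nucleus_axis_ratio_centre) &&
      nucleus_axis_ratio_centre >= 1
  ), "synthetic colony")

  # crude packing bound: even a pseudostratified colony, with nuclei stacked
  # at several z-levels, rarely exceeds ~1 nucleus / 10 um^2 in projection
  area <- pi * R^2
  max_cells <- floor(area / 10)
  if (n_cells > max_cells)
    stop(sprintf(
      "n_cells = %d exceeds the packing bound %d for a %g-um pattern",
      n_cells, max_cells, pattern_diameter), call. = FALSE)

  # radial shells with piecewise-constant density; mass = area x multiplier
  shells <- data.frame(
    inner = c(0, band_inner_radius, band_outer_radius),
    outer = c(band_inner_radius, band_outer_radius, R),
    mult  = c(1, band_density_multiplier, 1)
  )
  shells <- shells[shells$outer > shells$inner, , drop = FALSE]
  shells$area <- pi * (shells$outer^2 - shells$inner^2)
  shells$mass <- shells$area * shells$mult

  with_seed(seed, function() {
    shell_idx <- sample.int(nrow(shells), n_cells, replace = TRUE,
                            prob = shells$mass)
    u <- stats::runif(n_cells)
    r <- sqrt(shells$inner[shell_idx]^2 +
                u * (shells$outer[shell_idx]^2 - shells$inner[shell_idx]^2))
    phi <- stats::runif(n_cells, 0, 2 * pi)
    in_band <- r >= band_inner_radius & r < band_outer_radius

    marker <- stats::rbinom(n_cells, 1,
                            ifelse(in_band, marker_prob_band,
                                   marker_prob_elsewhere)) == 1

    ratio <- ifelse(in_band, nucleus_axis_ratio_band,
                    nucleus_axis_ratio_centre) *
      exp(stats::rnorm(n_cells, 0, 0.05))
    ratio <- pmax(ratio, 1)
    major <- nucleus_diameter_um * sqrt(ratio)
    minor <- nucleus_diameter_um / sqrt(ratio)
    orient <- ifelse(in_band, phi + pi / 2, stats::runif(n_cells, 0, pi))

    tab <- data.frame(
      nucleus_id = sprintf("nuc_%05d", seq_len(n_cells)),
      x_um = centre[1] + r * cos(phi),
      y_um = centre[2] + r * sin(phi),
      major_um = major,
      minor_um = minor,
      orientation_rad = orient %% pi,
      region = ifelse(in_band, "band", ifelse(r < band_inner_radius,
                                              "inner", "outer")),
      stringsAsFactors = FALSE
    )
    tab[[marker_name]] <- marker
    attr(tab, "geometry") <- pattern_geometry(centre = centre,
                                              diameter = pattern_diameter)
    class(tab) <- c("nucleus_table", "data.frame")
    tab
  })
}

#' Simulate an image stack of beating tissue
#'
#' Builds a grayscale time-lapse stack in which a textured disc undergoes
#' periodic radial displacement \eqn{u(t) = A sin(2 pi f t)}, with the
#' amplitude A chosen so that the peak displacement rate equals
#' `peak_velocity`. The texture is fixed-seed band-limited noise warped by the
#' analytic displacement field via bilinear interpolation, so block matching
#' has structure to lock onto; Gaussian sensor noise is added per frame. The
#' true per-interval mean speed waveform is attached for oracle tests.
#'
#' @param frame_rate Frames per second (default 20).
#' @param n_frames Number of frames (default 500).
#' @param beat_frequency Beat frequency f in Hz; must be below the Nyquist
#'   rate `frame_rate / 2`.
#' @param peak_velocity Peak tissue speed in um/s (default 10).
#' @param image_size Frame side length in pixels (default 128).
#' @param pixel_size Pixel size in um/pixel (default 1).
#' @param noise_sd Gaussian intensity noise s.d. (8-bit-like scale, default 2).
#' @param disc_radius_fraction Optional radius, as a fraction of
#'   `image_size`, of a disc to which texture and motion are confined (flat
#'   background outside); the default `NULL` lets the moving tissue fill the
#'   whole frame, as in a close-up recording of a beating microchamber.
#' @param seed Optional integer seed.
#' @return An `image_stack` (list of frames plus `frame_rate`, `pixel_size`)
#'   with attributes `true_waveform` (data frame `time_s`, `speed_um_s` at
#'   inter-frame midpoints) and `disc` (centre and radius in pixels).
#' @export
simulate_beating_stack <- function(frame_rate = 20, n_frames = 500,
                                   beat_frequency = 1, peak_velocity = 10,
                                   image_size = 128, pixel_size = 1,
                                   noise_sd = 2, disc_radius_fraction = NULL,
                                   seed = NULL) {
  check_config(list(
    frame_rate = is_pos(frame_rate),
    n_frames = is_count(n_frames, min = 2),
    beat_frequency = is_nonneg(beat_frequency),
    peak_velocity = is_nonneg(peak_velocity),
    image_size = is_count(image_size, min = 16),
    pixel_size = is_pos(pixel_size),
    noise_sd = is_nonneg(noise_sd),
    disc_radius_fraction = is.null(disc_radius_fraction) ||
      (is_pos(disc_radius_fraction) && disc_radius_fraction <= 0.5)
  ), "synthetic beat")
  if (beat_frequency >= frame_rate / 2)
    stop(sprintf(
      "beat_frequency (%g Hz) must be below the Nyquist rate %g Hz",
      beat_frequency, frame_rate / 2), call. = FALSE)
  if (beat_frequency > 0 && n_frames / frame_rate < 2 / beat_frequency)
    stop("stack must cover at least 2 full beat periods", call. = FALSE)

  A_um <- if (beat_frequency > 0) peak_velocity / (2 * pi * beat_frequency)
          else 0
  A_px <- A_um / pixel_size
  n <- image_size
  ctr <- (n + 1) / 2
  confined <- !is.null(disc_radius_fraction)
  disc_r <- if (confined) disc_radius_fraction * n else n / 2

  with_seed(seed, function() {
    # band-limited texture: white noise smoothed by a separable Gaussian
    tex <- matrix(stats::rnorm(n * n), n, n)
    ksd <- 2
    kh <- stats::dnorm(-6:6, sd = ksd); kh <- kh / sum(kh)
    tex <- apply(tex, 2, function(col) stats::filter(col, kh, circular = TRUE))
    tex <- t(apply(t(tex), 2, function(col)
      stats::filter(col, kh, circular = TRUE)))
    tex <- 100 + 30 * tex / stats::sd(tex)

    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), n), n, n)          # row index
    rx <- xs - ctr; ry <- ys - ctr
    rr <- sqrt(rx^2 + ry^2)
    inside <- if (confined) rr <= disc_r else matrix(TRUE, n, n)
    # unit radial direction; taper near the centre avoids the singular point
    safe_r <- pmax(rr, 1e-9)
    ux <- rx / safe_r; uy <- ry / safe_r
    taper_r <- 0.2 * disc_r
    g <- pmin(1, rr / taper_r)

    tt <- (seq_len(n_frames) - 1) / frame_rate
    u_px <- A_px * sin(2 * pi * beat_frequency * tt)

    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      fr <- matrix(100, n, n)
      # pull-back warp: sample texture at x - d(x)
      sx <- xs - u_px[k] * g * ux
      sy <- ys - u_px[k] * g * uy
      fr[inside] <- bilinear_sample(tex, sx[inside], sy[inside])
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
      frames[[k]] <- fr
    }

    stack <- image_stack(frames, frame_rate = frame_rate,
                         pixel_size = pixel_size)
    # true mean speed over the disc at inter-frame midpoints
    g_mean <- mean(g[inside])
    mid <- (tt[-1] + tt[-n_frames]) / 2
    speed_true <- abs(diff(u_px)) * pixel_size * frame_rate * g_mean
    attr(stack, "true_waveform") <- data.frame(time_s = mid,
                                               speed_um_s = speed_true)
    attr(stack, "disc") <- list(centre_px = c(ctr, ctr), radius_px = disc_r)
    stack
  })
}

# bilinear interpolation of matrix `img` at fractional (col = x, row = y)
bilinear_sample <- function(img, x, y) {
  n <- nrow(img); m <- ncol(img)
  x <- pmin(pmax(x, 1), m); y <- pmin(pmax(y, 1), n)
  x0 <- pmin(floor(x), m - 1L); y0 <- pmin(floor(y), n - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * n + y0
  v00 <- img[i00];       v10 <- img[i00 + 1L]
  v01 <- img[i00 + n];   v11 <- img[i00 + n + 1L]
  (1 - fx) * ((1 - fy) * v00 + fy * v10) + fx * ((1 - fy) * v01 + fy * v11)
}
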