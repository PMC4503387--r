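# Independent oracles and small fixture builders used across the suite.

# Brute-force MSD: enumerate every overlapping (i, i + k) pair explicitly.
# Deliberately naive; the implementation under test must agree exactly.
brute_force_msd <- function(track, max_lag_fraction = 1 / 3) {
  n <- length(track$t)
  n_int <- n - 1L
  k_max <- max(1L, floor(max_lag_fraction * n_int))
  vapply(seq_len(k_max), function(k) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2
      cnt <- cnt + 1L
    }
    acc / cnt
  }, numeric(1))
}

# closed-form PRW MSD used as a forward model in tests
prw_msd_closed_form <- function(t, P, S) {
  2 * S^2 * P * (t - P * (1 - exp(-t / P)))
}

random_track <- function(n, dt = 30, scale = 10) {
  cell_track(times = (seq_len(n) - 1) * dt,
             x = cumsum(stats::rnorm(n, sd = scale)),
             y = cumsum(stats::rnorm(n, sd = scale)))
}

straight_track <- function(n = 49, v = 1, dt = 30, angle = 0.3) {
  tt <- (seq_len(n) - 1) * dt
  cell_track(times = tt, x = v * tt * cos(angle), y = v * tt * sin(angle))
}

# ensemble (pooled) MSD over a list of tracks: mean of per-track MSD curves
pooled_msd <- function(tracks, max_lag_fraction = 1 / 3) {
  curves <- lapply(tracks, compute_msd, max_lag_fraction = max_lag_fraction)
  out <- curves[[1]]
  out$msd <- rowMeans(vapply(curves, function(cv) cv$msd,
                             numeric(nrow(out))))
  out$n_pairs <- out$n_pairs * length(tracks)
  out
}

# brute-force annulus assignment: per-nucleus radius classification
brute_force_annulus_counts <- function(nuclei, geom) {
  R <- geom$diameter / 2
  w <- geom$annulus_width
  n_ann <- ceiling(R / w)
  counts <- integer(n_ann)
  out_of_pattern <- 0L
  for (i in seq_len(nrow(nuclei))) {
    r <- sqrt((nuclei$x_um[i] - geom$centre[1])^2 +
                (nuclei$y_um[i] - geom$centre[2])^2)
    if (r > R) { out_of_pattern <- out_of_pattern + 1L; next }
    j <- min(floor(r / w) + 1L, n_ann)
    counts[j] <- counts[j] + 1L
  }
  list(counts = counts, out_of_pattern = out_of_pattern)
}

# expected perimeter/centre density ratio for a colony config, from the
# generative piecewise-constant radial density and exact region areas
expected_density_ratio <- function(R = 200, band = c(150, 200), mult = 3,
                                   thr = 100) {
  seg_mass <- function(a, b) {
    # integral of density over the annulus [a, b], density 1 or mult in band
    lo <- pmax(a, band[1]); hi <- pmin(b, band[2])
    band_area <- if (hi > lo) pi * (hi^2 - lo^2) else 0
    pi * (b^2 - a^2) - band_area + mult * band_area
  }
  dens_c <- seg_mass(0, thr) / (pi * thr^2)
  dens_p <- seg_mass(thr, R) / (pi * (R^2 - thr^2))
  dens_p / dens_c
}

small_beating_stack <- function(f = 1, n_frames = 120, seed = 7, ...) {
  simulate_beating_stack(frame_rate = 20, n_frames = n_frames,
                         beat_frequency = f, peak_velocity = 10,
                         image_size = 96, seed = seed, ...)
}

# stack whose frames are exact integer circular shifts of one texture
shifted_stack <- function(dx, dy, n_frames = 2, n = 96, seed = 11) {
  set.seed(seed)
  tex <- matrix(stats::rnorm(n * n, 100, 20), n, n)
  shift_mat <- function(m, dr, dc) {
    ri <- ((seq_len(n) - 1 - dr) %% n) + 1
    ci <- ((seq_len(n) - 1 - dc) %% n) + 1
    m[ri, ci]
  }
  frames <- lapply(seq_len(n_frames) - 1L, function(k)
    shift_mat(tex, k * dy, k * dx))
  image_stack(frames, frame_rate = 20, pixel_size = 1)
}
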