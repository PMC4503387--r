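test_that("identical frames produce an all-zero motion field", {
  st <- shifted_stack(0, 0, n_frames = 3)
  fld <- block_match_motion(st)
  expect_true(all(fld$dx == 0) && all(fld$dy == 0))
  wf <- motion_waveform(fld)
  expect_equal(wf$mean_speed, c(0, 0))
})

test_that("featureless frames yield non-confident vectors and missing waveform", {
  flat <- image_stack(list(matrix(100, 64, 64), matrix(100, 64, 64),
                           matrix(100, 64, 64)), frame_rate = 20)
  fld <- block_match_motion(flat)
  expect_false(any(fld$confident))
  wf <- motion_waveform(fld)
  expect_true(all(is.na(wf$mean_speed)))
  expect_true(all(wf$n_confident == 0))
})

test_that("pure integer translations are recovered exactly", {
  for (d in list(c(3, 0), c(0, -2), c(-4, 5), c(7, 7))) {
    st <- shifted_stack(d[1], d[2])
    fld <- block_match_motion(st)
    conf <- fld$confident[, , 1]
    expect_true(all(conf))
    expect_true(all(fld$dx[, , 1][conf] == d[1]))
    expect_true(all(fld$dy[, , 1][conf] == d[2]))
  }
})

test_that("time-reversing a stack negates the field and preserves the waveform", {
  st <- small_beating_stack(f = 1, n_frames = 60)
  rev_st <- image_stack(rev(st$frames), st$frame_rate, st$pixel_size)
  f1 <- block_match_motion(st)
  f2 <- block_match_motion(rev_st)
  n <- dim(f1$dx)[3]
  both <- f1$confident & f2$confident[, , n:1]
  expect_gt(mean(both), 0.8)
  err_x <- abs(f1$dx + f2$dx[, , n:1])[both]
  err_y <- abs(f1$dy + f2$dy[, , n:1])[both]
  expect_lt(stats::median(err_x), 0.25)
  expect_lt(stats::median(err_y), 0.25)
  w1 <- motion_waveform(f1)$mean_speed
  w2 <- rev(motion_waveform(f2)$mean_speed)
  expect_equal(w1, w2, tolerance = 0.1)
})

test_that("block matching tracks the known analytic beating field", {
  st <- small_beating_stack(f = 1, n_frames = 120, seed = 13)
  fld <- block_match_motion(st)
  wf <- motion_waveform(fld)
  tw <- attr(st, "true_waveform")
  # compare at the high-motion samples, where subpixel error is relative
  hi <- tw$speed_um_s > 0.5 * max(tw$speed_um_s)
  rel <- abs(wf$mean_speed[hi] - tw$speed_um_s[hi]) / tw$speed_um_s[hi]
  expect_lt(stats::median(rel), 0.15)
})

test_that("waveform arithmetic converts uniform motion to um/s", {
  st <- shifted_stack(1, 0, n_frames = 5)     # 1 px/frame at 20 fps, 1 um/px
  wf <- motion_waveform(block_match_motion(st))
  expect_equal(wf$mean_speed, rep(20, 4))
  expect_equal(wf$time_s, (1:4 - 0.5) / 20)
})

test_that("beat detection finds frequency, phase and peak velocity", {
  st <- small_beating_stack(f = 1, n_frames = 200, seed = 17)
  beats <- detect_beats(motion_waveform(block_match_motion(st)))
  expect_false(beats$quiescent)
  expect_equal(beats$beat_frequency, 1, tolerance = 0.05)
  expect_equal(beats$max_contraction_velocity, 10, tolerance = 0.15)
  # two humps per cycle: contraction and relaxation alternate
  expect_true(all(rle(beats$peaks$phase)$lengths == 1))
})

test_that("peak-based frequency agrees with an FFT cross-check", {
  st <- small_beating_stack(f = 1.5, n_frames = 400, seed = 29)
  wf <- motion_waveform(block_match_motion(st))
  beats <- detect_beats(wf)
  # the speed of |cos| motion oscillates at twice the beat frequency; the
  # dominant FFT bin of the demeaned waveform is an independent estimate
  y <- wf$mean_speed - mean(wf$mean_speed)
  pw <- Mod(stats::fft(y))^2
  freqs <- (seq_along(y) - 1) / length(y) * attr(wf, "frame_rate")
  half <- 2:floor(length(y) / 2)
  f_fft <- freqs[half][which.max(pw[half])] / 2
  expect_equal(beats$beat_frequency, f_fft, tolerance = 0.05)
  expect_equal(beats$beat_frequency, 1.5, tolerance = 0.04)
})

test_that("quiescent tissue yields zero beats without false peaks", {
  st <- simulate_beating_stack(frame_rate = 20, n_frames = 80,
                               beat_frequency = 1, peak_velocity = 0,
                               image_size = 96, seed = 19)
  beats <- detect_beats(motion_waveform(block_match_motion(st)))
  expect_true(beats$quiescent)
  expect_equal(beats$beat_frequency, 0)
  expect_equal(beats$max_contraction_velocity, 0)
})

test_that("contraction heatmaps localize and scale with the motion", {
  st <- simulate_beating_stack(frame_rate = 20, n_frames = 50,
                               beat_frequency = 1, peak_velocity = 10,
                               image_size = 96, disc_radius_fraction = 0.3,
                               seed = 21)
  fld <- block_match_motion(st)
  hm <- contraction_heatmap(fld)
  disc <- attr(st, "disc")
  above <- which(hm$matrix > max(hm$matrix) / 2, arr.ind = TRUE)
  d <- sqrt((hm$bx[above] - disc$centre_px[1])^2 +
              (hm$by[above] - disc$centre_px[2])^2)
  # support of strong motion is concentric with the disc, within one block
  expect_true(all(d <= disc$radius_px + fld$block_size))
  # heatmap max dominates the waveform max by construction
  wf <- motion_waveform(fld)
  expect_gte(max(hm$matrix), max(wf$mean_speed, na.rm = TRUE))
  # doubling the peak velocity doubles the heatmap, block by block over the
  # beating region (the per-block maximum is noisy; compare the strong blocks)
  st2 <- simulate_beating_stack(frame_rate = 20, n_frames = 50,
                                beat_frequency = 1, peak_velocity = 20,
                                image_size = 96, disc_radius_fraction = 0.3,
                                seed = 21)
  hm2 <- contraction_heatmap(block_match_motion(st2))
  # compare blocks lying fully inside the disc; blocks straddling the disc
  # boundary mix moving and static pixels and their maxima are erratic
  inside <- sqrt((hm$bx - disc$centre_px[1])^2 +
                   (hm$by - disc$centre_px[2])^2) <
    disc$radius_px - fld$block_size / 2
  expect_equal(stats::median((hm2$matrix / hm$matrix)[inside]), 2,
               tolerance = 0.15)
})

test_that("heatmap PNG export writes a readable image", {
  st <- small_beating_stack(f = 1, n_frames = 40)
  hm <- contraction_heatmap(block_match_motion(st))
  path <- tempfile(fileext = ".png")
  write_heatmap_png(hm, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(hm$matrix))
})

test_that("condition comparisons report group statistics and t-tests", {
  make_group <- function(bf, cv) data.frame(beat_frequency = bf,
                                            max_contraction_velocity = cv)
  set.seed(23)
  a <- make_group(rnorm(6, 1.2, 0.05), rnorm(6, 10, 0.5))
  cmp_same <- compare_conditions(a, a)
  expect_true(all(abs(cmp_same$p_value - 1) < 1e-8))
  b <- make_group(rnorm(6, 0.6, 0.05), rnorm(6, 5, 0.5))
  cmp <- compare_conditions(a, b)
  expect_true(all(cmp$p_value < 0.05))
  expect_error(compare_conditions(a[1, , drop = FALSE], b), "control")
  # zero-variance metrics degrade to an exact-equality report
  consts <- make_group(rep(1, 3), rep(2, 3))
  cmp0 <- compare_conditions(consts, consts)
  expect_true(all(cmp0$p_value == 1))
})

test_that("block matching validates its configuration", {
  st <- shifted_stack(1, 0)
  expect_error(block_match_motion(st, block_size = 2), "block_size")
  expect_error(block_match_motion(st, search_radius = 0), "search_radius")
  tiny <- image_stack(list(matrix(1:64, 8, 8), matrix(1:64, 8, 8)),
                      frame_rate = 20)
  expect_error(block_match_motion(tiny), "too small")
})
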