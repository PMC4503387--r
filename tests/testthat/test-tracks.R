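test_that("compute_msd equals the brute-force all-pairs oracle", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    tr <- random_track(n)
    expect_equal(compute_msd(tr, 1)$msd, brute_force_msd(tr, 1))
    expect_equal(compute_msd(tr)$msd, brute_force_msd(tr))
  }
})

test_that("the 5-point worked example enumerates overlapping pairs correctly", {
  tr <- cell_track(times = 0:4, x = c(0, 1, 1, 2, 2), y = c(0, 0, 1, 1, 2))
  m <- compute_msd(tr, max_lag_fraction = 1)
  expect_equal(m$msd[1], 1)
  expect_equal(m$msd[2], 2)
  expect_equal(m$msd[3], mean(c((2 - 0)^2 + (1 - 0)^2,
                                (2 - 1)^2 + (2 - 0)^2)))
  expect_equal(m$n_pairs, c(4, 3, 2, 1))
})

test_that("ballistic and stationary closed forms hold exactly", {
  tr <- straight_track(n = 49, v = 1, dt = 30)
  m <- compute_msd(tr, max_lag_fraction = 1)
  expect_equal(m$msd, (30 * seq_len(48))^2)
  still <- cell_track(times = (0:10) * 30, x = rep(2, 11), y = rep(-1, 11))
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("MSD input validation rejects short or non-uniform tracks", {
  expect_error(cell_track(times = c(0, 30, 70), x = 1:3, y = 1:3), "uniform")
  tr2 <- cell_track(times = c(0, 30), x = c(0, 1), y = c(0, 1))
  expect_error(compute_msd(tr2), "insufficient")
})

test_that("noiseless PRW inversion recovers P, S and mu", {
  P <- 60; S <- 0.5
  lags <- seq(30, 480, by = 30)
  msd <- structure(data.frame(lag_min = lags,
                              msd = prw_msd_closed_form(lags, P, S),
                              n_pairs = rev(seq_along(lags)) + 10),
                   class = c("msd_curve", "data.frame"), dt = 30)
  fit <- fit_prw(msd)
  expect_true(fit$converged)
  expect_equal(fit$P, P, tolerance = 0.01)
  expect_equal(fit$S, S, tolerance = 0.01)
  expect_equal(fit$mu, S^2 * P / 2, tolerance = 0.02)
})

test_that("a flat MSD yields the degenerate zero-motility fit", {
  msd <- structure(data.frame(lag_min = (1:10) * 30, msd = numeric(10),
                              n_pairs = 10:1),
                   class = c("msd_curve", "data.frame"), dt = 30)
  fit <- fit_prw(msd)
  expect_true(fit$converged)
  expect_equal(fit$S, 0)
  expect_equal(fit$mu, 0)
  expect_equal(fit$residual_norm, 0)
})

test_that("a linear (diffusive-limit) MSD recovers the diffusion coefficient", {
  mu0 <- 2
  lags <- seq(30, 480, by = 30)
  msd <- structure(data.frame(lag_min = lags, msd = 4 * mu0 * lags,
                              n_pairs = rev(seq_along(lags)) + 10),
                   class = c("msd_curve", "data.frame"), dt = 30)
  fit <- fit_prw(msd)
  expect_equal(fit$mu, mu0, tolerance = 0.05)
})

test_that("the motility identity mu = S^2 P / 2 holds exactly for every fit", {
  set.seed(2)
  for (i in 1:10) {
    tr <- simulate_prw_track(sample(c(30, 60, 120), 1), runif(1, 0.2, 1),
                             seed = 100 + i)
    fit <- fit_prw(compute_msd(tr))
    if (fit$converged) expect_identical(fit$mu, fit$S^2 * fit$P / 2)
  }
})

test_that("MSD and PRW fits are invariant under rigid motion", {
  tr <- simulate_prw_track(60, 0.5, seed = 9)
  th <- 0.7; shift <- c(120, -45)
  tr2 <- cell_track(times = tr$t,
                    x = cos(th) * tr$x - sin(th) * tr$y + shift[1],
                    y = sin(th) * tr$x + cos(th) * tr$y + shift[2])
  m1 <- compute_msd(tr); m2 <- compute_msd(tr2)
  expect_equal(m1$msd, m2$msd, tolerance = 1e-10)
  f1 <- fit_prw(m1); f2 <- fit_prw(m2)
  expect_equal(f1$P, f2$P, tolerance = 1e-6)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
})

test_that("classification applies the strict mu > 5 rule with fit quality", {
  good <- structure(list(P = 60, S = 0.5, mu = 7.5, rel_residual = 0.05,
                         converged = TRUE, classification = NA),
                    class = "prw_fit")
  expect_equal(classify_migration(good)$classification, "biased")
  at_threshold <- good; at_threshold$mu <- 5.0
  expect_equal(classify_migration(at_threshold)$classification, "random")
  poor_fit <- good; poor_fit$rel_residual <- 0.5
  expect_equal(classify_migration(poor_fit)$classification, "random")
  diverged <- good; diverged$converged <- FALSE
  expect_equal(classify_migration(diverged)$classification, "random")
  stationary <- good; stationary$mu <- 0; stationary$rel_residual <- 0
  expect_equal(classify_migration(stationary)$classification, "random")
})

test_that("region assignment uses the first position and a strict boundary", {
  rule <- region_rule(centre = c(0, 0), radial_threshold = 100)
  at_centre <- cell_track(times = c(0, 30), x = c(0, 500), y = c(0, 0))
  expect_equal(assign_region(at_centre, rule)$region, "centre")
  out <- cell_track(times = c(0, 30), x = c(150, 0), y = c(0, 0))
  expect_equal(assign_region(out, rule)$region, "perimeter")
  boundary <- cell_track(times = c(0, 30), x = c(100, 0), y = c(0, 0))
  expect_equal(assign_region(boundary, rule)$region, "centre")
})

test_that("fitted mu increases with true speed at fixed persistence", {
  mus <- vapply(c(0.25, 0.5, 1.0), function(S) {
    tracks <- simulate_prw_cohort(100, 60, S, seed = round(1000 * S))
    fit_prw(pooled_msd(tracks))$mu
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("cohort summaries order regions by their generative parameters", {
  rule <- region_rule()
  centre_tracks <- simulate_prw_cohort(30, 120, 0.6, seed = 30,
                                       origins = matrix(c(10, 0), 30, 2,
                                                        byrow = TRUE))
  perim_tracks <- simulate_prw_cohort(30, 30, 0.3, seed = 60,
                                      origins = matrix(c(150, 0), 30, 2,
                                                       byrow = TRUE))
  tracks <- c(centre_tracks, perim_tracks)
  tracks <- lapply(tracks, assign_region, rule = rule)
  fits <- lapply(tracks, function(tr) classify_migration(fit_prw(compute_msd(tr))))
  summ <- summarize_cohort(tracks, fits)
  pr <- summ$per_region
  ctr <- pr[pr$region == "centre", ]; per <- pr[pr$region == "perimeter", ]
  expect_gt(ctr$velocity_mean, per$velocity_mean)
  expect_gt(ctr$mu_mean, per$mu_mean)
  expect_gt(ctr$P_mean, per$P_mean)
  expect_gte(ctr$pct_biased, per$pct_biased)
  expect_true(all(is.finite(summ$p_values)))
})

test_that("a single-region cohort is summarized without error", {
  tracks <- lapply(simulate_prw_cohort(5, 60, 0.5, seed = 80),
                   assign_region, rule = region_rule())
  fits <- lapply(tracks, function(tr) classify_migration(fit_prw(compute_msd(tr))))
  summ <- summarize_cohort(tracks, fits)
  expect_equal(summ$missing_regions, "perimeter")
  expect_equal(nrow(summ$per_region), 1)
  expect_true(all(is.na(summ$p_values)))
})
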