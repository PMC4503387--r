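#' Mean-square displacement by the overlapping-interval method
#'
#' For a track of \eqn{n} positions sampled at interval \eqn{\Delta t}, the
#' MSD at lag \eqn{k\Delta t} averages the squared displacement over all
#' \eqn{n - k} overlapping start indices:
#' \deqn{MSD(k\Delta t) = \frac{1}{n-k}\sum_{i=1}^{n-k}
#'   [x_{i+k}-x_i]^2 + [y_{i+k}-y_i]^2.}
#' Lags are restricted to `max_lag_fraction` of the total duration (default
#' one third), the customary window that keeps the high-lag estimates, which
#' average few intervals, out of the fit.
#'
#' @param track A [cell_track()].
#' @param max_lag_fraction Largest lag as a fraction of total duration,
#'   in (0, 1]; default 1/3.
#' @return An `msd_curve` data frame with columns `lag_min`, `msd` (um^2) and
#'   `n_pairs`; attribute `dt` carries the sampling interval.
#' @examples
#' tr <- simulate_prw_track(60, 0.5, seed = 1)
#' head(compute_msd(tr))
#' @export
compute_msd <- function(track, max_lag_fraction = 1 / 3) {
  stopifnot(inherits(track, "cell_track"))
  n <- length(track$t)
  if (n < 3L) stop("insufficient data: MSD needs at least 3 positions",
                   call. = FALSE)
  if (!is_pos(max_lag_fraction) || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]", call. = FALSE)
  n_int <- n - 1L
  k_max <- max(1L, floor(max_lag_fraction * n_int))
  msd <- numeric(k_max); npairs <- integer(k_max)
  for (k in seq_len(k_max)) {
    dx <- track$x[(1 + k):n] - track$x[1:(n - k)]
    dy <- track$y[(1 + k):n] - track$y[1:(n - k)]
    msd[k] <- mean(dx^2 + dy^2)
    npairs[k] <- n - k
  }
  out <- data.frame(lag_min = seq_len(k_max) * track$dt, msd = msd,
                    n_pairs = npairs)
  attr(out, "dt") <- track$dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

# PRW closed form: MSD(t) = 2 S^2 P [t - P(1 - exp(-t/P))]
prw_msd <- function(t, P, S) 2 * S^2 * P * (t - P * (-expm1(-t / P)))

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Fits \eqn{MSD(t) = 2 S^2 P [t - P(1 - e^{-t/P})]} by weighted nonlinear
#' least squares, returning the persistence time \eqn{P} (min), root-mean-square
#' speed \eqn{S} (um/min) and the random motility coefficient
#' \eqn{\mu = S^2 P / n_d} (um^2/min, \eqn{n_d = 2} for 2D migration).
#'
#' The optimisation runs over \eqn{(\log P, \log S)} so both parameters stay
#' positive. Lags are weighted by `n_pairs / msd^2`: the overlapping-interval
#' MSD estimator has a standard deviation proportional to its mean and to the
#' inverse square root of the pair count, so this weighting equalises the
#' relative error across lags and keeps the short, persistence-informative
#' lags from being swamped by the large long-lag values. Several persistence
#' starting values are tried and the best weighted fit kept; a fit that fails
#' to converge is returned with `converged = FALSE` rather than raising.
#'
#' Persistence times beyond the observation window cannot be told apart
#' from pure ballistic motion, so the fit is constrained to
#' `P <= 2 max(lag)`; single near-ballistic tracks sit at this bound rather
#' than diverging.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_d Migration dimensionality for the motility coefficient
#'   (default 2).
#' @return A `prw_fit` list: `P`, `S`, `mu`, `residual_norm` (um^2),
#'   `rel_residual`, `converged`, `classification` (unset, see
#'   [classify_migration()]).
#' @export
fit_prw <- function(msd, n_d = 2) {
  stopifnot(inherits(msd, "msd_curve"))
  if (nrow(msd) < 3L)
    stop("insufficient data: PRW fit needs at least 3 lags", call. = FALSE)
  tt <- msd$lag_min; yy <- msd$msd
  # constant-relative-error noise model for the overlapping MSD estimator
  w <- msd$n_pairs / pmax(yy, 1e-12 * max(yy, 1))^2
  msd_norm <- sqrt(sum(yy^2))

  new_fit <- function(P, S, resid, converged) {
    rn <- sqrt(sum(resid^2))
    structure(list(P = P, S = S, mu = S^2 * P / n_d,
                   n_d = n_d,
                   residual_norm = rn,
                   rel_residual = if (msd_norm > 0) rn / msd_norm else 0,
                   converged = converged,
                   classification = NA_character_),
              class = "prw_fit")
  }

  # degenerate flat curve: stationary cell, S = 0 at arbitrary P
  if (max(yy) <= 0) return(new_fit(P = tt[1], S = 0, resid = yy,
                                   converged = TRUE))

  # starting values: long-time linear regime msd ~ 4 mu t - 4 mu P
  half <- tt >= stats::median(tt)
  lf <- stats::lm.wfit(cbind(1, tt[half]), yy[half], w[half])
  mu0 <- max(unname(lf$coefficients[2]) / (2 * n_d), 1e-8)
  P0 <- -unname(lf$coefficients[1]) / (2 * n_d * mu0)
  t_max <- max(tt)
  # persistence times beyond the observation window are not identifiable
  # from the MSD; the fit is boxed to [t_max * 1e-4, 2 t_max] so that
  # near-ballistic tracks sit at the bound instead of diverging
  lp_lims <- log(c(t_max * 1e-4, t_max * 2))
  ls_lims <- c(-30, 30)
  P_starts <- unique(pmin(pmax(c(P0, tt[1], t_max / 3, t_max),
                               exp(lp_lims[1]) * 2),
                          exp(lp_lims[2]) / 2))

  best <- NULL; best_obj <- Inf
  for (P0i in P_starts) {
    S0i <- sqrt(max(n_d * mu0 / P0i, 1e-12))          # S^2 = n_d mu / P
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ prw_msd(tt, exp(lp), exp(ls)),
        start = list(lp = log(P0i), ls = min(max(log(S0i), ls_lims[1]),
                                             ls_lims[2])),
        lower = c(lp_lims[1], ls_lims[1]),
        upper = c(lp_lims[2], ls_lims[2]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(w * stats::residuals(fit)^2)
    if (obj < best_obj) { best_obj <- obj; best <- fit }
  }

  if (is.null(best)) {
    # Levenberg-Marquardt can fail outright in the diffusive limit, where the
    # model flattens to 2 S^2 P t and only the product S^2 P is identifiable;
    # fall back to direct minimisation of the weighted SSE.
    obj <- function(par) sum(w * (yy - prw_msd(tt, exp(par[1]), exp(par[2])))^2)
    bo <- NULL
    for (P0i in P_starts) {
      S0i <- sqrt(max(n_d * mu0 / P0i, 1e-12))
      o <- stats::optim(c(log(P0i), min(max(log(S0i), ls_lims[1]), ls_lims[2])),
                        obj, method = "L-BFGS-B",
                        lower = c(lp_lims[1], ls_lims[1]),
                        upper = c(lp_lims[2], ls_lims[2]),
                        control = list(maxit = 2000, factr = 10))
      if (is.null(bo) || o$value < bo$value) bo <- o
    }
    P_hat <- exp(bo$par[1]); S_hat <- exp(bo$par[2])
    return(new_fit(P_hat, S_hat, yy - prw_msd(tt, P_hat, S_hat),
                   converged = bo$convergence == 0))
  }
  cf <- stats::coef(best)
  P_hat <- exp(cf[["lp"]]); S_hat <- exp(cf[["ls"]])
  conv <- isTRUE(best$convInfo$isConv) && is.finite(P_hat) && is.finite(S_hat)
  new_fit(P = P_hat, S = S_hat, resid = yy - prw_msd(tt, P_hat, S_hat),
          converged = conv)
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_fit: P = %.3g min, S = %.3g um/min, mu = %.3g um^2/min,\n  rel. residual = %.3g, converged = %s, class = %s>\n",
    x$P, x$S, x$mu, x$rel_residual, x$converged, x$classification))
  invisible(x)
}

#' Classify a cell's migration as biased or random
#'
#' A cell is `"biased"` (directionally migrating) when its displacement data
#' are well described by the persistent-random-walk model *and* its motility
#' coefficient exceeds the threshold: `converged`, relative residual
#' `<= gof_threshold`, and `mu > mu_threshold` (strictly — a cell at exactly
#' the threshold is `"random"`). Everything else is `"random"`.
#'
#' @param fit A `prw_fit` from [fit_prw()].
#' @param mu_threshold Motility-coefficient threshold in um^2/min (default 5).
#' @param gof_threshold Maximum relative residual norm for an acceptable fit
#'   (default 0.3).
#' @return The fit with `classification` set.
#' @export
classify_migration <- function(fit, mu_threshold = 5, gof_threshold = 0.3) {
  stopifnot(inherits(fit, "prw_fit"))
  check_config(list(mu_threshold = is_nonneg(mu_threshold),
                    gof_threshold = is_pos(gof_threshold)),
               "migration classification")
  ok <- isTRUE(fit$converged) && is.finite(fit$mu) &&
    fit$rel_residual <= gof_threshold && fit$mu > mu_threshold
  fit$classification <- if (ok) "biased" else "random"
  fit
}

#' Assign a track to the centre or perimeter region
#'
#' Uses the track's *initial* position only: strictly more than
#' `radial_threshold` from the pattern centre is `"perimeter"`, otherwise
#' (including exactly at the threshold) `"centre"`.
#'
#' @param track A [cell_track()].
#' @param rule A [region_rule()].
#' @return The track with `region` set.
#' @export
assign_region <- function(track, rule = region_rule()) {
  stopifnot(inherits(track, "cell_track"), inherits(rule, "region_rule"))
  r0 <- sqrt((track$x[1] - rule$centre[1])^2 +
               (track$y[1] - rule$centre[2])^2)
  track$region <- if (r0 > rule$radial_threshold) "perimeter" else "centre"
  track
}

# mean frame-to-frame displacement per unit time, um/min
track_velocity <- function(track) {
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  mean(steps) / track$dt
}

#' Summarize a cohort of tracked cells by region
#'
#' Computes, per region (centre / perimeter), the mean and s.d. of migratory
#' velocity (mean frame-to-frame displacement over `dt`), motility coefficient
#' mu, persistence time P, and the percentage of cells classified as biased;
#' plus a two-sided Student's t-test p-value between regions for each
#' continuous metric (a generic utility, reported as-is).
#'
#' @param tracks List of region-assigned [cell_track()] objects.
#' @param fits List of classified `prw_fit` objects aligned with `tracks`.
#' @return A `cohort_summary` list with elements `per_region` (data frame),
#'   `p_values` (named numeric for velocity, mu, P), `missing_regions`
#'   (character), and `cells` (the per-cell table).
#' @export
summarize_cohort <- function(tracks, fits) {
  if (length(tracks) != length(fits))
    stop("tracks and fits must be aligned", call. = FALSE)
  cells <- data.frame(
    cell_id = vapply(tracks, function(tr) tr$cell_id, character(1)),
    region = vapply(tracks, function(tr) as.character(tr$region), character(1)),
    velocity = vapply(tracks, track_velocity, numeric(1)),
    mu = vapply(fits, function(f) f$mu, numeric(1)),
    P = vapply(fits, function(f) f$P, numeric(1)),
    biased = vapply(fits, function(f)
      identical(f$classification, "biased"), logical(1)),
    stringsAsFactors = FALSE
  )
  regions <- c("centre", "perimeter")
  present <- regions[regions %in% cells$region]
  missing <- setdiff(regions, present)

  per_region <- do.call(rbind, lapply(present, function(rg) {
    d <- cells[cells$region == rg, ]
    data.frame(region = rg, n = nrow(d),
               velocity_mean = mean(d$velocity), velocity_sd = stats::sd(d$velocity),
               mu_mean = mean(d$mu), mu_sd = stats::sd(d$mu),
               P_mean = mean(d$P), P_sd = stats::sd(d$P),
               pct_biased = 100 * mean(d$biased),
               stringsAsFactors = FALSE)
  }))

  p_values <- c(velocity = NA_real_, mu = NA_real_, P = NA_real_)
  if (length(present) == 2L) {
    for (m in names(p_values)) {
      a <- cells[cells$region == "centre", m]
      b <- cells[cells$region == "perimeter", m]
      p_values[[m]] <- safe_t_test(a, b)
    }
  }
  structure(list(per_region = per_region, p_values = p_values,
                 missing_regions = missing, cells = cells),
            class = "cohort_summary")
}

# Welch t-test that degrades gracefully on degenerate variance
safe_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$per_region, row.names = FALSE)
  if (length(x$missing_regions))
    cat("missing regions:", paste(x$missing_regions, collapse = ", "), "\n")
  cat("t-test p-values:",
      paste(sprintf("%s = %.3g", names(x$p_values), x$p_values),
            collapse = ", "), "\n")
  invisible(x)
}
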