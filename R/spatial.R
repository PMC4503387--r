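#' Per-annulus cell density map of a circular colony
#'
#' Dissects the pattern into concentric annuli of width
#' `geom$annulus_width` (default 15 um) and assigns each nucleus to an
#' annulus by its centroid radius. Annuli are half-open `[inner, outer)`
#' from the centre outward; the terminal annulus is closed at the pattern
#' radius and truncated (its true, smaller area is used) when the radius is
#' not a multiple of the annulus width. Nuclei outside the pattern circle are
#' excluded and tallied.
#'
#' @param nuclei A `nucleus_table` data frame (columns `x_um`, `y_um`, ...).
#' @param geom A [pattern_geometry()].
#' @return A `density_map` data frame with one row per annulus: `annulus`
#'   (1-based index), `inner_um`, `outer_um`, `count`, `area_um2`, `density`
#'   (cells/um^2). Attributes: `out_of_pattern` (excluded count), `geometry`.
#' @export
annulus_density_map <- function(nuclei, geom = pattern_geometry()) {
  stopifnot(is.data.frame(nuclei), inherits(geom, "pattern_geometry"))
  if (nrow(nuclei) == 0L) stop("nuclei table is empty", call. = FALSE)
  R <- geom$diameter / 2
  w <- geom$annulus_width
  r <- sqrt((nuclei$x_um - geom$centre[1])^2 +
              (nuclei$y_um - geom$centre[2])^2)
  inside <- r <= R
  n_ann <- ceiling(R / w)
  inner <- (seq_len(n_ann) - 1) * w
  outer <- pmin(seq_len(n_ann) * w, R)
  # [inner, outer) except the terminal annulus, closed at R
  idx <- pmin(floor(r[inside] / w) + 1L, n_ann)
  counts <- tabulate(idx, nbins = n_ann)
  area <- pi * (outer^2 - inner^2)
  out <- data.frame(annulus = seq_len(n_ann), inner_um = inner,
                    outer_um = outer, count = counts, area_um2 = area,
                    density = counts / area)
  attr(out, "out_of_pattern") <- sum(!inside)
  attr(out, "geometry") <- geom
  class(out) <- c("density_map", "data.frame")
  out
}

# radius of each nucleus relative to a centre
nucleus_radius <- function(nuclei, centre) {
  sqrt((nuclei$x_um - centre[1])^2 + (nuclei$y_um - centre[2])^2)
}

#' Marker-positive fraction of a colony
#'
#' Fraction of nuclei positive for a marker (e.g. OCT4 or EdU), computed from
#' nuclei counts: positives over total. With `by_region = TRUE` the fraction
#' is also reported separately for the centre and perimeter regions defined
#' by `rule`.
#'
#' @param nuclei A `nucleus_table` with a logical column named `marker`.
#' @param marker Name of the marker column.
#' @param rule A [region_rule()] used when `by_region = TRUE`.
#' @param by_region Also report per-region fractions?
#' @return A list with `overall`, and when requested `centre`, `perimeter`
#'   and the per-region counts.
#' @export
marker_positive_fraction <- function(nuclei, marker, rule = region_rule(),
                                     by_region = FALSE) {
  stopifnot(is.data.frame(nuclei))
  if (!marker %in% names(nuclei))
    stop(sprintf("marker column '%s' not found", marker), call. = FALSE)
  if (nrow(nuclei) == 0L)
    stop("undefined fraction: nuclei table is empty", call. = FALSE)
  pos <- as.logical(nuclei[[marker]])
  out <- list(marker = marker, overall = mean(pos),
              n = nrow(nuclei), n_positive = sum(pos))
  if (by_region) {
    r <- nucleus_radius(nuclei, rule$centre)
    per <- r > rule$radial_threshold
    out$centre <- if (any(!per)) mean(pos[!per]) else NA_real_
    out$perimeter <- if (any(per)) mean(pos[per]) else NA_real_
    out$n_centre <- sum(!per); out$n_perimeter <- sum(per)
  }
  out
}

#' Nucleus shape index
#'
#' The shape index of a nucleus is its longest axis divided by its shortest
#' axis: 1 for a circular nucleus, larger for elongated nuclei (a signature
#' of mechanical stress at the pattern perimeter). Records with non-positive
#' axes are rejected with a reason rather than propagated.
#'
#' @param nuclei A `nucleus_table` with `major_um` and `minor_um` columns.
#' @param rule Optional [region_rule()]; when supplied, per-region mean and
#'   s.d. are reported.
#' @return A list with `per_nucleus` (data frame `nucleus_id`, `shape_index`,
#'   and `region` when a rule is given), `summary` (per-region mean/sd), and
#'   `rejected` (data frame of rejected records with reasons).
#' @export
nucleus_shape_index <- function(nuclei, rule = NULL) {
  stopifnot(is.data.frame(nuclei))
  bad <- !is.finite(nuclei$major_um) | !is.finite(nuclei$minor_um) |
    nuclei$major_um <= 0 | nuclei$minor_um <= 0
  rejected <- data.frame(
    nucleus_id = nuclei$nucleus_id[bad],
    reason = rep("non-positive or non-finite axis length", sum(bad)),
    stringsAsFactors = FALSE)
  ok <- nuclei[!bad, , drop = FALSE]
  idx <- pmax(ok$major_um, ok$minor_um) / pmin(ok$major_um, ok$minor_um)
  per_nucleus <- data.frame(nucleus_id = ok$nucleus_id, shape_index = idx,
                            stringsAsFactors = FALSE)
  summary <- NULL
  if (!is.null(rule)) {
    r <- nucleus_radius(ok, rule$centre)
    per_nucleus$region <- ifelse(r > rule$radial_threshold,
                                 "perimeter", "centre")
    summary <- do.call(rbind, lapply(split(per_nucleus, per_nucleus$region),
      function(d) data.frame(region = d$region[1], n = nrow(d),
                             mean = mean(d$shape_index),
                             sd = stats::sd(d$shape_index),
                             stringsAsFactors = FALSE)))
    rownames(summary) <- NULL
  }
  list(per_nucleus = per_nucleus, summary = summary, rejected = rejected)
}

#' Spatial cell density ratio (perimeter over centre)
#'
#' Pools annulus counts and areas on each side of the region boundary and
#' divides the perimeter density by the centre density. A ratio above 1
#' indicates condensation of cells at the pattern perimeter. Annuli straddling
#' the boundary are split pro rata by area.
#'
#' @param map A `density_map` from [annulus_density_map()].
#' @param rule A [region_rule()]; its `radial_threshold` splits the annuli.
#' @return A list with `ratio`, the pooled `centre_density` and
#'   `perimeter_density` (cells/um^2), and `infinite` flag (zero centre
#'   density with occupied perimeter).
#' @export
spatial_density_ratio <- function(map, rule = region_rule()) {
  stopifnot(inherits(map, "density_map"))
  thr <- rule$radial_threshold
  R <- max(map$outer_um)
  if (thr <= 0 || thr >= R)
    stop("radial threshold must fall inside the pattern", call. = FALSE)
  # pro-rata split of each annulus by area on each side of the threshold
  inner_c <- pmin(map$inner_um, thr); outer_c <- pmin(map$outer_um, thr)
  area_c <- pi * pmax(outer_c^2 - inner_c^2, 0)
  frac_c <- ifelse(map$area_um2 > 0, area_c / map$area_um2, 0)
  cnt_c <- sum(map$count * frac_c)
  cnt_p <- sum(map$count * (1 - frac_c))
  area_p <- sum(map$area_um2) - sum(area_c)
  dens_c <- cnt_c / sum(area_c)
  dens_p <- cnt_p / area_p
  if (dens_c == 0) {
    return(list(ratio = if (dens_p > 0) Inf else 0,
                centre_density = dens_c, perimeter_density = dens_p,
                infinite = dens_p > 0))
  }
  list(ratio = dens_p / dens_c, centre_density = dens_c,
       perimeter_density = dens_p, infinite = FALSE)
}

#' Fit a two-term power function to an intensity-vs-thickness profile
#'
#' Regresses normalized intensity on tissue thickness with the two-term power
#' model \eqn{y = a x^b + c} by nonlinear least squares, reporting the
#' coefficients with 95% (Wald) confidence intervals and the fit statistics
#' SSE, RMSE and R^2. Marker intensities are first divided by the normalizer
#' channel (typically DAPI), making the fit invariant to common scaling of
#' both channels.
#'
#' @param thickness Positive thickness values (um).
#' @param intensity Marker intensity at each thickness.
#' @param normalizer Optional normalizing intensity (e.g. DAPI); must be
#'   nonzero. `NULL` fits `intensity` directly.
#' @return A `profile_fit` list: `a`, `b`, `c`, `ci` (2x3 matrix of 95%
#'   bounds), `sse`, `rmse`, `r_squared`, `converged`, `identifiable`.
#'   A constant response is flagged `identifiable = FALSE` with `a = 0`,
#'   `b = NA`, `c` at the mean and `r_squared = 0`.
#' @examples
#' x <- 1:20
#' fit_power_profile(x, 2 * x^0.5 + 1)
#' @export
fit_power_profile <- function(thickness, intensity, normalizer = NULL) {
  x <- as.numeric(thickness)
  y <- as.numeric(intensity)
  if (length(x) != length(y))
    stop("thickness and intensity must have equal length", call. = FALSE)
  if (!is.null(normalizer)) {
    normalizer <- as.numeric(normalizer)
    if (length(normalizer) != length(y))
      stop("normalizer must match intensity length", call. = FALSE)
    if (any(!is.finite(normalizer)) || any(normalizer == 0))
      stop("normalizer must be finite and nonzero", call. = FALSE)
    y <- y / normalizer
  }
  if (length(x) < 4L)
    stop("insufficient data: power fit needs at least 4 points", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("thickness values must be positive and finite", call. = FALSE)

  make_fit <- function(a, b, c0, ci, fitted, converged, identifiable) {
    res <- y - fitted
    sse <- sum(res^2)
    sst <- sum((y - mean(y))^2)
    structure(list(a = a, b = b, c = c0, ci = ci, sse = sse,
                   rmse = sqrt(sse / max(length(y) - 3, 1)),
                   r_squared = if (sst > 0) 1 - sse / sst else 0,
                   converged = converged, identifiable = identifiable),
              class = "profile_fit")
  }

  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    ci <- matrix(NA_real_, 2, 3, dimnames = list(c("2.5%", "97.5%"),
                                                 c("a", "b", "c")))
    return(make_fit(0, NA_real_, mean(y), ci, rep(mean(y), length(y)),
                    converged = TRUE, identifiable = FALSE))
  }

  # starting values from a log-log fit of (y - c0) on x
  c0 <- min(y) - 0.05 * diff(range(y))
  pos <- y - c0 > 0
  ll <- stats::lm.fit(cbind(1, log(x[pos])), log(y[pos] - c0))
  a0 <- exp(unname(ll$coefficients[1])); b0 <- unname(ll$coefficients[2])
  if (!is.finite(a0) || a0 <= 0) a0 <- diff(range(y)) / diff(range(x))
  if (!is.finite(b0)) b0 <- 1

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b + cc,
                      start = list(a = a0, b = b0, cc = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ci <- matrix(NA_real_, 2, 3, dimnames = list(c("2.5%", "97.5%"),
                                                 c("a", "b", "c")))
    return(make_fit(NA_real_, NA_real_, NA_real_, ci, rep(mean(y), length(y)),
                    converged = FALSE, identifiable = FALSE))
  }
  cf <- stats::coef(fit)
  # Wald 95% CIs; a rank-deficient Jacobian leaves them NA and flags the fit
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  tq <- stats::qt(0.975, max(length(y) - 3, 1))
  ci <- rbind(cf - tq * se, cf + tq * se)
  dimnames(ci) <- list(c("2.5%", "97.5%"), c("a", "b", "c"))
  identifiable <- all(is.finite(se)) &&
    !(is.finite(ci["2.5%", "b"]) && ci["2.5%", "b"] < 0 &&
        ci["97.5%", "b"] > 0)
  make_fit(cf[["a"]], cf[["b"]], cf[["cc"]], ci, stats::fitted(fit),
           converged = isTRUE(fit$convInfo$isConv), identifiable = identifiable)
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "<profile_fit y = a*x^b + c: a = %.4g, b = %.4g, c = %.4g\n  SSE = %.4g, RMSE = %.4g, R^2 = %.4g, identifiable = %s>\n",
    x$a, x$b, x$c, x$sse, x$rmse, x$r_squared, x$identifiable))
  invisible(x)
}
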