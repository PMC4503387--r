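default_config <- function() {
  list(
    pattern = list(diameter = 400, centre = c(0, 0), annulus_width = 15),
    tracks = list(dt_min = 30, n_frames = 49, radial_threshold = 100,
                  mu_threshold = 5, gof_threshold = 0.3,
                  max_lag_fraction = 1 / 3),
    contraction = list(frame_rate = 20, n_frames = 500, pixel_size = 1,
                       block_size = 16, search_radius = 8, step = 8,
                       min_prominence = 0.3, min_separation = 0.2),
    seed = 1,
    output_dir = "."
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with per-stage sections (`pattern`, `tracks`,
#' `contraction`, plus `seed` and `output_dir`), fills in documented defaults
#' for anything omitted, and validates every numeric field against the module
#' preconditions, reporting *all* violations at once. An empty or missing
#' section simply takes the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (sec in intersect(names(user), names(cfg))) {
      if (is.list(cfg[[sec]]) && is.list(user[[sec]]))
        cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
      else cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$pattern; tr <- cfg$tracks; ct <- cfg$contraction
  check_config(list(
    `pattern.diameter` = is_pos(p$diameter),
    `pattern.centre` = is.numeric(p$centre) && length(p$centre) == 2L,
    `pattern.annulus_width` = is_pos(p$annulus_width) &&
      p$annulus_width <= p$diameter / 2,
    `tracks.dt_min` = is_pos(tr$dt_min),
    `tracks.n_frames` = is_count(tr$n_frames, min = 2),
    `tracks.radial_threshold` = is_pos(tr$radial_threshold) &&
      tr$radial_threshold < p$diameter / 2,
    `tracks.mu_threshold` = is_nonneg(tr$mu_threshold),
    `tracks.gof_threshold` = is_pos(tr$gof_threshold),
    `tracks.max_lag_fraction` = is_pos(tr$max_lag_fraction) &&
      tr$max_lag_fraction <= 1,
    `contraction.frame_rate` = is_pos(ct$frame_rate),
    `contraction.n_frames` = is_count(ct$n_frames, min = 2),
    `contraction.pixel_size` = is_pos(ct$pixel_size),
    `contraction.block_size` = is_count(ct$block_size, min = 4),
    `contraction.search_radius` = is_count(ct$search_radius, min = 1),
    `contraction.step` = is_count(ct$step, min = 1),
    `contraction.min_prominence` = is_prob(ct$min_prominence),
    `contraction.min_separation` = is_nonneg(ct$min_separation),
    seed = is.numeric(cfg$seed) && length(cfg$seed) == 1L
  ), "pipeline")
  invisible(cfg)
}

#' Write a configuration back to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages over the supplied inputs — `tracks` (a tracks
#' CSV path or list of [cell_track()]), `nuclei` (a nuclei CSV path or
#' `nucleus_table`), `stack` (a TIFF path or [image_stack()]) — and returns a
#' single report aggregating all module outputs with provenance (config hash,
#' seed, package version). A stage that fails is recorded in the report with
#' its diagnostic message; the remaining stages still run.
#'
#' @param config A `run_config` from [load_config()].
#' @param inputs Named list with any of `tracks`, `nuclei`, `stack`.
#' @param stages Character subset of `c("tracks", "spatial", "contraction")`.
#' @param report_path Optional path; when given, the report is written there
#'   as JSON (deterministic for a fixed config and inputs).
#' @return A `pipeline_report` list with one element per executed stage plus
#'   `provenance` and `failed_stages`.
#' @export
run_pipeline <- function(config = load_config(), inputs = list(),
                         stages = c("tracks", "spatial", "contraction"),
                         report_path = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(provenance = list(
    package = "mpquant",
    version = as.character(utils::packageVersion("mpquant")),
    config_hash = config_hash(config),
    seed = config$seed
  ))
  failed <- character(0)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      failed <<- c(failed, name)
      list(error = conditionMessage(e))
    })
  }

  rr <- region_rule(centre = config$pattern$centre,
                    radial_threshold = config$tracks$radial_threshold)

  if ("tracks" %in% stages && !is.null(inputs$tracks)) {
    report$tracks <- run_stage("tracks", function() {
      trs <- inputs$tracks
      if (is.character(trs)) trs <- read_tracks_csv(trs)
      trs <- lapply(trs, assign_region, rule = rr)
      fits <- lapply(trs, function(tr)
        classify_migration(
          fit_prw(compute_msd(tr, config$tracks$max_lag_fraction)),
          mu_threshold = config$tracks$mu_threshold,
          gof_threshold = config$tracks$gof_threshold))
      summ <- summarize_cohort(trs, fits)
      list(per_region = summ$per_region,
           p_values = as.list(summ$p_values),
           missing_regions = summ$missing_regions,
           n_cells = nrow(summ$cells))
    })
  }

  if ("spatial" %in% stages && !is.null(inputs$nuclei)) {
    report$spatial <- run_stage("spatial", function() {
      nuc <- inputs$nuclei
      if (is.character(nuc)) nuc <- read_nuclei_csv(nuc)
      geom <- pattern_geometry(centre = config$pattern$centre,
                               diameter = config$pattern$diameter,
                               annulus_width = config$pattern$annulus_width)
      dmap <- annulus_density_map(nuc, geom)
      ratio <- spatial_density_ratio(dmap, rr)
      markers <- setdiff(names(nuc)[vapply(nuc, is.logical, logical(1))],
                         character(0))
      mk <- lapply(markers, function(m)
        marker_positive_fraction(nuc, m, rr, by_region = TRUE))
      names(mk) <- markers
      shape <- nucleus_shape_index(nuc, rr)
      list(density_map = as.data.frame(dmap),
           out_of_pattern = attr(dmap, "out_of_pattern"),
           density_ratio = ratio,
           marker_fractions = mk,
           shape_summary = shape$summary)
    })
  }

  if ("contraction" %in% stages && !is.null(inputs$stack)) {
    report$contraction <- run_stage("contraction", function() {
      st <- inputs$stack
      if (is.character(st))
        st <- read_stack_tiff(st, frame_rate = config$contraction$frame_rate,
                              pixel_size = config$contraction$pixel_size)
      fld <- block_match_motion(st,
                                block_size = config$contraction$block_size,
                                search_radius = config$contraction$search_radius,
                                step = config$contraction$step)
      wf <- motion_waveform(fld)
      beats <- detect_beats(wf,
                            min_prominence = config$contraction$min_prominence,
                            min_separation = config$contraction$min_separation)
      hm <- contraction_heatmap(fld)
      list(beat_frequency = beats$beat_frequency,
           max_contraction_velocity = beats$max_contraction_velocity,
           n_peaks = nrow(beats$peaks),
           quiescent = beats$quiescent,
           heatmap_max = max(hm$matrix))
    })
  }

  report$failed_stages <- failed
  class(report) <- "pipeline_report"
  if (!is.null(report_path))
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  report
}
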