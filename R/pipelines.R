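#' Run configuration for the analysis pipelines
#'
#' Collects every tunable parameter with its documented default: spatial
#' and temporal calibration, the PIV pass/validation settings, kinetics
#' thresholds, morphometry preprocessing, and scoring parameters. Configs
#' round-trip losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame (contractility movies).
#' @param piv list of [piv_config()] arguments.
#' @param kinetics list: `prominence_fraction`, `velocity_window`,
#'   `baseline_window` (NULL for traces without baseline), `pad_factor`,
#'   `noise_floor_factor`.
#' @param morphometry list: `background_radius`, `min_area_px`,
#'   `min_overlap`, `nucleus_min_area_px`.
#' @param scoring list: `histogram_bins`, `btx_factor`,
#'   `perinuclear_half_length_um`, `spot_min_area_px`, `spot_max_area_px`.
#' @param seed integer seed for any stochastic step.
#' @param output_dir where pipeline CSVs are written.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.5, frame_interval = 0.02,
                       piv = list(), kinetics = list(), morphometry = list(),
                       scoring = list(), seed = 1L, output_dir = ".") {
  cfg <- list(
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    piv = utils::modifyList(list(pass_windows = c(64L, 32L),
                                 overlap_fraction = 0.5,
                                 validation_threshold = 2.0,
                                 validation_eps = 0.1), piv),
    kinetics = utils::modifyList(list(prominence_fraction = 0.1,
                                      velocity_window = 2.0,
                                      baseline_window = NA_real_,
                                      pad_factor = 4L,
                                      noise_floor_factor = 5), kinetics),
    morphometry = utils::modifyList(list(background_radius = 50,
                                         min_area_px = 20,
                                         min_overlap = 0.5,
                                         nucleus_min_area_px = 20), morphometry),
    scoring = utils::modifyList(list(histogram_bins = 64L,
                                     btx_factor = 2.0,
                                     perinuclear_half_length_um = 50,
                                     spot_min_area_px = 1L,
                                     spot_max_area_px = 400L), scoring),
    seed = as.integer(seed),
    output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[c("pixel_size", "frame_interval", "piv", "kinetics",
                            "morphometry", "scoring", "seed", "output_dir")])
}

.cfg_meta <- function(cfg) {
  c(config_hash = .config_hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("twitchkit")))
}

.cfg_piv <- function(cfg)
  piv_config(pass_windows = cfg$piv$pass_windows,
             overlap_fraction = cfg$piv$overlap_fraction,
             validation_threshold = cfg$piv$validation_threshold,
             validation_eps = cfg$piv$validation_eps)

#' Contractility pipeline: movie to trace and kinetics summary
#'
#' End-to-end PIV analysis of one movie: per-pair displacement fields,
#' Lagrangian tracking of a reference point (the nucleus position), twitch
#' dissection and the kinetics summary. Deterministic for a fixed input
#' and config. Writes `trace.csv`, `kinetics_summary.csv` and a
#' `vector_fields.csv` archive when `output_dir` is set.
#'
#' @param movie a [movie_stack()] or path to a multi-page TIFF.
#' @param config a [run_config()].
#' @param point `c(x, y)` reference point in px; defaults to the grid
#'   point with the largest mean displacement magnitude (the most active
#'   part of the cell).
#' @param output_dir directory for CSV output, `NULL` to skip writing.
#' @return list: `trace`, `summary`, `fields`, `point`.
#' @export
run_contractility <- function(movie, config = run_config(), point = NULL,
                              output_dir = config$output_dir) {
  if (is.character(movie))
    movie <- read_movie(movie, config$pixel_size, config$frame_interval)
  stopifnot(inherits(movie, "movie_stack"))
  fields <- movie_to_fields(movie, .cfg_piv(config))
  if (is.null(point)) {
    mag <- Reduce(`+`, lapply(fields, `[[`, "magnitude")) / length(fields)
    pk <- arrayInd(which.max(mag), dim(mag))
    point <- c(fields[[1]]$x[pk[2]], fields[[1]]$y[pk[1]])
  }
  trace <- track_point(fields, point, movie$pixel_size, movie$frame_interval)
  bw <- config$kinetics$baseline_window
  summary <- summarize_kinetics(
    trace, window = config$kinetics$velocity_window,
    prominence_fraction = config$kinetics$prominence_fraction,
    baseline_window = if (is.null(bw) || is.na(bw)) NULL else bw)
  events <- dissect_twitches(
    trace, prominence_fraction = config$kinetics$prominence_fraction)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- .cfg_meta(config)
    write_trace_csv(trace, file.path(output_dir, "trace.csv"), meta)
    .write_csv_meta(summary, file.path(output_dir, "kinetics_summary.csv"), meta)
    .write_csv_meta(events, file.path(output_dir, "twitch_events.csv"), meta)
    .write_csv_meta(.fields_to_df(fields),
                    file.path(output_dir, "vector_fields.csv"), meta)
  }
  list(trace = trace, summary = summary, events = events, fields = fields,
       point = point)
}

.fields_to_df <- function(fields) {
  do.call(rbind, lapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    data.frame(pair = k,
               x = rep(f$x, each = length(f$y)), y = rep(f$y, length(f$x)),
               u = as.vector(f$u), v = as.vector(f$v),
               magnitude = as.vector(f$magnitude),
               valid = as.vector(f$valid), replaced = as.vector(f$replaced))
  }))
}

#' Morphology pipeline: channels to maturation metrics
#'
#' Preprocesses the actinin and DAPI channels, computes width and
#' myonuclei metrics, per-tube spacing along the mask centerline, BTX
#' scoring (skipped with a warning when no BTX channel is supplied) and
#' perinuclear FISH spot counts (skipped without a FISH channel). Channel
#' inputs may be matrices or TIFF paths.
#'
#' @param channels named list with `actinin` and `dapi` (required), `btx`
#'   and `fish` (optional): matrices or file paths.
#' @param config a [run_config()].
#' @param output_dir directory for CSV output, `NULL` to skip writing.
#' @return list: `morphometry` (one-row data frame), `nuclei`, `spacing`,
#'   `achr` (or NULL), `spots` (or NULL).
#' @export
run_morphology <- function(channels, config = run_config(),
                           output_dir = config$output_dir) {
  stopifnot(all(c("actinin", "dapi") %in% names(channels)))
  paths <- vapply(channels, is.character, logical(1))
  if (any(paths)) channels[paths] <- read_channels(unlist(channels[paths]))
  d0 <- dim(channels$actinin)
  for (nm in names(channels))
    if (!all(dim(channels[[nm]]) == d0))
      stop(sprintf("channel '%s' shape differs from 'actinin'", nm),
           call. = FALSE)
  mp <- config$morphometry
  px <- config$pixel_size
  act_mask <- preprocess_channel(channels$actinin, mp$background_radius,
                                 mp$min_area_px)
  dapi_mask <- preprocess_channel(channels$dapi, mp$background_radius,
                                  mp$nucleus_min_area_px)
  wm <- if (any(act_mask)) width_metrics(act_mask, px) else
    list(proportional_area = 0, skeleton_length_um = 0,
         average_width_um = NA_real_)
  nuc <- assign_myonuclei(dapi_mask, act_mask, px, mp$min_overlap,
                          mp$nucleus_min_area_px)
  myo <- nuc$nuclei[nuc$nuclei$is_myonucleus, , drop = FALSE]
  spacing <- NULL
  centerline <- NULL
  if (nrow(myo) >= 2L && any(act_mask)) {
    centerline <- mask_centerline(act_mask, px)
    sp <- nuclei_spacing((cbind(myo$cx, myo$cy) - 0.5) * px, centerline)
    spacing <- data.frame(mean_distance_um = sp$mean_distance_um, cov = sp$cov)
  }
  morpho <- data.frame(
    proportional_area = wm$proportional_area,
    skeleton_length_um = wm$skeleton_length_um,
    average_width_um = wm$average_width_um,
    myonuclei_count = nrow(myo),
    myonuclei_density_per_mm2 = nuc$density_per_mm2,
    mean_spacing_um = if (is.null(spacing)) NA_real_ else spacing$mean_distance_um,
    spacing_cov = if (is.null(spacing)) NA_real_ else spacing$cov)
  sc <- config$scoring
  achr <- NULL
  if (!is.null(channels$btx) && nrow(nuc$nuclei) > 0) {
    lab <- label_components(dapi_mask)
    # restrict intensity records to myonuclei
    keep <- nuc$nuclei$label[nuc$nuclei$is_myonucleus]
    lab[!(lab %in% keep)] <- 0L
    rec <- nucleus_mean_intensity(channels$btx, lab)
    achr <- tryCatch({
      bg <- btx_background(rec$mean_btx, sc$histogram_bins)
      cls <- classify_high_btx(rec, bg, sc$btx_factor)
      list(records = cls$records, background = bg, proportion = cls$proportion)
    }, error = function(e) { warning(conditionMessage(e)); NULL })
  } else if (is.null(channels$btx)) {
    warning("no BTX channel supplied: AChR scoring skipped")
  }
  spots <- NULL
  if (!is.null(channels$fish) && nrow(myo) >= 1L && !is.null(centerline)) {
    fish_mask <- preprocess_channel(channels$fish, mp$background_radius,
                                    sc$spot_min_area_px)
    spots <- do.call(rbind, lapply(seq_len(nrow(myo)), function(i) {
      ctr <- (c(myo$cx[i], myo$cy[i]) - 0.5) * px
      reg <- tryCatch(
        perinuclear_region(ctr, centerline, act_mask, px,
                           sc$perinuclear_half_length_um),
        error = function(e) NULL)
      if (is.null(reg)) return(NULL)
      cs <- count_spots(fish_mask, reg, sc$spot_min_area_px,
                        sc$spot_max_area_px,
                        normalizer_um2 = sum(reg) * px^2)
      data.frame(nucleus_label = myo$label[i], spot_count = cs$spot_count,
                 region_area_um2 = sum(reg) * px^2,
                 density_per_um2 = cs$density_per_um2)
    }))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- .cfg_meta(config)
    .write_csv_meta(morpho, file.path(output_dir, "morphometry.csv"), meta)
    .write_csv_meta(nuc$nuclei, file.path(output_dir, "nuclei.csv"), meta)
    if (!is.null(achr))
      .write_csv_meta(achr$records, file.path(output_dir, "achr.csv"), meta)
    if (!is.null(spots))
      .write_csv_meta(spots, file.path(output_dir, "spots.csv"), meta)
  }
  list(morphometry = morpho, nuclei = nuc$nuclei, spacing = spacing,
       achr = achr, spots = spots)
}
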