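# Config-driven end-to-end runs: detect -> track -> features -> metrics,
# batch processing, and a per-frame detection preview for parameter tuning.

.merge_params <- function(constructor, overrides) {
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  do.call(constructor, overrides)
}

#' Load (or normalise) a run configuration
#'
#' A run configuration is a JSON document (or equivalent nested list) with
#' sections `calibration` (pixel size, frame interval, channel file paths),
#' `detection` (overrides for [detection_params()]), `tracking` (overrides
#' for [link_params()]), `features` (channels to extract, `half_size`,
#' `min_area_um2`, `arrest_threshold_um_min`, `ratio_high`/`ratio_low`),
#' plus `output_dir`, optional `experiment_id`, `edits` (CSV path),
#' `overlay_channel` and `seed`.
#'
#' @param config Path to a JSON file or a named list.
#' @return Normalised config list with parameter objects filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$calibration)) stop("config lacks a calibration section")
  cal <- config$calibration
  config$calibration <- calibration(cal$pixel_size_um, cal$frame_interval_s,
                                    as.list(cal$channels))
  config$detection <- .merge_params(detection_params, as.list(config$detection))
  config$tracking <- .merge_params(link_params, as.list(config$tracking))
  f <- as.list(config$features)
  config$features <- list(
    channels = f$channels,  # NULL = all available
    half_size = f$half_size, max_center_distance = f$max_center_distance,
    min_area_um2 = if (is.null(f$min_area_um2)) 3 else f$min_area_um2,
    arrest_threshold_um_min =
      if (is.null(f$arrest_threshold_um_min)) 0.5 else f$arrest_threshold_um_min,
    ratio_high = if (is.null(f$ratio_high)) 2 else f$ratio_high,
    ratio_low = if (is.null(f$ratio_low)) 0.5 else f$ratio_low)
  if (is.null(config$output_dir)) stop("config lacks output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$experiment_id)) config$experiment_id <- "run1"
  config
}

#' Run the full analysis pipeline
#'
#' Detection, two-tier tracking, optional manual edits, per-position feature
#' extraction, cell-type assignment and motility summaries; everything is
#' written to `output_dir` (detections, long-format tracks+features table,
#' per-step metrics, per-track summary, optional outline overlay TIFF) along
#' with a JSON run log recording every effective parameter and per-stage
#' timings. Reruns with the same config and inputs are bit-identical.
#'
#' @param config Path to a JSON config or a config list
#'   (see [load_run_config()]).
#' @param channels Optional named list of in-memory [image_series()]; when
#'   `NULL` the channels are read from the calibration's file paths.
#' @return Invisible list with `detections`, `tracks`, `observations`,
#'   `labels`, `summary`, `steps`, `log`.
#' @export
run_pipeline <- function(config, channels = NULL) {
  config <- load_run_config(config)
  set.seed(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(experiment_id = config$experiment_id, seed = config$seed,
              parameters = list(
                calibration = config$calibration[c("pixel_size_um", "frame_interval_s")],
                detection = unclass(config$detection),
                tracking = unclass(config$tracking),
                features = config$features),
              stages = list())
  tic <- function() Sys.time()
  stage <- function(name, t0, ...) {
    log$stages[[name]] <<- c(list(seconds = as.numeric(Sys.time() - t0,
                                                       units = "secs")), list(...))
  }

  t0 <- tic()
  if (is.null(channels)) channels <- read_channels(config$calibration)
  if (is.null(channels$transmitted))
    stop("stage image_io: required channel missing: transmitted")
  stage("image_io", t0, n_frames = length(channels$transmitted$frames),
        channels = names(channels))

  t0 <- tic()
  detections <- detect_cells(channels$transmitted, config$detection)
  stage("detection", t0, n_detections = nrow(detections),
        detections_per_frame = round(nrow(detections) /
                                       length(channels$transmitted$frames), 2))
  write.csv(detections, file.path(out_dir, "detections.csv"), row.names = FALSE)

  t0 <- tic()
  segments <- link_nearest_neighbor(detections, config$tracking)
  tracks <- join_segments(segments, config$tracking)
  n_joins <- length(unique(segments$seg_id)) - length(unique(tracks$track_id))
  tracks <- filter_short_tracks(tracks, config$tracking)
  stage("tracking", t0, n_segments = length(unique(segments$seg_id)),
        joins_accepted = n_joins, n_tracks = length(unique(tracks$track_id)))

  if (!is.null(config$edits)) {
    tracks <- edit_tracks(tracks, config$edits)
    log$stages$tracking$edits_applied <- TRUE
  }

  t0 <- tic()
  feat_channels <- config$features$channels
  if (is.null(feat_channels)) feat_channels <- names(channels)
  fx <- extract_features(channels, tracks, config$calibration,
                         which_channels = feat_channels,
                         half_size = config$features$half_size,
                         max_center_distance = config$features$max_center_distance,
                         min_area_um2 = config$features$min_area_um2,
                         detection_params = config$detection)
  observations <- fx$observations
  labels <- assign_cell_types(observations, config$features$ratio_high,
                              config$features$ratio_low)
  stage("features", t0, n_observations = nrow(observations),
        channels = feat_channels)

  t0 <- tic()
  steps <- step_metrics(tracks, config$calibration)
  summary <- summarize_tracks(tracks, config$calibration, observations, labels,
                              config$features$arrest_threshold_um_min)
  summary$experiment_id <- config$experiment_id
  stage("metrics", t0, n_tracks = nrow(summary))

  write_tracks_table(tracks, observations, config$calibration,
                     file.path(out_dir, "tracks.csv"))
  write.csv(steps, file.path(out_dir, "step_metrics.csv"), row.names = FALSE)
  write.csv(summary, file.path(out_dir, "track_summary.csv"), row.names = FALSE)
  if (!is.null(config$overlay_channel) &&
      config$overlay_channel %in% names(channels))
    write_overlay_series(channels[[config$overlay_channel]], fx$outlines,
                         file.path(out_dir, "overlay.tif"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(detections = detections, tracks = tracks,
                 observations = observations, labels = labels,
                 summary = summary, steps = steps, log = log))
}

#' Run several experiments and combine their track summaries
#'
#' Each config is run independently; a failure in one run is recorded and
#' does not abort the others. The per-track summary tables (which carry
#' `experiment_id` and `cell_type`) are concatenated and written to
#' `combined_summary.csv` under `combined_dir`.
#'
#' @param configs List of configs (paths or lists).
#' @param combined_dir Directory for the combined outputs (default: the
#'   first config's output_dir).
#' @return Invisible list: `runs` (per-run results or error conditions),
#'   `combined` (row-bound summary table), `failures` (character).
#' @export
run_batch <- function(configs, combined_dir = NULL) {
  runs <- vector("list", length(configs))
  failures <- character(0)
  for (i in seq_along(configs)) {
    runs[[i]] <- tryCatch(run_pipeline(configs[[i]]),
                          error = function(e) e)
    if (inherits(runs[[i]], "error"))
      failures <- c(failures, sprintf("config %d: %s", i,
                                      conditionMessage(runs[[i]])))
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  combined <- do.call(rbind, lapply(runs[ok], `[[`, "summary"))
  if (is.null(combined_dir)) {
    c1 <- load_run_config(configs[[1]])
    combined_dir <- c1$output_dir
  }
  dir.create(combined_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(combined))
    write.csv(combined, file.path(combined_dir, "combined_summary.csv"),
              row.names = FALSE)
  if (length(failures))
    writeLines(failures, file.path(combined_dir, "batch_failures.log"))
  invisible(list(runs = runs, combined = combined, failures = failures))
}

#' Preview the detection stages on one frame
#'
#' Writes the Canny edge map, the Hough accumulator (normalised) and a
#' centroid overlay for a single frame, the images one inspects when tuning
#' detection parameters.
#'
#' @param config Config path/list (see [load_run_config()]).
#' @param frame_index 0-based frame index.
#' @param channels Optional in-memory channels (as in [run_pipeline()]).
#' @return Invisible data.frame of the frame's detections.
#' @export
preview_detection <- function(config, frame_index, channels = NULL) {
  config <- load_run_config(config)
  if (is.null(channels)) channels <- read_channels(config$calibration)
  series <- channels$transmitted
  if (frame_index < 0 || frame_index >= length(series$frames))
    stop("frame_index ", frame_index, " out of range [0, ",
         length(series$frames) - 1, "]")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$detection
  fr <- .rescale_frame(series$frames[[frame_index + 1L]], params$scale_factor)
  edges <- compute_edge_map(fr, params)
  h <- circular_hough(edges, params = params)
  det <- select_centroids(h, params, frame = frame_index)
  acc <- h$accumulator
  if (max(acc) > 0) acc <- acc / max(acc)
  write_image_series(list(edges * 1), file.path(config$output_dir, "preview_edges.tif"))
  write_image_series(list(acc), file.path(config$output_dir, "preview_accumulator.tif"))
  overlay <- fr
  d <- dim(overlay)
  for (i in seq_len(nrow(det))) {
    phi <- seq(0, 2 * pi, length.out = 64)
    xs <- pmin(pmax(round(det$x[i] + det$radius[i] * cos(phi)), 0), d[2] - 1)
    ys <- pmin(pmax(round(det$y[i] + det$radius[i] * sin(phi)), 0), d[1] - 1)
    overlay[cbind(ys + 1L, xs + 1L)] <- 1
  }
  write_image_series(list(overlay), file.path(config$output_dir, "preview_overlay.tif"))
  if (nrow(det) && params$scale_factor != 1) {
    det$x <- det$x / params$scale_factor
    det$y <- det$y / params$scale_factor
    det$radius <- det$radius / params$scale_factor
  }
  invisible(det)
}
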