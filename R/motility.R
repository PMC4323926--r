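# Per-step and per-track motility characteristics. All speeds use the actual
# elapsed time between points, so frame gaps left by segment joining do not
# bias the estimates.

#' Instantaneous speeds along a track
#'
#' Euclidean displacement between consecutive track points divided by the
#' actual elapsed time (`delta frame * frame_interval_s / 60`), in um/min.
#'
#' @param track data.frame of one track's points (`frame`, `x`, `y` in px),
#'   sorted by frame.
#' @param calibration A [calibration()].
#' @return data.frame with `frame` (of the step's end point) and
#'   `speed_um_min`; zero rows for single-point tracks.
#' @export
instantaneous_speeds <- function(track, calibration) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) return(data.frame(frame = integer(), speed_um_min = numeric()))
  disp_um <- sqrt(diff(track$x)^2 + diff(track$y)^2) * calibration$pixel_size_um
  dt_min <- diff(track$frame) * calibration$frame_interval_s / 60
  data.frame(frame = track$frame[-1], speed_um_min = disp_um / dt_min)
}

#' Turn angles along a track
#'
#' Angle between successive displacement vectors, in degrees within
#' `[0, 180]`; NA where either displacement is (numerically) zero.
#'
#' @param track data.frame of one track's points (`frame`, `x`, `y`).
#' @return data.frame with `frame` (of the vertex point) and
#'   `turn_angle_deg`; zero rows for tracks with fewer than 3 points.
#' @export
turn_angles <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 3L) return(data.frame(frame = integer(), turn_angle_deg = numeric()))
  dx <- diff(track$x); dy <- diff(track$y)
  len <- sqrt(dx^2 + dy^2)
  a <- numeric(n - 2L)
  for (i in seq_len(n - 2L)) {
    if (len[i] <= .Machine$double.eps || len[i + 1] <= .Machine$double.eps) {
      a[i] <- NA_real_
    } else {
      cosang <- (dx[i] * dx[i + 1] + dy[i] * dy[i + 1]) / (len[i] * len[i + 1])
      a[i] <- acos(min(max(cosang, -1), 1)) * 180 / pi
    }
  }
  data.frame(frame = track$frame[2:(n - 1L)], turn_angle_deg = a)
}

#' Arrest coefficient
#'
#' Fraction of instantaneous speeds strictly below a threshold (default
#' 0.5 um/min); high values indicate an arrested cell.
#'
#' @param speeds Numeric vector of instantaneous speeds (um/min), or the
#'   data.frame from [instantaneous_speeds()].
#' @param threshold_um_min Speed threshold, um/min.
#' @return Fraction in `[0, 1]`; NA for empty input.
#' @export
arrest_coefficient <- function(speeds, threshold_um_min = 0.5) {
  if (is.data.frame(speeds)) speeds <- speeds$speed_um_min
  if (!length(speeds)) return(NA_real_)
  mean(speeds < threshold_um_min)
}

#' Confinement index
#'
#' Net displacement (first to last point) divided by total path length, in
#' `[0, 1]`: 1 for perfectly straight motion, near 0 for confined or
#' meandering motion.
#'
#' @param track data.frame of one track's points (`frame`, `x`, `y`).
#' @return Ratio in `[0, 1]`; NA when the path length is zero or the track
#'   has fewer than 2 points.
#' @export
confinement_index <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) return(NA_real_)
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  if (path <= 0) return(NA_real_)
  net <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  net / path
}

#' Per-step metrics for all tracks
#'
#' @param tracks data.frame of track points (`track_id`, `frame`, `x`, `y`).
#' @param calibration A [calibration()].
#' @return data.frame `track_id`, `frame`, `speed_um_min`, `turn_angle_deg`
#'   (NA at steps where the angle is undefined).
#' @export
step_metrics <- function(tracks, calibration) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    sp <- instantaneous_speeds(tr, calibration)
    if (!nrow(sp)) return(NULL)
    ta <- turn_angles(tr)
    sp$turn_angle_deg <- ta$turn_angle_deg[match(sp$frame, ta$frame)]
    cbind(data.frame(track_id = tr$track_id[1]), sp)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(track_id = integer(), frame = integer(),
                                      speed_um_min = numeric(),
                                      turn_angle_deg = numeric())
  rownames(out) <- NULL
  out
}

#' Per-track motility summaries
#'
#' Computes, per track: mean speed, median turn angle, arrest coefficient,
#' confinement index, path length, net displacement, frame count; merged
#' with the track-level attachment flag (a track is attached if any of its
#' observations is) and the cell-type label when available.
#'
#' @param tracks data.frame of track points.
#' @param calibration A [calibration()].
#' @param observations Optional per-position feature table (from
#'   [extract_features()]) providing `attached`.
#' @param labels Optional cell-type table (from [assign_cell_types()]).
#' @param arrest_threshold_um_min Threshold for the arrest coefficient.
#' @return data.frame, one row per track.
#' @export
summarize_tracks <- function(tracks, calibration, observations = NULL,
                             labels = NULL, arrest_threshold_um_min = 0.5) {
  if (!is.null(observations) && nrow(observations) &&
      !all(observations$track_id %in% tracks$track_id))
    stop("observations reference track ids absent from tracks")
  if (!is.null(labels) && nrow(labels) &&
      !all(labels$track_id %in% tracks$track_id))
    stop("labels reference track ids absent from tracks")
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    sp <- instantaneous_speeds(tr, calibration)
    ta <- turn_angles(tr)
    px <- calibration$pixel_size_um
    n <- nrow(tr)
    path <- if (n > 1) sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)) * px else 0
    net <- if (n > 1) sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2) * px else 0
    data.frame(track_id = tr$track_id[1],
               n_frames = n,
               mean_speed_um_min = if (nrow(sp)) mean(sp$speed_um_min) else NA_real_,
               median_turn_angle_deg =
                 if (nrow(ta) && any(!is.na(ta$turn_angle_deg)))
                   median(ta$turn_angle_deg, na.rm = TRUE) else NA_real_,
               arrest_coefficient = arrest_coefficient(sp, arrest_threshold_um_min),
               confinement_index = confinement_index(tr),
               path_length_um = path,
               net_displacement_um = net)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$attached <- FALSE
  if (!is.null(observations) && nrow(observations) &&
      "attached" %in% names(observations)) {
    att <- tapply(observations$attached, observations$track_id,
                  function(v) any(v, na.rm = TRUE))
    out$attached <- as.logical(att[as.character(out$track_id)])
    out$attached[is.na(out$attached)] <- FALSE
    area <- tapply(observations$contact_area_um2, observations$track_id,
                   function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out$mean_contact_area_um2 <- as.numeric(area[as.character(out$track_id)])
  }
  if (!is.null(labels) && nrow(labels)) {
    out$cell_type <- labels$label[match(out$track_id, labels$track_id)]
    out$cell_type[is.na(out$cell_type)] <- "unassigned"
  }
  out
}

#' Population medians of motility characteristics, normalised to a control
#'
#' Groups per-track summaries and reports the group median of each motility
#' characteristic divided by the corresponding median in the named control
#' group, the usual heat-map representation for perturbation panels.
#'
#' @param summaries data.frame from [summarize_tracks()].
#' @param group Factor/character vector, one entry per row of `summaries`.
#' @param control Name of the control group.
#' @return data.frame: one row per group, one column per characteristic,
#'   values as ratios to the control median.
#' @export
group_median_table <- function(summaries, group, control) {
  group <- as.character(group)
  stopifnot(length(group) == nrow(summaries), control %in% group)
  chars <- intersect(c("mean_speed_um_min", "median_turn_angle_deg",
                       "arrest_coefficient", "confinement_index",
                       "path_length_um", "net_displacement_um",
                       "mean_contact_area_um2"),
                     names(summaries))
  med <- aggregate(summaries[chars], list(group = group), median, na.rm = TRUE)
  ctrl <- med[med$group == control, chars]
  for (cn in chars) {
    c0 <- as.numeric(ctrl[[cn]])
    # a zero control median leaves ratios undefined except for exact equality
    med[[cn]] <- if (!is.na(c0) && c0 == 0)
      ifelse(med[[cn]] == 0, 1, NA_real_) else med[[cn]] / c0
  }
  med
}
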