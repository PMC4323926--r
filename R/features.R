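# Local, per-track-position feature extraction. A square box is cropped
# around each tracked centroid in each secondary channel and segmented
# locally; local segmentation is what makes reflection series with
# spatiotemporally drifting background tractable at all, since global
# thresholding has no single valid threshold there.

#' Crop a square local box around a centroid
#'
#' @param frame Numeric matrix (one channel, one frame).
#' @param center Numeric `c(x, y)` in 0-based pixels; must lie inside the
#'   image.
#' @param half_size Half edge of the box, px; the box is clipped at image
#'   borders and the offset of its top-left corner recorded so local
#'   coordinates map back globally.
#' @return List of class `local_box`: `raster`, `x0`, `y0` (0-based global
#'   coordinates of the box's top-left pixel), `center` (the requested
#'   global center).
#' @export
crop_local_box <- function(frame, center, half_size) {
  d <- dim(frame)
  cx <- round(center[1]); cy <- round(center[2])
  if (cx < 0 || cy < 0 || cx > d[2] - 1 || cy > d[1] - 1)
    stop("box center (", center[1], ", ", center[2], ") outside image")
  x0 <- max(0L, cx - half_size); x1 <- min(d[2] - 1L, cx + half_size)
  y0 <- max(0L, cy - half_size); y1 <- min(d[1] - 1L, cy + half_size)
  structure(list(raster = frame[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE],
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 center = c(x = center[1], y = center[2])),
            class = "local_box")
}

# boundary pixels of a logical mask (4-connectivity), as 0-based local coords
.mask_outline <- function(mask) {
  if (!any(mask)) return(data.frame(x = integer(), y = integer()))
  pad <- function(dy, dx) .shift(mask, dy, dx)
  interior <- mask & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  # border pixels of the raster count as boundary
  interior[1, ] <- FALSE; interior[nrow(mask), ] <- FALSE
  interior[, 1] <- FALSE; interior[, ncol(mask)] <- FALSE
  idx <- which(mask & !interior)
  nr <- nrow(mask)
  data.frame(x = ((idx - 1L) %/% nr), y = ((idx - 1L) %% nr))
}

# pick from a label matrix the region whose centroid is admissible;
# mode "nearest" = closest centroid, "largest" = largest admissible region
.select_region <- function(labels, box, max_center_distance, mode) {
  ids <- setdiff(unique(as.vector(labels)), 0)
  if (!length(ids)) return(NULL)
  ctr_local <- unname(c(box$center["x"] - box$x0, box$center["y"] - box$y0))
  stats <- lapply(ids, function(id) {
    idx <- which(labels == id)
    nr <- nrow(labels)
    xs <- (idx - 1L) %/% nr; ys <- (idx - 1L) %% nr
    c(id = id, n = length(idx),
      d = sqrt((mean(xs) - ctr_local[1])^2 + (mean(ys) - ctr_local[2])^2))
  })
  st <- do.call(rbind, stats)
  ok <- st[, "d"] <= max_center_distance
  if (!any(ok)) return(NULL)
  st <- st[ok, , drop = FALSE]
  pick <- if (mode == "nearest") which.min(st[, "d"]) else which.max(st[, "n"])
  labels == st[pick, "id"]
}

.empty_seg <- function() list(mask = NULL, outline = data.frame(x = integer(),
                                                                y = integer()))

# wrap a local mask into the return structure with global outline coords
.seg_result <- function(mask, box) {
  ol <- .mask_outline(mask)
  ol$x <- ol$x + box$x0; ol$y <- ol$y + box$y0
  list(mask = mask, outline = ol)
}

#' Segment the cell of interest in a reflection or fluorescence box
#'
#' Otsu's threshold splits the box into foreground and background; for the
#' reflection channel the foreground is the sub-threshold (dark) class, since
#' close cell-glass apposition appears dark in interference reflection, while
#' fluorescence foreground is supra-threshold. The watershed transform of the
#' foreground's distance map separates touching cells, and the region whose
#' centroid lies nearest the box center (within `max_center_distance`) is
#' returned.
#'
#' @param box A [crop_local_box()] result.
#' @param channel `"reflection"`, `"fluor1"` or `"fluor2"`.
#' @param max_center_distance Maximal allowed distance (px) between the
#'   selected region's centroid and the box center.
#' @param min_contrast Minimal difference between the background and
#'   foreground mean intensities for the Otsu split to be considered a real
#'   object rather than a partition of background noise; boxes below it
#'   yield an empty mask.
#' @return List with `mask` (logical matrix, `NULL` when nothing qualifies)
#'   and `outline` (data.frame of 0-based global boundary pixel coordinates).
#' @export
segment_local_intensity <- function(box, channel = c("reflection", "fluor1", "fluor2"),
                                    max_center_distance = 18,
                                    min_contrast = 0.08) {
  channel <- match.arg(channel)
  m <- box$raster
  if (diff(range(m)) <= 0) return(.empty_seg())
  # threshold chosen from a center subwindow: the tracked cell sits at the
  # box center, so a bright/dark neighbour elsewhere in the box cannot
  # dominate the histogram and hide a dim cell of interest
  ctr <- round(c(box$center["x"] - box$x0, box$center["y"] - box$y0))
  hw <- max(ceiling(max_center_distance), 12)
  d <- dim(m)
  cwin <- m[max(1, ctr[2] + 1 - hw):min(d[1], ctr[2] + 1 + hw),
            max(1, ctr[1] + 1 - hw):min(d[2], ctr[1] + 1 + hw), drop = FALSE]
  if (diff(range(cwin)) <= 0) return(.empty_seg())
  th <- EBImage::otsu(EBImage::Image(cwin), range = range(cwin))
  fg <- if (channel == "reflection") m < th else m > th
  if (!any(fg) || all(fg)) return(.empty_seg())
  cfg <- if (channel == "reflection") cwin < th else cwin > th
  if (!any(cfg) || all(cfg) ||
      abs(mean(cwin[cfg]) - mean(cwin[!cfg])) < min_contrast)
    return(.empty_seg())
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  labels <- as.matrix(EBImage::watershed(dm, tolerance = 1))
  mask <- .select_region(labels, box, max_center_distance, mode = "nearest")
  if (is.null(mask)) return(.empty_seg())
  .seg_result(mask, box)
}

#' Segment the cell of interest in a transmitted-light box
#'
#' Canny edges are extracted in the box and voted through the circular Hough
#' transform; watershed regions grown from the accumulator maxima split the
#' edge-enclosed foreground (morphological closing of the edges followed by
#' hole filling) into per-cell territories. Among regions whose centroid lies
#' within `max_center_distance` of the box center the largest is returned.
#'
#' @param box A [crop_local_box()] result (transmitted channel).
#' @param detection_params A [detection_params()] used for the local Canny
#'   and Hough stages.
#' @param max_center_distance Maximal centroid distance from box center, px.
#' @return As [segment_local_intensity()].
#' @export
segment_local_transmitted <- function(box, detection_params = detection_params(),
                                      max_center_distance = 18) {
  m <- box$raster
  if (diff(range(m)) <= 0) return(.empty_seg())
  edges <- compute_edge_map(m, detection_params)
  if (!any(edges)) return(.empty_seg())
  h <- circular_hough(edges, params = detection_params)
  acc <- h$accumulator
  if (max(acc) <= 0) return(.empty_seg())
  # edge-enclosed foreground: close small gaps in the ring, fill the hull
  brush <- EBImage::makeBrush(5, shape = "disc")
  closed <- EBImage::closing(EBImage::Image((edges * 1)), brush)
  filled <- EBImage::fillHull(closed)
  # the outer hysteresis edge of a boundary-relief band sits about
  # canny_sigma outside the true cell boundary, and the band itself is
  # another pixel thick; erode by that much to compensate
  er <- max(1, round(detection_params$canny_sigma + 1))
  if (er >= 1)
    filled <- EBImage::erode(filled, EBImage::makeBrush(2 * er + 1, "disc"))
  fg <- as.matrix(filled) > 0
  if (!any(fg)) return(.empty_seg())
  # seeds: accumulator peaks; territories grown over the foreground by the
  # watershed-style propagation of EBImage
  pk <- acc >= 0.5 * max(acc) & fg
  if (!any(pk)) return(.empty_seg())
  seeds <- EBImage::bwlabel(EBImage::Image(pk * 1))
  labels <- as.matrix(EBImage::propagate(EBImage::Image(m), seeds,
                                         mask = EBImage::Image(fg * 1)))
  mask <- .select_region(labels, box, max_center_distance, mode = "largest")
  if (is.null(mask)) return(.empty_seg())
  .seg_result(mask, box)
}

#' Contact area and attachment from a reflection mask
#'
#' @param mask Logical matrix (or `NULL`) from [segment_local_intensity()].
#' @param calibration A [calibration()].
#' @param min_area_um2 Footprints smaller than this are treated as noise,
#'   not attachment (default 3 um^2).
#' @return List `contact_area_um2` (0 when no admissible footprint) and
#'   `attached` (logical).
#' @export
compute_contact_features <- function(mask, calibration, min_area_um2 = 3) {
  area <- if (is.null(mask)) 0 else sum(mask) * calibration$pixel_size_um^2
  attached <- area >= min_area_um2
  if (!attached) area <- 0
  list(contact_area_um2 = area, attached = attached)
}

#' Mean intensity under a mask
#'
#' @param mask Logical matrix or `NULL`.
#' @param raster Numeric matrix of the same shape.
#' @return Mean of `raster` over `mask`; NA for an empty mask.
#' @export
compute_mean_intensity <- function(mask, raster) {
  if (is.null(mask) || !any(mask)) return(NA_real_)
  mean(raster[mask])
}

#' Aspect ratio of a mask (second-moment ellipse)
#'
#' Ratio of major to minor axis lengths of the ellipse with the same second
#' central moments as the mask; a readout of morphological polarity.
#'
#' @param mask Logical matrix or `NULL`.
#' @return Aspect ratio `>= 1`; NA for masks with fewer than 5 pixels or
#'   degenerate (collinear) masks.
#' @export
compute_aspect_ratio <- function(mask) {
  if (is.null(mask) || sum(mask) < 5L) return(NA_real_)
  idx <- which(mask)
  nr <- nrow(mask)
  xs <- (idx - 1L) %/% nr; ys <- (idx - 1L) %% nr
  cv <- stats::cov(cbind(xs, ys))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9) return(NA_real_)
  sqrt(ev[1] / ev[2])
}

#' Extract per-position features for all tracks from secondary channels
#'
#' For every track point, crops a local box in each requested channel and
#' extracts: contact area and attachment (reflection), mean dye intensity
#' (fluorescence 1/2), and outline plus aspect ratio (transmitted light).
#'
#' @param channels Named list of [image_series()] (`transmitted` required for
#'   aspect ratio; `reflection`, `fluor1`, `fluor2` optional).
#' @param tracks data.frame of track points (`track_id`, `frame`, `x`, `y`).
#' @param calibration A [calibration()].
#' @param which_channels Channels to extract; defaults to all present.
#' @param half_size Box half size, px; default 2.5 x `radius_max` of
#'   `detection_params` so the box holds one cell plus margin.
#' @param max_center_distance Region admissibility radius, px (default
#'   `radius_max`).
#' @param min_area_um2 Attachment threshold on footprint area.
#' @param detection_params Parameters for transmitted-light local
#'   segmentation.
#' @return List: `observations` (data.frame, one row per track point, with
#'   feature columns), `outlines` (per-frame list of outline pixel tables for
#'   [write_overlay_series()], taken from the first extracted channel).
#' @export
extract_features <- function(channels, tracks, calibration,
                             which_channels = names(channels),
                             half_size = NULL, max_center_distance = NULL,
                             min_area_um2 = 3,
                             detection_params = cellmotr::detection_params()) {
  if (is.null(half_size))
    half_size <- ceiling(2.5 * detection_params$radius_max /
                           detection_params$scale_factor)
  if (is.null(max_center_distance))
    max_center_distance <- detection_params$radius_max /
      detection_params$scale_factor
  which_channels <- intersect(which_channels, names(channels))
  n <- nrow(tracks)
  obs <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x = tracks$x, y = tracks$y)
  obs$contact_area_um2 <- NA_real_; obs$attached <- NA
  obs$mean_fluor1 <- NA_real_; obs$mean_fluor2 <- NA_real_
  obs$aspect_ratio <- NA_real_
  n_frames <- if (length(channels)) length(channels[[1]]$frames) else 0L
  outlines <- vector("list", n_frames)
  outline_channel <- which_channels[1]
  for (i in seq_len(n)) {
    fidx <- tracks$frame[i] + 1L
    ctr <- c(tracks$x[i], tracks$y[i])
    main_ol <- NULL
    for (chn in which_channels) {
      fr <- channels[[chn]]$frames[[fidx]]
      box <- crop_local_box(fr, ctr, half_size)
      if (chn == "transmitted") {
        seg <- segment_local_transmitted(box, detection_params, max_center_distance)
        obs$aspect_ratio[i] <- compute_aspect_ratio(seg$mask)
      } else {
        seg <- segment_local_intensity(box, chn, max_center_distance)
        if (chn == "reflection") {
          cf <- compute_contact_features(seg$mask, calibration, min_area_um2)
          obs$contact_area_um2[i] <- cf$contact_area_um2
          obs$attached[i] <- cf$attached
        } else {
          val <- compute_mean_intensity(seg$mask, box$raster)
          if (chn == "fluor1") obs$mean_fluor1[i] <- val else obs$mean_fluor2[i] <- val
        }
      }
      if (chn == outline_channel) main_ol <- seg$outline
    }
    if (!is.null(main_ol) && nrow(main_ol))
      outlines[[fidx]] <- rbind(outlines[[fidx]], main_ol)
  }
  list(observations = obs, outlines = outlines)
}

#' Assign cell types from differential vital-dye labels
#'
#' Per track, the mean over observations of the ratio
#' `(mean_fluor1 + eps) / (mean_fluor2 + eps)` decides the label: at or above
#' `ratio_high` the track is `typeA` (dye 1 loaded), at or below `ratio_low`
#' it is `typeB`, otherwise `unassigned`.
#'
#' @param observations data.frame with `track_id`, `mean_fluor1`,
#'   `mean_fluor2`.
#' @param ratio_high,ratio_low Decision thresholds on the dye ratio.
#' @param eps Regulariser against division by zero.
#' @return data.frame `track_id`, `label`, `ratio`.
#' @export
assign_cell_types <- function(observations, ratio_high = 2, ratio_low = 0.5,
                              eps = 1e-3) {
  stopifnot(ratio_high > ratio_low)
  ratio <- tapply(seq_len(nrow(observations)), observations$track_id, function(ii) {
    f1 <- observations$mean_fluor1[ii]; f2 <- observations$mean_fluor2[ii]
    ok <- !is.na(f1) & !is.na(f2)
    if (!any(ok)) return(NA_real_)
    mean((f1[ok] + eps) / (f2[ok] + eps))
  })
  lab <- ifelse(is.na(ratio), "unassigned",
                ifelse(ratio >= ratio_high, "typeA",
                       ifelse(ratio <= ratio_low, "typeB", "unassigned")))
  data.frame(track_id = as.integer(names(ratio)), label = unname(lab),
             ratio = as.numeric(ratio))
}
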