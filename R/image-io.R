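#' @importFrom stats median quantile rnorm runif rlnorm sd setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

CHANNEL_ROLES <- c("transmitted", "reflection", "fluor1", "fluor2")

#' Spatial and temporal calibration of an imaging experiment
#'
#' Bundles the pixel size, the frame interval and the per-channel file
#' locations of one co-registered multi-channel acquisition. All downstream
#' micron quantities are obtained by multiplying pixel coordinates by
#' `pixel_size_um`; all times by multiplying frame indices by
#' `frame_interval_s`.
#'
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#' @param channels Named character vector or list mapping channel roles
#'   (`"transmitted"`, `"reflection"`, `"fluor1"`, `"fluor2"`) to file paths.
#'   May be empty when images are passed around in memory.
#' @return An object of class `calibration`.
#' @export
calibration <- function(pixel_size_um, frame_interval_s, channels = character()) {
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L, pixel_size_um > 0,
            is.numeric(frame_interval_s), length(frame_interval_s) == 1L, frame_interval_s > 0)
  channels <- as.list(channels)
  if (length(channels)) {
    if (is.null(names(channels)) || !all(names(channels) %in% CHANNEL_ROLES))
      stop("channel names must be among: ", paste(CHANNEL_ROLES, collapse = ", "))
    if (length(channels) > 4L) stop("at most 4 channels are supported")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channels = channels),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4g um/px, %.4g s/frame, channels: %s\n",
              x$pixel_size_um, x$frame_interval_s,
              if (length(x$channels)) paste(names(x$channels), collapse = ", ") else "(none)"))
  invisible(x)
}

#' Construct an image series
#'
#' An `image_series` is one channel of a time-lapse acquisition: an ordered
#' list of equally sized 2D intensity matrices (rows = y, columns = x,
#' intensities in `[0, 1]`) plus its calibration. Frame indices are 0-based
#' everywhere in this package; matrix element `[y + 1, x + 1]` holds the
#' intensity of the 0-based pixel `(x, y)`.
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param channel_role One of `"transmitted"`, `"reflection"`, `"fluor1"`,
#'   `"fluor2"`.
#' @param pixel_size_um,frame_interval_s Calibration (see [calibration()]).
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, channel_role, pixel_size_um, frame_interval_s) {
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of matrices")
  dims <- vapply(frames, function(f) dim(as.matrix(f)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  structure(list(frames = lapply(frames, as.matrix),
                 channel_role = channel_role,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_series [%s]: %d frames of %dx%d px, %.4g um/px, %.4g s/frame\n",
              x$channel_role, length(x$frames), d[1], d[2],
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
length.image_series <- function(x) length(x$frames)

# collapse a readTIFF result (matrix or h x w x s array) to grayscale
.to_gray <- function(a) {
  if (length(dim(a)) == 3L) a <- rowMeans(a, dims = 2L)
  as.matrix(a)
}

#' Read one channel of a time-lapse series from TIFF
#'
#' Accepts either a multi-page TIFF file or a directory of single-frame TIFFs
#' (combined in lexicographic filename order). Multi-sample (e.g. RGB) pixels
#' are collapsed to grayscale by the mean over samples; intensities are
#' returned in `[0, 1]`.
#'
#' @param path Path to a TIFF file or a directory of TIFF files.
#' @param role Channel role for the resulting series.
#' @param calibration A [calibration()] object.
#' @return An [image_series()].
#' @export
read_image_series <- function(path, role, calibration) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no TIFF files found in directory: ", path)
    files <- files[order(basename(files))]
    frames <- lapply(files, function(f) .to_gray(tiff::readTIFF(f)))
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("cannot read TIFF '", path, "': ",
                                               conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, .to_gray)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes in ", path)
  image_series(frames, role, calibration$pixel_size_um, calibration$frame_interval_s)
}

#' Write an image series as a multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` and written as 16-bit grayscale.
#'
#' @param series An [image_series()] or plain list of matrices.
#' @param path Output file path.
#' @export
write_image_series <- function(series, path) {
  frames <- if (inherits(series, "image_series")) series$frames else series
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read all channels listed in a calibration
#'
#' @param calibration A [calibration()] whose `channels` map roles to paths.
#' @return Named list of [image_series()], one per channel role.
#' @export
read_channels <- function(calibration) {
  if (!length(calibration$channels)) stop("calibration lists no channel files")
  if (is.null(calibration$channels$transmitted))
    stop("required channel missing: transmitted")
  out <- lapply(names(calibration$channels), function(role)
    read_image_series(calibration$channels[[role]], role, calibration))
  names(out) <- names(calibration$channels)
  d1 <- dim(out[[1]]$frames[[1]])
  for (s in out)
    if (!identical(dim(s$frames[[1]]), d1))
      stop("channels are not co-registered: frame shapes differ")
  out
}

#' Read ground-truth tracks from a ViPER-style XML annotation
#'
#' Parses the minimal bounding-box dialect produced by the ViPER video
#' annotation tool: `object` elements containing `bbox` descriptors with
#' per-frame `x`, `y`, `width`, `height` attributes, possibly spanning frame
#' ranges. Frame indices are normalised to 0-based. Non-bbox descriptors are
#' ignored.
#'
#' @param path Path to the XML file.
#' @return A data.frame with columns `gt_id`, `frame`, `x`, `y`, `w`, `h`
#'   (pixels, 0-based frames and coordinates), one row per annotated box.
#' @export
read_viper_ground_truth <- function(path) {
  doc <- xml2::read_xml(path)
  objects <- xml2::xml_find_all(doc, ".//*[local-name()='object']")
  if (!length(objects)) stop("no object elements found in ", path)
  rows <- list()
  for (obj in objects) {
    id <- xml2::xml_attr(obj, "id")
    if (is.na(id)) id <- xml2::xml_attr(obj, "name")
    boxes <- xml2::xml_find_all(obj, ".//*[local-name()='bbox']")
    if (!length(boxes)) next
    for (b in boxes) {
      att <- function(nm) {
        v <- xml2::xml_attr(b, nm)
        if (is.na(v)) stop("bbox of object '", id, "' lacks attribute '", nm, "'")
        as.numeric(v)
      }
      span <- xml2::xml_attr(b, "framespan")
      if (is.na(span)) {
        fr <- att("frame")
        frames <- fr
      } else {
        parts <- as.integer(strsplit(span, ":", fixed = TRUE)[[1]])
        frames <- seq(parts[1], parts[length(parts)])
      }
      # ViPER frame numbering is 1-based; normalise to 0-based
      frames <- frames - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gt_id = as.integer(id), frame = as.integer(frames),
        x = att("x"), y = att("y"), w = att("width"), h = att("height"))
    }
  }
  gt <- do.call(rbind, rows)
  if (any(gt$w <= 0) || any(gt$h <= 0)) stop("non-positive box extent in ", path)
  gt <- gt[order(gt$gt_id, gt$frame), , drop = FALSE]
  if (anyDuplicated(gt[c("gt_id", "frame")]))
    stop("duplicate frame annotation for an object in ", path)
  rownames(gt) <- NULL
  gt
}

#' Write ground-truth tracks as ViPER-style XML
#'
#' Inverse of [read_viper_ground_truth()]; boxes with consecutive frames are
#' written one `bbox` per frame under a single `object` element.
#'
#' @param gt data.frame with columns `gt_id`, `frame`, `x`, `y`, `w`, `h`.
#' @param path Output path.
#' @export
write_viper_ground_truth <- function(gt, path) {
  doc <- xml2::xml_new_root("viper")
  data <- xml2::xml_add_child(doc, "data")
  sf <- xml2::xml_add_child(data, "sourcefile")
  for (id in unique(gt$gt_id)) {
    obj <- xml2::xml_add_child(sf, "object", id = as.character(id), name = "CELL")
    sub <- gt[gt$gt_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      f1 <- sub$frame[i] + 1L  # ViPER frames are 1-based
      num <- function(v) sprintf("%.10g", v)
      xml2::xml_add_child(obj, "bbox",
                          framespan = sprintf("%d:%d", f1, f1),
                          x = num(sub$x[i]), y = num(sub$y[i]),
                          width = num(sub$w[i]), height = num(sub$h[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write tracks and per-position features as a long-format CSV
#'
#' One row per (track, frame): `track_id`, `frame`, `time_s`, `x_um`, `y_um`
#' plus one column per extracted feature (NA where a feature is absent). A
#' sidecar JSON file (same path with extension `.json`) stores the
#' calibration so the table is self-describing.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (pixel coordinates).
#' @param observations Optional data.frame of per-position features keyed by
#'   `track_id` and `frame` (as produced by [extract_features()]); `NULL` for
#'   positions only.
#' @param calibration A [calibration()].
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_tracks_table <- function(tracks, observations = NULL, calibration, path) {
  tab <- data.frame(track_id = tracks$track_id,
                    frame = tracks$frame,
                    time_s = tracks$frame * calibration$frame_interval_s,
                    x_um = tracks$x * calibration$pixel_size_um,
                    y_um = tracks$y * calibration$pixel_size_um)
  if ("radius" %in% names(tracks)) tab$radius_px <- tracks$radius
  if (!is.null(observations) && nrow(observations)) {
    key_t <- paste(tracks$track_id, tracks$frame)
    key_o <- paste(observations$track_id, observations$frame)
    if (!all(key_o %in% key_t))
      stop("observation references a (track, frame) absent from tracks")
    feat_cols <- setdiff(names(observations), c("track_id", "frame", "x", "y"))
    for (cn in feat_cols) tab[[cn]] <- observations[[cn]][match(key_t, key_o)]
  }
  tab <- tab[order(tab$track_id, tab$frame), , drop = FALSE]
  write.csv(tab, path, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(pixel_size_um = calibration$pixel_size_um,
                            frame_interval_s = calibration$frame_interval_s),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Burn cell outlines into an image series and write it as TIFF
#'
#' Marks outline pixels at a fixed marker intensity so segmentation quality
#' can be assessed visually frame by frame.
#'
#' @param series An [image_series()].
#' @param outlines List indexed by frame (1-based list position = frame 0,
#'   ...), each element a data.frame with columns `x`, `y` of outline pixels
#'   (0-based), or `NULL`.
#' @param path Output TIFF path.
#' @param marker Intensity burned at outline pixels (default 1, i.e. white).
#' @export
write_overlay_series <- function(series, outlines, path, marker = 1) {
  frames <- series$frames
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    ol <- if (i <= length(outlines)) outlines[[i]] else NULL
    if (is.null(ol) || !nrow(ol)) next
    if (any(ol$x < 0 | ol$x >= d[2] | ol$y < 0 | ol$y >= d[1]))
      stop("outline coordinates outside image bounds at frame ", i - 1L)
    frames[[i]][cbind(ol$y + 1L, ol$x + 1L)] <- marker
  }
  write_image_series(frames, path)
}
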