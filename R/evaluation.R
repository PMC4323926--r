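# Performance evaluation of detection and tracking against bounding-box
# ground truth: Jaccard similarity, per-frame detection accuracy (FDA),
# sequence FDA, Hungarian track correspondence, and (thresholded) ATA.

#' Jaccard similarity of two axis-aligned boxes
#'
#' `|intersection| / |union|` of the two rectangles; 0 when disjoint.
#'
#' @param a,b Boxes as numeric vectors / one-row data.frames with `x`, `y`
#'   (top-left corner), `w`, `h`.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  iw <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  ih <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- iw * ih
  union <- a$w * a$h + b$w * b$h - inter
  if (union <= 0) return(0)
  inter / union
}

# vectorised Jaccard for aligned rows of two box tables
.jaccard_rows <- function(A, B) {
  iw <- pmax(0, pmin(A$x + A$w, B$x + B$w) - pmax(A$x, B$x))
  ih <- pmax(0, pmin(A$y + A$h, B$y + B$h) - pmax(A$y, B$y))
  inter <- iw * ih
  inter / (A$w * A$h + B$w * B$h - inter)
}

# maximum-sum one-to-one matching on a (rectangular) score matrix; returns
# integer vector over rows: matched column or NA
.match_max <- function(S) {
  n <- nrow(S); m <- ncol(S)
  if (!n || !m) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { S <- t(S); transposed <- TRUE }
  sol <- as.integer(clue::solve_LSAP(S, maximum = TRUE))
  if (!transposed) return(sol)
  out <- rep(NA_integer_, n)
  out[sol] <- seq_len(nrow(S))
  out  # length = original n
}

#' Frame detection accuracy (FDA)
#'
#' Hungarian-matches ground-truth and result boxes of one frame by Jaccard
#' similarity and returns the matched-Jaccard sum normalised by the average
#' object count: `sum(J) / ((N_gt + N_res) / 2)`; 1 when both sides are
#' empty.
#'
#' @param gt_boxes,result_boxes data.frames of boxes (`x`, `y`, `w`, `h`) on
#'   one frame.
#' @return Accuracy in `[0, 1]`.
#' @export
frame_detection_accuracy <- function(gt_boxes, result_boxes) {
  ng <- nrow(gt_boxes); nr <- nrow(result_boxes)
  if (ng == 0 && nr == 0) return(1)
  if (ng == 0 || nr == 0) return(0)
  S <- matrix(0, ng, nr)
  for (i in seq_len(ng))
    S[i, ] <- .jaccard_rows(gt_boxes[rep(i, nr), , drop = FALSE], result_boxes)
  mt <- .match_max(S)
  tot <- sum(S[cbind(which(!is.na(mt)), mt[!is.na(mt)])])
  tot / ((ng + nr) / 2)
}

#' Convert circle detections or tracked points to bounding boxes
#'
#' The axis-aligned square of side `2 * radius` centered on each point.
#'
#' @param points data.frame with `frame`, `x`, `y` and optionally `radius`
#'   (fallback used where absent), plus an id column.
#' @param id Name of the id column to carry through (`"track_id"` or none).
#' @param default_radius Radius used when the `radius` column is missing/NA.
#' @return data.frame of boxes with the id column, `frame`, `x`, `y`, `w`,
#'   `h`.
#' @export
points_to_boxes <- function(points, id = "track_id", default_radius = 10) {
  r <- if ("radius" %in% names(points)) points$radius else
    rep(default_radius, nrow(points))
  r[is.na(r)] <- default_radius
  out <- data.frame(frame = points$frame,
                    x = points$x - r, y = points$y - r, w = 2 * r, h = 2 * r)
  if (!is.null(id) && id %in% names(points))
    out <- cbind(points[id], out)
  out
}

#' Sequence frame detection accuracy (SFDA)
#'
#' Mean of [frame_detection_accuracy()] over all frames where either side
#' has at least one box.
#'
#' @param gt_boxes data.frame of ground-truth boxes (`frame`, `x`, `y`, `w`,
#'   `h`).
#' @param result_boxes data.frame of result boxes (same columns).
#' @return List: `sfda` and the per-frame `fda` table.
#' @export
sfda <- function(gt_boxes, result_boxes) {
  frames <- sort(union(gt_boxes$frame, result_boxes$frame))
  fda <- vapply(frames, function(f)
    frame_detection_accuracy(gt_boxes[gt_boxes$frame == f, , drop = FALSE],
                             result_boxes[result_boxes$frame == f, , drop = FALSE]),
    numeric(1))
  list(sfda = if (length(fda)) mean(fda) else 1,
       fda = data.frame(frame = frames, fda = fda))
}

# spatiotemporal pair score between one gt track and one result track:
# mean over the union of their frames of per-frame Jaccard (0 where one side
# is absent; J >= threshold counts as 1 when thresholding)
.pair_score <- function(g, r, jaccard_threshold = NULL) {
  common <- intersect(g$frame, r$frame)
  n_union <- length(union(g$frame, r$frame))
  if (!length(common)) return(0)
  gi <- g[match(common, g$frame), , drop = FALSE]
  ri <- r[match(common, r$frame), , drop = FALSE]
  J <- .jaccard_rows(gi, ri)
  if (!is.null(jaccard_threshold)) J[J >= jaccard_threshold] <- 1
  sum(J) / n_union
}

#' One-to-one correspondence between ground-truth and result tracks
#'
#' The pairwise score is the mean per-frame Jaccard over the union of the
#' two tracks' frames (frames covered by only one side contribute 0); with
#' `jaccard_threshold` set, per-frame values at or above the threshold count
#' as 1 so that minor localisation inaccuracy is not penalised. The
#' Hungarian algorithm then maximises the total score one-to-one.
#'
#' @param gt_boxes data.frame of ground-truth boxes (`gt_id`, `frame`, `x`,
#'   `y`, `w`, `h`).
#' @param result_boxes data.frame of result boxes (`track_id`, `frame`, ...).
#' @param jaccard_threshold Per-frame threshold or `NULL` for the raw score.
#' @return List of class `correspondence`: `pairs` (data.frame `gt_id`,
#'   `track_id`, `score`), `unmatched_gt`, `unmatched_result`, and the score
#'   matrix.
#' @export
track_correspondence <- function(gt_boxes, result_boxes, jaccard_threshold = NULL) {
  gt_split <- split(gt_boxes, gt_boxes$gt_id)
  res_split <- split(result_boxes, result_boxes$track_id)
  ng <- length(gt_split); nr <- length(res_split)
  S <- matrix(0, ng, nr,
              dimnames = list(names(gt_split), names(res_split)))
  if (ng && nr) {
    # frame-range prefilter keeps the double loop cheap
    g_rng <- t(vapply(gt_split, function(g) range(g$frame), numeric(2)))
    r_rng <- t(vapply(res_split, function(r) range(r$frame), numeric(2)))
    for (i in seq_len(ng)) for (j in seq_len(nr)) {
      if (g_rng[i, 1] > r_rng[j, 2] || r_rng[j, 1] > g_rng[i, 2]) next
      S[i, j] <- .pair_score(gt_split[[i]], res_split[[j]], jaccard_threshold)
    }
  }
  mt <- if (ng && nr) .match_max(S) else rep(NA_integer_, ng)
  matched <- which(!is.na(mt) & S[cbind(seq_len(ng), ifelse(is.na(mt), 1L, mt))] > 0)
  pairs <- data.frame(
    gt_id = as.integer(names(gt_split))[matched],
    track_id = as.integer(names(res_split))[mt[matched]],
    score = S[cbind(matched, mt[matched])])
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(as.integer(names(gt_split)), pairs$gt_id),
                 unmatched_result = setdiff(as.integer(names(res_split)),
                                            pairs$track_id),
                 scores = S),
            class = "correspondence")
}

#' Average tracking accuracy (ATA)
#'
#' Sum of matched pair scores from [track_correspondence()] divided by the
#' average number of tracks, `(N_gt + N_result) / 2`.
#'
#' @inheritParams track_correspondence
#' @return ATA in `[0, 1]`.
#' @export
ata <- function(gt_boxes, result_boxes, jaccard_threshold = NULL) {
  ng <- length(unique(gt_boxes$gt_id))
  nr <- length(unique(result_boxes$track_id))
  if (ng == 0 && nr == 0) return(1)
  if (ng == 0 || nr == 0) return(0)
  corr <- track_correspondence(gt_boxes, result_boxes, jaccard_threshold)
  sum(corr$pairs$score) / ((ng + nr) / 2)
}

#' Full evaluation report of detection and tracking
#'
#' @param gt_boxes Ground-truth box table (`gt_id`, `frame`, `x`, `y`, `w`,
#'   `h`), e.g. from [read_viper_ground_truth()].
#' @param result_boxes Result box table (`track_id`, `frame`, ...), e.g.
#'   from [points_to_boxes()].
#' @param jaccard_threshold Threshold for the thresholded ATA (default 0.4).
#' @return List of class `eval_report`: `sfda`, `ata`, `ata_thresholded`,
#'   `jaccard_threshold`, `fda` (per-frame table), `pairs` (thresholded
#'   correspondence).
#' @export
evaluate_tracking <- function(gt_boxes, result_boxes, jaccard_threshold = 0.4) {
  sf <- sfda(gt_boxes, result_boxes)
  structure(list(sfda = sf$sfda,
                 ata = ata(gt_boxes, result_boxes, NULL),
                 ata_thresholded = ata(gt_boxes, result_boxes, jaccard_threshold),
                 jaccard_threshold = jaccard_threshold,
                 fda = sf$fda,
                 pairs = track_correspondence(gt_boxes, result_boxes,
                                              jaccard_threshold)$pairs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("SFDA %.3f | ATA %.3f | ATA(thresholded, J>=%.2f) %.3f | %d matched pairs\n",
              x$sfda, x$ata, x$jaccard_threshold, x$ata_thresholded, nrow(x$pairs)))
  invisible(x)
}

#' Evaluate feature extraction against ground truth
#'
#' Per frame, ground-truth cells and extracted observations are matched
#' one-to-one by centroid distance (Hungarian, gated at `max_distance`), and
#' the absolute and relative error of each feature is reported per matched
#' pair, with the median absolute relative error as summary.
#'
#' @param gt_features data.frame of ground-truth cells per frame with
#'   centroid columns `x`, `y` and feature columns.
#' @param observations Extracted observations (from [extract_features()]).
#' @param features Named character vector mapping observation columns to
#'   ground-truth columns; the default matches the synthetic generator's
#'   truth table.
#' @param max_distance Centroid gate, px.
#' @return List: `pairs` (long table of per-pair errors) and `summary`
#'   (median absolute relative error per feature).
#' @export
evaluate_feature_extraction <- function(gt_features, observations,
                                        features = c(
                                          contact_area_um2 = "footprint_area_um2",
                                          mean_fluor1 = "fluor1_mean",
                                          mean_fluor2 = "fluor2_mean",
                                          aspect_ratio = "aspect"),
                                        max_distance = 18) {
  features <- features[features %in% names(gt_features) &
                         names(features) %in% names(observations)]
  # drop features that were not extracted at all (channel not requested)
  extracted <- vapply(names(features), function(cn)
    any(!is.na(observations[[cn]])), logical(1))
  features <- features[extracted]
  frames <- sort(intersect(gt_features$frame, observations$frame))
  rows <- list()
  for (f in frames) {
    g <- gt_features[gt_features$frame == f, , drop = FALSE]
    o <- observations[observations$frame == f, , drop = FALSE]
    if (!nrow(g) || !nrow(o)) next
    D <- sqrt(outer(g$x, o$x, "-")^2 + outer(g$y, o$y, "-")^2)
    mt <- .match_max(max(D) + 1 - D)
    for (i in which(!is.na(mt))) {
      j <- mt[i]
      if (D[i, j] > max_distance) next
      for (k in seq_along(features)) {
        gv <- g[[features[k]]][i]; ov <- o[[names(features)[k]]][j]
        if (is.na(gv) || gv == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, feature = names(features)[k],
          gt = gv, result = ifelse(is.na(ov), 0, ov),
          abs_error = abs(ifelse(is.na(ov), 0, ov) - gv),
          rel_error = abs(ifelse(is.na(ov), 0, ov) - gv) / abs(gv))
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), feature = character(), gt = numeric(),
               result = numeric(), abs_error = numeric(), rel_error = numeric())
  summary <- aggregate(rel_error ~ feature, pairs, median)
  names(summary)[2] <- "median_abs_rel_error"
  list(pairs = pairs, summary = summary)
}
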