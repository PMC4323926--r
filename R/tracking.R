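# Two-tier tracking: conservative nearest-neighbour linking into confident
# frame-contiguous segments, then global end-to-end joining of segments by a
# similarity-scored assignment.

#' Tracking parameters
#'
#' @param r Maximal allowed link distance between consecutive frames, px.
#' @param max_gap Maximal frame gap bridged when joining segments.
#' @param v_max Plausible speed bound, px/frame, used by the segment
#'   similarity; `NULL` (default) estimates it from the data as 1.5 times the
#'   95th percentile of observed per-step displacements.
#' @param join_threshold Segments are joined only if their similarity exceeds
#'   this value, in `[0, 1]`.
#' @param w_time,w_space,w_speed Nonnegative similarity weights (normalised
#'   to sum to 1).
#' @param min_track_len Tracks with fewer points are discarded (default 5).
#' @return An object of class `link_params`.
#' @export
link_params <- function(r = 30, max_gap = 4, v_max = NULL, join_threshold = 0.4,
                        w_time = 0.25, w_space = 0.5, w_speed = 0.25,
                        min_track_len = 5) {
  stopifnot(r > 0, max_gap >= 1, join_threshold >= 0, join_threshold <= 1,
            w_time >= 0, w_space >= 0, w_speed >= 0,
            w_time + w_space + w_speed > 0, min_track_len >= 1)
  s <- w_time + w_space + w_speed
  structure(list(r = r, max_gap = max_gap, v_max = v_max,
                 join_threshold = join_threshold,
                 w_time = w_time / s, w_space = w_space / s, w_speed = w_speed / s,
                 min_track_len = as.integer(min_track_len)),
            class = "link_params")
}

#' Link detections into confident track segments (modified nearest neighbour)
#'
#' Detections in consecutive frames are linked only when the association is
#' unambiguous: a segment end is extended to a detection at the next frame
#' when that detection is the only candidate within distance `r` of the end
#' *and* the end is the only segment competing for that detection. Any
#' ambiguity (several candidates within `r`, or a detection contested by two
#' ends) terminates the involved segments and starts fresh one-point segments
#' at the contested detections, deferring resolution to the joining stage.
#' Unclaimed detections always start new segments.
#'
#' @param detections data.frame from [detect_cells()] (`frame`, `x`, `y`,
#'   optionally `radius`, `score`).
#' @param params A [link_params()].
#' @return data.frame of segment points: `seg_id`, `frame`, `x`, `y` plus any
#'   extra detection columns; frames within a segment are consecutive.
#' @export
link_nearest_neighbor <- function(detections, params = link_params()) {
  cols <- names(detections)
  empty <- cbind(data.frame(seg_id = integer()),
                 detections[0, , drop = FALSE])
  if (!nrow(detections)) return(empty)
  det <- detections[order(detections$frame), , drop = FALSE]
  frames_all <- seq(min(det$frame), max(det$frame))
  seg_of_point <- integer(nrow(det))        # segment id per detection row
  det_row <- seq_len(nrow(det))
  by_frame <- split(det_row, factor(det$frame, levels = frames_all))
  n_seg <- 0L
  open_rows <- integer(0)                   # detection rows that are open ends
  for (fi in seq_along(frames_all)) {
    rows_t <- by_frame[[fi]]
    if (!length(rows_t)) { open_rows <- integer(0); next }
    if (!length(open_rows)) {
      seg_of_point[rows_t] <- n_seg + seq_along(rows_t)
      n_seg <- n_seg + length(rows_t)
      open_rows <- rows_t
      next
    }
    ex <- det$x[open_rows]; ey <- det$y[open_rows]
    dx <- outer(ex, det$x[rows_t], "-"); dy <- outer(ey, det$y[rows_t], "-")
    within <- sqrt(dx^2 + dy^2) <= params$r
    deg_end <- rowSums(within); deg_det <- colSums(within)
    new_open <- integer(0)
    extended_det <- logical(length(rows_t))
    for (k in seq_along(open_rows)) {
      if (deg_end[k] == 1L) {
        j <- which(within[k, ])
        if (deg_det[j] == 1L) {             # mutual unique: extend
          seg_of_point[rows_t[j]] <- seg_of_point[open_rows[k]]
          extended_det[j] <- TRUE
          new_open <- c(new_open, rows_t[j])
        }
      }
      # otherwise the segment terminates (0 candidates or ambiguity)
    }
    fresh <- which(!extended_det)
    if (length(fresh)) {
      seg_of_point[rows_t[fresh]] <- n_seg + seq_along(fresh)
      n_seg <- n_seg + length(fresh)
      new_open <- c(new_open, rows_t[fresh])
    }
    open_rows <- new_open
  }
  out <- cbind(data.frame(seg_id = seg_of_point), det)
  out <- out[order(out$seg_id, out$frame), , drop = FALSE]
  # renumber segments by (first frame, first x) for determinism
  first <- out[!duplicated(out$seg_id), ]
  remap <- setNames(seq_len(nrow(first)),
                    first$seg_id[order(first$frame, first$x)])
  out$seg_id <- as.integer(remap[as.character(out$seg_id)])
  out <- out[order(out$seg_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mean per-step displacement (px/frame) of a segment's points; NA if 1 point
.segment_speed <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(NA_real_)
  sum(sqrt(diff(pts$x)^2 + diff(pts$y)^2)) / (pts$frame[n] - pts$frame[1])
}

#' Similarity between two track segments
#'
#' Scores the plausibility that segment `b` is the continuation of segment
#' `a`, combining temporal proximity, spatial proximity relative to the
#' plausible speed bound, and agreement of mean speeds:
#' `w_time*s_time + w_space*s_space + w_speed*s_speed` with
#' `s_time = 1 - (gap-1)/(max_gap-1)`, `s_space = 1 - d/(v_max*gap)` and
#' `s_speed = 1 - |v_a - v_b| / max(v_a, v_b, eps)`. Returns 0 when the pair
#' is infeasible (`b` starts at or before the end of `a`, the gap exceeds
#' `max_gap`, or the end-to-start distance exceeds `v_max * gap`). When
#' either segment is a single point its speed is unknown and `s_speed` takes
#' the uninformative value 0.5.
#'
#' @param a,b data.frames of segment points (`frame`, `x`, `y`), `a` the
#'   candidate predecessor.
#' @param params A [link_params()]; `v_max` must be set.
#' @return Similarity in `[0, 1]`.
#' @export
segment_similarity <- function(a, b, params) {
  v_max <- params$v_max
  if (is.null(v_max)) stop("v_max must be set (it is estimated in join_segments)")
  na <- nrow(a)
  gap <- b$frame[1] - a$frame[na]
  if (gap < 1 || gap > params$max_gap) return(0)
  d <- sqrt((b$x[1] - a$x[na])^2 + (b$y[1] - a$y[na])^2)
  if (d > v_max * gap) return(0)
  s_time <- 1 - (gap - 1) / max(params$max_gap - 1, 1)
  s_space <- 1 - d / (v_max * gap)
  va <- .segment_speed(a); vb <- .segment_speed(b)
  s_speed <- if (is.na(va) || is.na(vb)) 0.5
             else 1 - abs(va - vb) / max(va, vb, 1e-9)
  s <- params$w_time * s_time + params$w_space * s_space + params$w_speed * s_speed
  min(max(s, 0), 1)
}

# full pairwise similarity matrix (rows = predecessors, cols = successors)
.similarity_matrix <- function(seg_list, params) {
  n <- length(seg_list)
  S <- matrix(0, n, n)
  if (n < 2L) return(S)
  starts <- vapply(seg_list, function(s) s$frame[1], numeric(1))
  ends <- vapply(seg_list, function(s) s$frame[nrow(s)], numeric(1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (starts[j] - ends[i] >= 1 && starts[j] - ends[i] <= params$max_gap)
      S[i, j] <- segment_similarity(seg_list[[i]], seg_list[[j]], params)
  }
  S
}

# default data-driven speed bound: 1.5 x the 95th percentile of per-step
# displacements, observed as consecutive-frame nearest-neighbour distances
# over all points. Within-segment steps are censored at the link radius r,
# which would make the bound (and hence the joining stage) depend on r in
# exactly the regime where joining must bridge what linking could not;
# nearest-neighbour displacements between raw consecutive frames are not.
.estimate_v_max <- function(seg_list, params) {
  pts <- do.call(rbind, lapply(seg_list, function(s) s[c("frame", "x", "y")]))
  by_frame <- split(pts, pts$frame)
  frames <- as.integer(names(by_frame))
  steps <- numeric(0)
  for (k in seq_len(length(frames) - 1)) {
    if (frames[k + 1] != frames[k] + 1L) next
    a <- by_frame[[k]]; b <- by_frame[[k + 1]]
    D <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    steps <- c(steps, apply(D, 1, min))
  }
  if (!length(steps) || max(steps) == 0) return(params$r)
  as.numeric(quantile(steps, 0.95)) * 1.5
}

#' Join track segments end-to-end into longer tracks
#'
#' Builds the full predecessor-by-successor similarity matrix, augments it
#' with per-predecessor "no join" options valued at `join_threshold`, and
#' solves the resulting assignment problem (Hungarian algorithm) for the
#' globally optimal mapping. Assigned pairs are joined only when their
#' similarity strictly exceeds `join_threshold`; accepted joins are chained
#' transitively. Joined tracks keep their frame gaps (no interpolation).
#'
#' @param segments data.frame from [link_nearest_neighbor()] (`seg_id` plus
#'   point columns).
#' @param params A [link_params()].
#' @return data.frame of track points: `track_id`, `frame`, `x`, `y`, plus
#'   carried-through columns. Track ids are assigned in order of first frame,
#'   then first x.
#' @export
join_segments <- function(segments, params = link_params()) {
  if (!nrow(segments)) {
    out <- cbind(data.frame(track_id = integer()), segments[0, ])
    out$seg_id <- NULL
    return(out)
  }
  seg_list <- split(segments, segments$seg_id)
  seg_list <- lapply(seg_list, function(s) s[order(s$frame), , drop = FALSE])
  n <- length(seg_list)
  if (is.null(params$v_max)) params$v_max <- .estimate_v_max(seg_list, params)
  succ <- rep(NA_integer_, n)
  if (n >= 2L) {
    S <- .similarity_matrix(seg_list, params)
    M <- cbind(S, matrix(params$join_threshold, n, n))
    sol <- clue::solve_LSAP(M, maximum = TRUE)
    assigned <- as.integer(sol)
    for (i in seq_len(n)) {
      j <- assigned[i]
      if (j <= n && S[i, j] > params$join_threshold) succ[i] <- j
    }
  }
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  chains <- list()
  for (i in which(!has_pred)) {
    chain <- i
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    chains[[length(chains) + 1L]] <- chain
  }
  tracks <- lapply(chains, function(ch) do.call(rbind, seg_list[ch]))
  firsts <- t(vapply(tracks, function(tr) c(tr$frame[1], tr$x[1]), numeric(2)))
  ord <- order(firsts[, 1], firsts[, 2])
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    tr <- tracks[[ord[k]]]
    cbind(data.frame(track_id = k), tr)
  }))
  out$seg_id <- NULL
  rownames(out) <- NULL
  out
}

#' Discard short tracks
#'
#' @param tracks data.frame of track points (`track_id`, ...).
#' @param params A [link_params()]; tracks with fewer than `min_track_len`
#'   points are removed.
#' @return Filtered data.frame.
#' @export
filter_short_tracks <- function(tracks, params = link_params()) {
  if (!nrow(tracks)) return(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= params$min_track_len]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply manual split/join edits to tracks
#'
#' Edits mirror manually compiled correction lists: all `split` operations
#' are applied first, then all `join` operations. `split` at frame `f` leaves
#' points with `frame <= f - 1` under the original id and moves points with
#' `frame >= f` to a fresh id (`max(id) + 1` at the time of the edit).
#' `join` concatenates `track_id2` onto `track_id` and requires the first
#' track to end strictly before the second begins.
#'
#' @param tracks data.frame of track points.
#' @param edits data.frame with columns `op` (`"split"` or `"join"`),
#'   `track_id`, `frame` (splits), `track_id2` (joins); or a path to a CSV
#'   file with those columns.
#' @return Edited data.frame of track points.
#' @export
edit_tracks <- function(tracks, edits) {
  if (is.character(edits)) edits <- read.csv(edits)
  stopifnot(all(edits$op %in% c("split", "join")))
  edits <- edits[order(match(edits$op, c("split", "join"))), , drop = FALSE]
  for (k in seq_len(nrow(edits))) {
    e <- edits[k, ]
    if (!e$track_id %in% tracks$track_id)
      stop("edit references unknown track id ", e$track_id)
    if (e$op == "split") {
      sel <- tracks$track_id == e$track_id & tracks$frame >= e$frame
      if (!any(sel) || all(tracks$frame[tracks$track_id == e$track_id] >= e$frame))
        stop("split of track ", e$track_id, " at frame ", e$frame,
             " would leave an empty piece")
      tracks$track_id[sel] <- max(tracks$track_id) + 1L
    } else {
      if (!e$track_id2 %in% tracks$track_id)
        stop("edit references unknown track id ", e$track_id2)
      f1 <- max(tracks$frame[tracks$track_id == e$track_id])
      f2 <- min(tracks$frame[tracks$track_id == e$track_id2])
      if (f1 >= f2)
        stop("cannot join tracks ", e$track_id, " and ", e$track_id2,
             ": frame ranges overlap")
      tracks$track_id[tracks$track_id == e$track_id2] <- e$track_id
    }
  }
  out <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
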