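# Shared fixtures and independent oracles for the test suite. The small
# synthetic movie is generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# small default-condition movie reused across modules (15 cells, 12 frames)
small_movie <- function() {
  if (is.null(.fixture_env$mv)) {
    .fixture_env$p <- synth_params(n_cells = 15, n_frames = 12, seed = 11)
    .fixture_env$mv <- synth_movie(.fixture_env$p)
  }
  .fixture_env$mv
}
small_params <- function() { small_movie(); .fixture_env$p }
small_cal <- function() {
  p <- small_params()
  calibration(p$pixel_size_um, p$frame_interval_s)
}

# detection + tracking on the small movie, cached
small_tracks <- function() {
  if (is.null(.fixture_env$tracks)) {
    mv <- small_movie()
    det <- detect_cells(mv$channels$transmitted)
    .fixture_env$detections <- det
    .fixture_env$tracks <- filter_short_tracks(
      join_segments(link_nearest_neighbor(det)), link_params())
  }
  .fixture_env$tracks
}
small_detections <- function() { small_tracks(); .fixture_env$detections }

# render a single frame containing one circle outline blurred slightly,
# for detector geometry tests
circle_frame <- function(W = 96, cx = 48, cy = 48, r = 10, arc_keep = 1) {
  img <- matrix(0.5, W, W)
  phi <- seq(0, 2 * pi * arc_keep, length.out = round(500 * arc_keep))
  for (k in seq_along(phi)) {
    x <- cx + r * cos(phi[k]); y <- cy + r * sin(phi[k])
    img[round(y) + 1, round(x) + 1] <- 1
  }
  as.matrix(EBImage::gblur(EBImage::Image(img), 1))
}

# brute-force circular Hough oracle: plain loops over edge pixels x radii x
# both gradient senses (independent of the vectorised implementation)
brute_force_hough <- function(edges, gradient, radius_min, radius_max) {
  W <- nrow(edges); H <- ncol(edges)
  acc <- matrix(0, W, H)
  for (iy in seq_len(W)) for (ix in seq_len(H)) {
    if (!edges[iy, ix]) next
    gx <- gradient$gx[iy, ix]; gy <- gradient$gy[iy, ix]
    mg <- sqrt(gx^2 + gy^2)
    if (mg <= 0) next
    for (r in seq(radius_min, radius_max)) for (s in c(-1, 1)) {
      cx <- round(ix + s * r * gx / mg); cy <- round(iy + s * r * gy / mg)
      if (cx >= 1 && cx <= H && cy >= 1 && cy <= W)
        acc[cy, cx] <- acc[cy, cx] + 1
    }
  }
  acc
}

# exhaustive maximum-weight one-to-one matching over a score matrix
# (enumerates all injective row->column assignments including "unmatched")
exhaustive_matching <- function(S) {
  n <- nrow(S); m <- ncol(S)
  best <- list(score = -Inf, match = rep(NA_integer_, n))
  recurse <- function(i, used, match, score) {
    if (i > n) {
      if (score > best$score) best <<- list(score = score, match = match)
      return(invisible())
    }
    recurse(i + 1L, used, match, score)  # row i unmatched
    for (j in seq_len(m)) if (!used[j]) {
      match[i] <- j; used[j] <- TRUE
      recurse(i + 1L, used, match, score + S[i, j])
      match[i] <- NA_integer_; used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, m), rep(NA_integer_, n), 0)
  best
}

# exhaustive segment-joining oracle: maximise sum of (sim - threshold) over
# any feasible set of predecessor->successor pairs, then chain to tracks;
# returns the partition of segment ids into chains
exhaustive_join <- function(S, threshold) {
  n <- nrow(S)
  gain <- S - threshold
  gain[gain <= 0] <- NA
  pairs <- which(!is.na(gain), arr.ind = TRUE)
  best <- list(score = 0, succ = rep(NA_integer_, n))
  k <- nrow(pairs)
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel)) {
      pr <- pairs[sel, , drop = FALSE]
      if (anyDuplicated(pr[, 1]) || anyDuplicated(pr[, 2])) next
      sc <- sum(gain[pr])
    } else sc <- 0
    if (sc > best$score) {
      succ <- rep(NA_integer_, n)
      if (length(sel)) succ[pairs[sel, 1]] <- pairs[sel, 2]
      best <- list(score = sc, succ = succ)
    }
  }
  best
}

# chains (tracks) implied by a successor map, as sorted list of id vectors
chains_of <- function(succ) {
  n <- length(succ)
  has_pred <- rep(FALSE, n); has_pred[succ[!is.na(succ)]] <- TRUE
  out <- list()
  for (i in which(!has_pred)) {
    ch <- i
    while (!is.na(succ[ch[length(ch)]])) ch <- c(ch, succ[ch[length(ch)]])
    out[[length(out) + 1L]] <- ch
  }
  out[order(vapply(out, `[`, integer(1), 1))]
}

# break ground-truth positions into segments at random frames; returns a
# segment table (seg_id, frame, x, y) and the parent cell of each segment
break_tracks <- function(positions, n_breaks_per_track = 2, seed = 1) {
  set.seed(seed)
  out <- list(); parent <- integer(0); sid <- 0L
  for (cid in unique(positions$cell_id)) {
    tr <- positions[positions$cell_id == cid, ]
    tr <- tr[order(tr$frame), ]
    nb <- min(n_breaks_per_track, nrow(tr) - 1)
    cuts <- sort(sample(seq_len(nrow(tr) - 1), nb))
    bounds <- c(0, cuts, nrow(tr))
    for (b in seq_len(length(bounds) - 1)) {
      sid <- sid + 1L
      piece <- tr[(bounds[b] + 1):bounds[b + 1], ]
      out[[sid]] <- data.frame(seg_id = sid, frame = piece$frame,
                               x = piece$x, y = piece$y,
                               radius = piece$radius %||% 10)
      parent <- c(parent, cid)
    }
  }
  list(segments = do.call(rbind, out), parent = parent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
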