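det_df <- function(...) {
  # rows of (frame, x, y)
  m <- rbind(...)
  data.frame(frame = m[, 1], x = m[, 2], y = m[, 3])
}

test_that("unambiguous nearest-neighbour linking follows cells", {
  # two cells moving apart 5 px/frame for 5 frames
  rows <- do.call(rbind, lapply(0:4, function(f)
    rbind(c(f, 10 + 5 * f, 50), c(f, 90 - 5 * f, 50))))
  seg <- link_nearest_neighbor(det_df(rows), link_params(r = 10))
  expect_equal(length(unique(seg$seg_id)), 2)
  expect_equal(as.integer(table(seg$seg_id)), c(5L, 5L))
})

test_that("ambiguity terminates segments and starts fresh ones", {
  # one cell at (50,50); at frame 2 two detections both within r
  d <- det_df(c(0, 50, 50), c(1, 50, 50), c(2, 46, 50), c(2, 54, 50))
  seg <- link_nearest_neighbor(d, link_params(r = 10))
  lens <- as.integer(table(seg$seg_id))
  expect_equal(sort(lens), c(1L, 1L, 2L))  # old segment ends at frame 1
  ends <- tapply(seg$frame, seg$seg_id, max)
  expect_equal(sort(as.numeric(ends)), c(1, 2, 2))
})

test_that("an empty frame terminates all segments", {
  d <- det_df(c(0, 10, 10), c(1, 12, 10), c(3, 14, 10), c(4, 16, 10))
  seg <- link_nearest_neighbor(d, link_params(r = 10))
  expect_equal(length(unique(seg$seg_id)), 2)
  expect_true(all(tapply(seg$frame, seg$seg_id,
                         function(f) all(diff(f) == 1))))
})

test_that("a detection contested by two segment ends terminates both", {
  d <- det_df(c(0, 10, 50), c(0, 30, 50),
              c(1, 12, 50), c(1, 28, 50),
              c(2, 20, 50))                      # equidistant from both ends
  seg <- link_nearest_neighbor(d, link_params(r = 12))
  lens <- sort(as.integer(table(seg$seg_id)))
  expect_equal(lens, c(1L, 2L, 2L))
})

test_that("linking conserves detections (no duplication, no fabrication)", {
  det <- small_detections()
  seg <- link_nearest_neighbor(det, link_params())
  expect_equal(nrow(seg), nrow(det))
  expect_false(anyDuplicated(seg[c("frame", "x", "y")]) > 0)
  expect_true(all(tapply(seg$frame, seg$seg_id,
                         function(f) all(diff(f) == 1))))
})

test_that("segment similarity matches its defining formula", {
  p <- link_params(max_gap = 4, v_max = 10, w_time = 0.25, w_space = 0.5,
                   w_speed = 0.25)
  mk <- function(frames, xs, ys) data.frame(frame = frames, x = xs, y = ys)
  # temporal infeasibility
  a <- mk(0:10, seq(0, 50, 5), rep(0, 11))
  b_before <- mk(5:8, 1:4, rep(0, 4))
  expect_equal(segment_similarity(a, b_before, p), 0)
  # perfect continuation: gap 1, distance 0, equal speeds
  a2 <- mk(8:10, c(0, 5, 10), rep(0, 3))
  b2 <- mk(11:13, c(10, 15, 20), rep(0, 3))
  b2$x <- b2$x - 10  # end of a2 is (10,0); start b at (10,0)
  b2$x <- c(10, 15, 20)
  expect_equal(segment_similarity(a2, b2, p), 1.0)
  # the worked mixed case: gap 2, d 8, equal speeds 5
  a3 <- mk(6:10, seq(-20, 0, 5), rep(0, 5))     # ends frame 10 at (0,0), speed 5
  b3 <- mk(12:16, seq(8, 28, 5), rep(0, 5))     # starts frame 12 at (8,0), speed 5
  expect_equal(segment_similarity(a3, b3, p),
               0.25 * (2 / 3) + 0.5 * (1 - 8 / 20) + 0.25 * 1,
               tolerance = 1e-12)
  # distance beyond v_max * gap is infeasible
  b4 <- mk(11, 100, 0)
  expect_equal(segment_similarity(a3, b4, p), 0)
})

test_that("joining respects the similarity threshold", {
  p <- link_params(v_max = 10, join_threshold = 0.99)
  seg <- rbind(data.frame(seg_id = 1, frame = 0:2, x = c(0, 5, 10), y = 0),
               data.frame(seg_id = 2, frame = 4:6, x = c(30, 35, 40), y = 0))
  tr <- join_segments(seg, p)
  expect_equal(length(unique(tr$track_id)), 2)  # all sims below threshold
})

test_that("global assignment beats greedy on crossing broken tracks", {
  # two tracks crossing; each broken at the crossing. Speeds differ (2 vs 8
  # px/frame) so the correct continuation is speed-matched even though the
  # wrong one is spatially closer for one pair.
  p <- link_params(v_max = 12, join_threshold = 0.2)
  s1 <- data.frame(seg_id = 1, frame = 0:4, x = seq(0, 8, 2), y = seq(0, 8, 2))
  s2 <- data.frame(seg_id = 2, frame = 0:4, x = seq(40, 8, -8), y = seq(0, 8, 2))
  s3 <- data.frame(seg_id = 3, frame = 5:9, x = seq(10, 18, 2), y = seq(10, 18, 2))
  s4 <- data.frame(seg_id = 4, frame = 5:9, x = seq(0, -32, -8), y = seq(10, 18, 2))
  tr <- join_segments(rbind(s1, s2, s3, s4), p)
  expect_equal(length(unique(tr$track_id)), 2)
  by_track <- split(tr, tr$track_id)
  xs0 <- vapply(by_track, function(t) t$x[1], numeric(1))
  # slow track (starting at 0) must continue into s3 (x 10..18)
  slow <- by_track[[which(xs0 == 0)]]
  expect_true(18 %in% slow$x && !-32 %in% slow$x)
})

test_that("join_segments matches exhaustive search for up to 6 segments", {
  p <- link_params(v_max = 10, join_threshold = 0.4, max_gap = 4)
  set.seed(42)
  for (rep in 1:5) {
    segs <- list()
    t0 <- 0
    for (i in 1:6) {
      start <- sample(0:12, 1)
      len <- sample(1:4, 1)
      x0 <- runif(1, 0, 40)
      segs[[i]] <- data.frame(seg_id = i, frame = start:(start + len - 1),
                              x = x0 + seq(0, by = runif(1, 0, 6),
                                           length.out = len),
                              y = runif(1, 0, 40))
    }
    seg_df <- do.call(rbind, segs)
    # fix v_max so implementation and oracle score the same matrix
    seg_list <- split(seg_df, seg_df$seg_id)
    S <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) if (i != j)
      S[i, j] <- segment_similarity(seg_list[[i]], seg_list[[j]], p)
    oracle <- exhaustive_join(S, p$join_threshold)
    tr <- join_segments(seg_df, p)
    # compare implied chain partitions via total accepted gain
    got_chains <- lapply(split(tr, tr$track_id), function(t) nrow(t))
    impl_score <- {
      # recover successor pairs from the track composition
      sc <- 0
      for (t in split(tr, tr$track_id)) {
        ids <- unique(seg_df$seg_id[match(paste(t$frame, t$x, t$y),
                                          paste(seg_df$frame, seg_df$x, seg_df$y))])
        if (length(ids) > 1)
          for (k in seq_len(length(ids) - 1))
            sc <- sc + S[ids[k], ids[k + 1]] - p$join_threshold
      }
      sc
    }
    expect_equal(impl_score, oracle$score, tolerance = 1e-9)
  }
})

test_that("break-and-rejoin restores synthetically broken ground truth", {
  mv <- small_movie()
  br <- break_tracks(mv$positions, n_breaks_per_track = 2, seed = 5)
  p <- link_params(v_max = NULL, join_threshold = 0.4)
  tr <- join_segments(br$segments, p)
  # at least 90% of the breaks must be healed (an extreme-tail step can
  # legitimately exceed the estimated speed bound and stay split)
  n_cells <- length(unique(mv$positions$cell_id))
  n_breaks <- length(unique(br$segments$seg_id)) - n_cells
  n_healed <- length(unique(br$segments$seg_id)) -
    length(unique(tr$track_id))
  expect_gte(n_healed / n_breaks, 0.9)
  # every rejoined track covers exactly one parent cell's points
  for (t in split(tr, tr$track_id)) {
    key <- paste(t$frame, round(t$x, 6), round(t$y, 6))
    pk <- paste(mv$positions$frame, round(mv$positions$x, 6),
                round(mv$positions$y, 6))
    parents <- unique(mv$positions$cell_id[match(key, pk)])
    expect_length(parents, 1)
  }
})

test_that("short-track filtering keeps only tracks of the minimum length", {
  tr <- do.call(rbind, lapply(1:4, function(i)
    data.frame(track_id = i, frame = 0:(i + 1), x = 0, y = 0)))
  # lengths 3,4,5,6
  kept <- filter_short_tracks(tr, link_params(min_track_len = 5))
  expect_equal(sort(unique(kept$track_id)), 3:4)
  expect_identical(filter_short_tracks(tr, link_params(min_track_len = 1)), tr)
  empty <- tr[0, ]
  expect_equal(nrow(filter_short_tracks(empty, link_params())), 0)
})

test_that("track editing splits, rejoins, and validates", {
  tr <- data.frame(track_id = 1L, frame = 0:9, x = 0:9, y = 0)
  sp <- edit_tracks(tr, data.frame(op = "split", track_id = 1, frame = 5,
                                   track_id2 = NA))
  expect_equal(sort(as.integer(table(sp$track_id))), c(5L, 5L))
  new_id <- setdiff(unique(sp$track_id), 1L)
  back <- edit_tracks(sp, data.frame(op = "join", track_id = 1,
                                     frame = NA, track_id2 = new_id))
  expect_equal(back$frame[back$track_id == 1], 0:9)
  expect_equal(back$x[back$track_id == 1], 0:9)

  # joining temporally overlapping tracks fails
  tr2 <- rbind(data.frame(track_id = 1L, frame = 0:5, x = 0, y = 0),
               data.frame(track_id = 2L, frame = 3:8, x = 1, y = 1))
  expect_error(edit_tracks(tr2, data.frame(op = "join", track_id = 1,
                                           frame = NA, track_id2 = 2)),
               "overlap")
  expect_error(edit_tracks(tr2, data.frame(op = "split", track_id = 9,
                                           frame = 2, track_id2 = NA)),
               "unknown")
})

test_that("tracking pipeline conserves detections into tracks", {
  det <- small_detections()
  tr <- join_segments(link_nearest_neighbor(det), link_params())
  expect_equal(nrow(tr), nrow(det))
  expect_true(all(tapply(tr$frame, tr$track_id, function(f) all(diff(f) >= 1))))
})
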