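box <- function(x, y, w, h) data.frame(x = x, y = y, w = w, h = h)

test_that("jaccard similarity: identity, disjoint, partial overlap, symmetry", {
  a <- box(0, 0, 10, 10)
  expect_equal(jaccard(a, a), 1.0)
  expect_equal(jaccard(a, box(50, 50, 5, 5)), 0.0)
  expect_equal(jaccard(a, box(5, 0, 10, 10)), 50 / 150)
  set.seed(2)
  for (i in 1:20) {
    b1 <- box(runif(1, 0, 20), runif(1, 0, 20), runif(1, 1, 15), runif(1, 1, 15))
    b2 <- box(runif(1, 0, 20), runif(1, 0, 20), runif(1, 1, 15), runif(1, 1, 15))
    j <- jaccard(b1, b2)
    expect_equal(j, jaccard(b2, b1))
    expect_true(j >= 0 && j <= 1)
  }
})

test_that("frame detection accuracy follows the matched-Jaccard formula", {
  g <- rbind(box(0, 0, 10, 10), box(30, 30, 10, 10))
  expect_equal(frame_detection_accuracy(g, g), 1.0)
  expect_equal(frame_detection_accuracy(g, g[1, ]), 1 / 1.5)
  expect_equal(frame_detection_accuracy(g, g[0, ]), 0.0)
  expect_equal(frame_detection_accuracy(g[0, ], g[0, ]), 1.0)
})

test_that("SFDA: identity, empty results, box conversion", {
  gt <- data.frame(gt_id = rep(1:2, each = 3), frame = rep(0:2, 2),
                   x = c(0, 1, 2, 30, 31, 32), y = 5, w = 10, h = 10)
  res <- gt; names(res)[1] <- "track_id"
  expect_equal(sfda(gt, res)$sfda, 1.0)
  expect_equal(sfda(gt, res[0, ])$sfda, 0.0)
  # circles to boxes: square of side 2r centered on the point
  pts <- data.frame(track_id = 1, frame = 0, x = 10, y = 20, radius = 5)
  b <- points_to_boxes(pts)
  expect_equal(c(b$x, b$y, b$w, b$h), c(5, 15, 10, 10))
})

test_that("track correspondence: identity, threshold rule, crossed scores", {
  gt <- data.frame(gt_id = rep(1:2, each = 5), frame = rep(0:4, 2),
                   x = c(seq(0, 8, 2), seq(40, 48, 2)), y = 5, w = 10, h = 10)
  res <- gt; names(res)[1] <- "track_id"
  corr <- track_correspondence(gt, res)
  expect_equal(nrow(corr$pairs), 2)
  expect_equal(corr$pairs$score, c(1, 1))
  expect_equal(corr$pairs$gt_id, corr$pairs$track_id)

  # every-frame Jaccard 0.5 with threshold 0.4 counts as 1
  shifted <- res
  shifted$x <- shifted$x + 10 / 3  # overlap 2/3 width -> J = (20/3)/(40/3) = 0.5
  corr2 <- track_correspondence(gt, shifted, jaccard_threshold = 0.4)
  expect_equal(corr2$pairs$score, c(1, 1), tolerance = 1e-9)
  corr2r <- track_correspondence(gt, shifted, jaccard_threshold = NULL)
  expect_equal(corr2r$pairs$score, c(0.5, 0.5), tolerance = 1e-9)

  # crossed similarity structure resolves to the optimal pairing
  S <- matrix(c(0.9, 0.3, 0.2, 0.8), 2, 2)  # rows gt, cols result
  mk_tracks <- function(offsets, id_col) {
    # one-frame tracks whose pairwise J is controlled by x offset
    do.call(rbind, lapply(seq_along(offsets), function(i) {
      d <- data.frame(id = i, frame = 0, x = offsets[i], y = 0, w = 10, h = 10)
      names(d)[1] <- id_col; d
    }))
  }
  # construct x offsets giving approximately the crossed Jaccards
  off_for_j <- function(j) 10 * (1 - j) / (1 + j)
  gt3 <- mk_tracks(c(0, 100), "gt_id")
  res3 <- rbind(
    data.frame(track_id = 1, frame = 0, x = off_for_j(0.9), y = 0, w = 10, h = 10),
    data.frame(track_id = 2, frame = 0, x = 100 + off_for_j(0.8), y = 0,
               w = 10, h = 10))
  corr3 <- track_correspondence(gt3, res3)
  expect_equal(corr3$pairs$track_id[corr3$pairs$gt_id == 1], 1)
  expect_equal(corr3$pairs$track_id[corr3$pairs$gt_id == 2], 2)
})

test_that("ATA: identity, split penalty, monotone thresholding", {
  gt <- data.frame(gt_id = rep(1:2, each = 10), frame = rep(0:9, 2),
                   x = c(seq(0, 18, 2), seq(60, 78, 2)), y = 5, w = 12, h = 12)
  res <- gt; names(res)[1] <- "track_id"
  expect_equal(ata(gt, res), 1.0)
  expect_equal(ata(gt, res[0, ]), 0.0)

  # each GT track split into two result pieces: denominator penalises
  split_res <- res
  split_res$track_id <- rep(c(1, 3, 2, 4), each = 5)
  a_split <- ata(gt, split_res)
  expect_lt(a_split, 1)
  expect_equal(a_split, (0.5 + 0.5) / 3, tolerance = 1e-9)

  # thresholded ATA never below raw ATA; lowering threshold never decreases it
  jit <- res; jit$x <- jit$x + 2.5
  expect_gte(ata(gt, jit, 0.4), ata(gt, jit, NULL))
  expect_gte(ata(gt, jit, 0.3), ata(gt, jit, 0.5))
  # swapping sides leaves the metrics unchanged
  gt_sw <- jit; names(gt_sw)[1] <- "gt_id"
  res_sw <- gt; names(res_sw)[1] <- "track_id"
  expect_equal(ata(gt, jit), ata(gt_sw, res_sw), tolerance = 1e-12)
  expect_equal(sfda(gt, jit)$sfda, sfda(gt_sw, res_sw)$sfda, tolerance = 1e-12)
})

test_that("Hungarian correspondence equals exhaustive search on small cases", {
  set.seed(14)
  for (rep in 1:8) {
    ng <- sample(2:4, 1); nr <- sample(2:4, 1)
    gt <- do.call(rbind, lapply(1:ng, function(i)
      data.frame(gt_id = i, frame = 0:4,
                 x = runif(1, 0, 60) + seq(0, 4), y = runif(1, 0, 60),
                 w = 10, h = 10)))
    res <- do.call(rbind, lapply(1:nr, function(i)
      data.frame(track_id = i, frame = 0:4,
                 x = runif(1, 0, 60) + seq(0, 4), y = runif(1, 0, 60),
                 w = 10, h = 10)))
    corr <- track_correspondence(gt, res)
    best <- exhaustive_matching(corr$scores)
    expect_equal(sum(corr$pairs$score), best$score, tolerance = 1e-9)
  }
})

test_that("feature-extraction evaluation reports exact and inflated errors", {
  gt <- data.frame(frame = rep(0:4, each = 3),
                   x = rep(c(10, 40, 70), 5), y = rep(c(10, 40, 70), 5),
                   footprint_area_um2 = rep(c(20, 30, 40), 5),
                   fluor1_mean = 0.5, fluor2_mean = 0.2, aspect = 1.5)
  obs <- data.frame(track_id = rep(1:3, 5), frame = rep(0:4, each = 3),
                    x = rep(c(10, 40, 70), 5), y = rep(c(10, 40, 70), 5),
                    contact_area_um2 = rep(c(20, 30, 40), 5),
                    mean_fluor1 = 0.5, mean_fluor2 = 0.2, aspect_ratio = 1.5)
  ev <- evaluate_feature_extraction(gt, obs)
  expect_true(all(ev$summary$median_abs_rel_error == 0))

  obs2 <- obs; obs2$contact_area_um2 <- obs2$contact_area_um2 * 1.10
  ev2 <- evaluate_feature_extraction(gt, obs2)
  expect_equal(ev2$summary$median_abs_rel_error[
    ev2$summary$feature == "contact_area_um2"], 0.10, tolerance = 1e-9)
})
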