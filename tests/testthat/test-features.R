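# render a disk (value `fg`) on a uniform background, with optional second
# touching disk, for local-segmentation geometry tests
disk_frame <- function(W = 81, cx = 40, cy = 40, r = 10, fg = 0.8, bg = 0.03,
                       extra = NULL, noise = 0) {
  m <- matrix(bg, W, W)
  xs <- matrix(0:(W - 1), W, W, byrow = TRUE)
  ys <- matrix(0:(W - 1), W, W)
  m[sqrt((xs - cx)^2 + (ys - cy)^2) < r] <- fg
  if (!is.null(extra))
    m[sqrt((xs - extra[1])^2 + (ys - extra[2])^2) < extra[3]] <- fg
  if (noise > 0) m <- m + matrix(rnorm(W * W, 0, noise), W, W)
  m
}

test_that("local box cropping records offsets and clips at borders", {
  fr <- matrix(runif(200 * 200), 200, 200)
  b <- crop_local_box(fr, c(50, 50), 20)
  expect_identical(dim(b$raster), c(41L, 41L))
  expect_equal(c(b$x0, b$y0), c(30L, 30L))
  # local pixel maps back to its global value
  expect_equal(b$raster[5, 7], fr[b$y0 + 5, b$x0 + 7])

  b2 <- crop_local_box(fr, c(5, 50), 20)
  expect_equal(b2$x0, 0L)
  expect_identical(ncol(b2$raster), 26L)  # columns 0..25
  expect_error(crop_local_box(fr, c(300, 50), 20), "outside")
})

test_that("intensity segmentation recovers disk area and rejects uniformity", {
  b <- crop_local_box(disk_frame(), c(40, 40), 40)
  seg <- segment_local_intensity(b, "fluor1", 18)
  expect_false(is.null(seg$mask))
  expect_lt(abs(sum(seg$mask) - pi * 100) / (pi * 100), 0.05)
  # outline lies on the mask boundary, in global coordinates
  expect_true(all(seg$outline$x >= 28 & seg$outline$x <= 52))

  # uniform box: no features
  bu <- crop_local_box(matrix(0.5, 81, 81), c(40, 40), 40)
  expect_null(segment_local_intensity(bu, "fluor1", 18)$mask)
  # near-uniform noise box: contrast guard rejects
  set.seed(1)
  bn <- crop_local_box(matrix(0.5 + rnorm(81 * 81, 0, 0.015), 81, 81),
                       c(40, 40), 40)
  expect_null(segment_local_intensity(bn, "reflection", 18)$mask)
})

test_that("touching cells are split and the central one returned", {
  fr <- disk_frame(extra = c(59, 40, 10))  # second disk touching at x ~ 50
  b <- crop_local_box(fr, c(40, 40), 40)
  seg <- segment_local_intensity(b, "fluor1", 18)
  expect_false(is.null(seg$mask))
  area <- sum(seg$mask)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.25)  # one disk, not the doublet
  # centroid of the returned region is near the box center
  idx <- which(seg$mask); nr <- nrow(seg$mask)
  cx <- mean((idx - 1) %/% nr) + b$x0
  expect_lt(abs(cx - 40), 5)
})

test_that("reflection polarity is dark-foreground", {
  fr <- disk_frame(fg = 0.2, bg = 0.5)  # dark footprint on brighter background
  b <- crop_local_box(fr, c(40, 40), 40)
  seg <- segment_local_intensity(b, "reflection", 18)
  expect_false(is.null(seg$mask))
  expect_lt(abs(sum(seg$mask) - pi * 100) / (pi * 100), 0.05)
})

# draw a cell the way the transmitted channel renders one: slightly dark
# elliptical body with a bright boundary-relief ring
render_cell <- function(W = 91, cx = 45, cy = 45, r = 10, aspect = 1, th = 0) {
  a <- r * sqrt(aspect); b <- r / sqrt(aspect)
  xs <- matrix(0:(W - 1), W, W, byrow = TRUE) - cx
  ys <- matrix(0:(W - 1), W, W) - cy
  xr <- xs * cos(th) + ys * sin(th); yr <- -xs * sin(th) + ys * cos(th)
  q <- sqrt((xr / a)^2 + (yr / b)^2)
  0.5 - 0.05 * (q < 1) + 0.22 * exp(-(((q - 1) * r) / 1.3)^2)
}

test_that("transmitted-light segmentation recovers a rendered cell", {
  img <- render_cell()
  b <- crop_local_box(img, c(45, 45), 45)
  seg <- segment_local_transmitted(b, detection_params(), 18)
  expect_false(is.null(seg$mask))
  expect_lt(abs(sum(seg$mask) - pi * 100) / (pi * 100), 0.15)
  # a 2:1 ellipse is recovered as elongated
  img2 <- render_cell(aspect = 2, th = 0.5)
  b2 <- crop_local_box(img2, c(45, 45), 45)
  seg2 <- segment_local_transmitted(b2, detection_params(), 18)
  ar <- compute_aspect_ratio(seg2$mask)
  expect_gt(ar, 1.5)
  # empty box
  be <- crop_local_box(matrix(0.5, 41, 41), c(20, 20), 20)
  expect_null(segment_local_transmitted(be, detection_params(), 18)$mask)
})

test_that("contact features follow the area rule and units", {
  cal <- calibration(0.5, 30)
  mask <- matrix(FALSE, 30, 30); mask[1:20, 1:20] <- TRUE  # 400 px
  cf <- compute_contact_features(mask, cal, min_area_um2 = 3)
  expect_equal(cf$contact_area_um2, 100)
  expect_true(cf$attached)
  cf0 <- compute_contact_features(NULL, cal)
  expect_equal(cf0$contact_area_um2, 0)
  expect_false(cf0$attached)
  # sub-threshold footprints are treated as noise
  small <- matrix(FALSE, 30, 30); small[1:3, 1] <- TRUE
  cfs <- compute_contact_features(small, cal, min_area_um2 = 3)
  expect_false(cfs$attached)
  expect_equal(cfs$contact_area_um2, 0)
})

test_that("a footprint in part of a track marks the whole track attached", {
  obs <- data.frame(track_id = rep(1:2, each = 50), frame = rep(0:49, 2),
                    x = 0, y = 0,
                    contact_area_um2 = 0, attached = FALSE)
  obs$attached[obs$track_id == 1][c(10, 25, 40)] <- TRUE  # 3 of 50 frames
  obs$contact_area_um2[obs$attached] <- 12
  tracks <- data.frame(track_id = rep(1:2, each = 50), frame = rep(0:49, 2),
                       x = rep(seq(0, 49), 2), y = 0)
  s <- summarize_tracks(tracks, calibration(1, 60), obs)
  expect_true(s$attached[s$track_id == 1])
  expect_false(s$attached[s$track_id == 2])
})

test_that("mean intensity under masks is exact", {
  r <- matrix(100, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(compute_mean_intensity(mask, r), 100)
  r2 <- rbind(matrix(100, 5, 10), matrix(50, 5, 10))
  expect_equal(compute_mean_intensity(mask, r2), 75)
  expect_true(is.na(compute_mean_intensity(NULL, r)))
})

test_that("aspect ratio from moment ellipse: circle, ellipse, degenerate", {
  xs <- matrix(0:80, 81, 81, byrow = TRUE); ys <- matrix(0:80, 81, 81)
  circle <- sqrt((xs - 40)^2 + (ys - 40)^2) < 15
  expect_lt(abs(compute_aspect_ratio(circle) - 1), 0.05)
  ellipse <- sqrt(((xs - 40) / 24)^2 + ((ys - 40) / 12)^2) < 1
  expect_lt(abs(compute_aspect_ratio(ellipse) - 2), 0.15)
  line <- matrix(FALSE, 30, 30); line[15, 5:25] <- TRUE
  expect_true(is.na(compute_aspect_ratio(line)))
  tiny <- matrix(FALSE, 10, 10); tiny[1, 1:3] <- TRUE
  expect_true(is.na(compute_aspect_ratio(tiny)))
})

test_that("cell-type assignment follows the dye ratio thresholds", {
  obs <- data.frame(track_id = rep(1:3, each = 4),
                    mean_fluor1 = c(rep(0.8, 4), rep(0.1, 4), rep(0.3, 4)),
                    mean_fluor2 = c(rep(0.1, 4), rep(0.8, 4), rep(0.3, 4)))
  lab <- assign_cell_types(obs, ratio_high = 2, ratio_low = 0.5)
  expect_equal(lab$label, c("typeA", "typeB", "unassigned"))
})

test_that("cell types on a generator movie match programmed labels", {
  mv <- small_movie()
  tr <- small_tracks()
  fx <- extract_features(mv$channels, tr, small_cal(),
                         which_channels = c("fluor1", "fluor2"))
  lab <- assign_cell_types(fx$observations)
  first <- tr[!duplicated(tr$track_id), ]
  f0 <- mv$positions[mv$positions$frame == 0, ]
  cid <- vapply(seq_len(nrow(first)), function(i)
    f0$cell_id[which.min((f0$x - first$x[i])^2 + (f0$y - first$y[i])^2)],
    numeric(1))
  truth <- mv$cells$type[match(cid, mv$cells$cell_id)]
  got <- lab$label[match(first$track_id, lab$track_id)]
  expect_gte(mean(got == truth), 0.98)
})

test_that("local segmentation never selects a region beyond the center gate", {
  # bright disk far from center only
  fr <- disk_frame(cx = 70, cy = 70, r = 8)
  b <- crop_local_box(fr, c(30, 30), 40)
  expect_null(segment_local_intensity(b, "fluor1", 15)$mask)
})
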