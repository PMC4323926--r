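# Cell detection: Canny edges followed by a gradient-directed circular Hough
# transform over a radius range; accumulator maxima are cell centroids.

#' Detection parameters
#'
#' Defaults are stated at the reference scale where cell radii fall in
#' roughly 8--15 px after rescaling by `scale_factor`; images of larger or
#' smaller cells should set `scale_factor` so that rescaled cells match this
#' range rather than changing the radius range.
#'
#' @param canny_sigma Gaussian pre-smoothing scale, px.
#' @param canny_low,canny_high Hysteresis thresholds on the normalised
#'   gradient magnitude, `0 <= low < high < 1`.
#' @param radius_min,radius_max Voting radius range, px (at the rescaled
#'   resolution).
#' @param accumulator_sigma Gaussian smoothing of the vote accumulator, px.
#' @param vote_fraction Accept maxima with votes at or above this fraction of
#'   the global accumulator maximum, in `(0, 1]`.
#' @param maxima_min_separation Suppression radius between accepted maxima,
#'   px; allows one peak per cell even for imperfectly circular cells.
#' @param scale_factor Resampling factor applied before detection; reported
#'   centroids are mapped back to original coordinates.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(canny_sigma = 2, canny_low = 0.1, canny_high = 0.25,
                             radius_min = 6, radius_max = 18,
                             accumulator_sigma = 2, vote_fraction = 0.35,
                             maxima_min_separation = radius_min,
                             scale_factor = 1) {
  stopifnot(canny_sigma > 0, canny_low >= 0, canny_high < 1, canny_low < canny_high,
            radius_min >= 1, radius_max > radius_min, accumulator_sigma >= 0,
            vote_fraction > 0, vote_fraction <= 1,
            maxima_min_separation > 0, scale_factor > 0)
  structure(list(canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high, radius_min = radius_min,
                 radius_max = radius_max, accumulator_sigma = accumulator_sigma,
                 vote_fraction = vote_fraction,
                 maxima_min_separation = maxima_min_separation,
                 scale_factor = scale_factor),
            class = "detection_params")
}

#' Circular Hough transform of an edge map
#'
#' Every edge pixel casts votes along both senses of its gradient direction
#' at offsets `radius_min .. radius_max`, so circle centres accumulate votes
#' from their whole boundary even when only a partial, non-contiguous set of
#' edges is present. The summed accumulator is smoothed with
#' `accumulator_sigma`.
#'
#' @param edges Logical matrix from [compute_edge_map()].
#' @param gradient List with `gx`, `gy` matrices (same shape); taken from the
#'   `"gradient"` attribute of `edges` if `NULL`.
#' @param params A [detection_params()].
#' @return List: `accumulator` (smoothed vote sum over radii),
#'   `radius_votes` (matrix `n_radii` x pixels kept internally for radius
#'   estimation, as a 3D array `[row, col, radius]` of raw votes), `radii`
#'   (the voting radii).
#' @export
circular_hough <- function(edges, gradient = NULL, params = detection_params()) {
  if (is.null(gradient)) gradient <- attr(edges, "gradient")
  e <- as.matrix(edges)
  storage.mode(e) <- "logical"
  nr <- nrow(e); nc <- ncol(e)
  radii <- seq(ceiling(params$radius_min), floor(params$radius_max))
  acc3 <- array(0L, dim = c(nr, nc, length(radii)))
  idx <- which(e)
  if (length(idx)) {
    if (is.null(gradient) || !identical(dim(gradient$gx), dim(e)))
      stop("edges and gradient must share shape")
    ey <- ((idx - 1L) %% nr) + 1L      # row (1-based)
    ex <- ((idx - 1L) %/% nr) + 1L     # col (1-based)
    gx <- gradient$gx[idx]; gy <- gradient$gy[idx]
    mag <- sqrt(gx^2 + gy^2)
    ok <- mag > 0
    ex <- ex[ok]; ey <- ey[ok]
    ux <- gx[ok] / mag[ok]; uy <- gy[ok] / mag[ok]
    npix <- nr * nc
    for (k in seq_along(radii)) {
      r <- radii[k]
      slice <- acc3[, , k]
      for (s in c(-1, 1)) {
        cx <- as.integer(round(ex + s * r * ux))
        cy <- as.integer(round(ey + s * r * uy))
        inb <- cx >= 1L & cx <= nc & cy >= 1L & cy <= nr
        if (!any(inb)) next
        lin <- (cx[inb] - 1L) * nr + cy[inb]
        tab <- tabulate(lin, nbins = npix)
        slice <- slice + tab
      }
      acc3[, , k] <- slice
    }
  }
  acc <- rowSums(acc3, dims = 2L)
  if (params$accumulator_sigma > 0 && max(acc) > 0)
    acc <- as.matrix(EBImage::gblur(EBImage::Image(acc),
                                    sigma = params$accumulator_sigma,
                                    boundary = "replicate"))
  list(accumulator = acc, radius_votes = acc3, radii = radii)
}

# is each candidate pixel a local maximum in its 3x3 neighbourhood?
.is_local_max <- function(acc, rows, cols) {
  nr <- nrow(acc); nc <- ncol(acc)
  ok <- rep(TRUE, length(rows))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rr <- pmin(pmax(rows + dy, 1L), nr)
    cc <- pmin(pmax(cols + dx, 1L), nc)
    ok <- ok & acc[cbind(rows, cols)] >= acc[cbind(rr, cc)]
  }
  ok
}

#' Select cell centroids from a Hough accumulator
#'
#' Local maxima with votes at or above `vote_fraction` times the global
#' maximum are accepted greedily in descending vote order (ties broken in
#' raster order); any candidate within `maxima_min_separation` pixels of an
#' already accepted centroid is suppressed. The per-centroid radius estimate
#' is the radius gathering the most votes in a 3x3 neighbourhood of the peak.
#'
#' @param hough Result of [circular_hough()], or a plain accumulator matrix.
#' @param params A [detection_params()].
#' @param frame 0-based frame index recorded in the output.
#' @return data.frame with columns `frame`, `x`, `y` (0-based px), `radius`,
#'   `score`; zero rows when the accumulator is all zero.
#' @export
select_centroids <- function(hough, params = detection_params(), frame = 0L) {
  if (is.matrix(hough)) hough <- list(accumulator = hough, radius_votes = NULL,
                                      radii = NULL)
  acc <- hough$accumulator
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      radius = numeric(), score = numeric())
  mx <- max(acc)
  if (mx <= 0) return(empty)
  thr <- params$vote_fraction * mx
  cand <- which(acc >= thr)
  nr <- nrow(acc)
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  lm <- .is_local_max(acc, rows, cols)
  cand <- cand[lm]; rows <- rows[lm]; cols <- cols[lm]
  if (!length(cand)) return(empty)
  score <- acc[cand]
  ord <- order(-score, cand)  # descending votes, raster order on ties
  rows <- rows[ord]; cols <- cols[ord]; score <- score[ord]
  keep <- logical(length(rows))
  acc_r <- numeric(0); acc_c <- numeric(0)
  sep2 <- params$maxima_min_separation^2
  for (i in seq_along(rows)) {
    if (length(acc_r) &&
        any((acc_r - rows[i])^2 + (acc_c - cols[i])^2 < sep2)) next
    keep[i] <- TRUE
    acc_r <- c(acc_r, rows[i]); acc_c <- c(acc_c, cols[i])
  }
  rows <- rows[keep]; cols <- cols[keep]; score <- score[keep]
  radius <- rep(mean(c(params$radius_min, params$radius_max)), length(rows))
  if (!is.null(hough$radius_votes)) {
    av <- hough$radius_votes
    ncm <- ncol(acc)
    for (i in seq_along(rows)) {
      rr <- max(1L, rows[i] - 1L):min(nr, rows[i] + 1L)
      cc <- max(1L, cols[i] - 1L):min(ncm, cols[i] + 1L)
      per_r <- apply(av[rr, cc, , drop = FALSE], 3L, sum)
      radius[i] <- hough$radii[which.max(per_r)]
    }
  }
  data.frame(frame = as.integer(frame), x = cols - 1, y = rows - 1,
             radius = radius, score = score)
}

# resample a frame by scale_factor using bilinear interpolation
.rescale_frame <- function(frame, scale_factor) {
  if (scale_factor == 1) return(as.matrix(frame))
  d <- dim(frame)
  as.matrix(EBImage::resize(EBImage::Image(as.matrix(frame)),
                            w = max(2L, round(d[1] * scale_factor)),
                            h = max(2L, round(d[2] * scale_factor))))
}

#' Detect cells in every frame of a transmitted-light series
#'
#' Per frame: resample by `scale_factor`, extract Canny edges, vote in the
#' circular Hough accumulator, select centroids, and map the centroids (and
#' radii) back to original image coordinates.
#'
#' @param series An [image_series()] (transmitted channel).
#' @param params A [detection_params()].
#' @return data.frame of detections across all frames: `frame`, `x`, `y`
#'   (0-based px, original scale), `radius` (px, original scale), `score`.
#' @export
detect_cells <- function(series, params = detection_params()) {
  frames <- if (inherits(series, "image_series")) series$frames else series
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- .rescale_frame(frames[[i]], params$scale_factor)
    edges <- compute_edge_map(fr, params)
    h <- circular_hough(edges, params = params)
    det <- select_centroids(h, params, frame = i - 1L)
    if (nrow(det) && params$scale_factor != 1) {
      det$x <- det$x / params$scale_factor
      det$y <- det$y / params$scale_factor
      det$radius <- det$radius / params$scale_factor
      d <- dim(as.matrix(frames[[i]]))
      det$x <- pmin(det$x, d[2] - 1)
      det$y <- pmin(det$y, d[1] - 1)
    }
    out[[i]] <- det
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
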