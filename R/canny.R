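# Canny edge extraction. EBImage supplies Gaussian smoothing and connected
# components; gradient, non-maximum suppression and hysteresis are done here.

# shift a matrix by (dy, dx), replicating the border
.shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Image gradient of a smoothed frame
#'
#' Sobel gradients after Gaussian pre-smoothing. Returned components follow
#' the package coordinate convention: `gx` is the derivative along columns
#' (x), `gy` along rows (y).
#'
#' @param frame Numeric matrix.
#' @param sigma Gaussian smoothing scale in pixels (0 disables smoothing).
#' @return List with matrices `gx`, `gy`, `mag` (gradient magnitude).
#' @export
image_gradient <- function(frame, sigma = 2) {
  m <- as.matrix(frame)
  if (sigma > 0)
    m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                                  boundary = "replicate"))
  # Sobel via shifted sums; x = column direction, y = row direction
  gx <- (.shift(m, 0, -1) - .shift(m, 0, 1)) * 2 +
        (.shift(m, -1, -1) - .shift(m, -1, 1)) +
        (.shift(m, 1, -1) - .shift(m, 1, 1))
  gy <- (.shift(m, -1, 0) - .shift(m, 1, 0)) * 2 +
        (.shift(m, -1, -1) - .shift(m, 1, -1)) +
        (.shift(m, -1, 1) - .shift(m, 1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Binary edge map of one frame (Canny)
#'
#' Gaussian smoothing, Sobel gradient, non-maximum suppression along the
#' quantised gradient direction and hysteresis thresholding. Thresholds are
#' expressed as fractions of the maximum gradient magnitude in the frame, so
#' the edge map is invariant under affine intensity changes.
#'
#' @param frame Numeric matrix.
#' @param params A [detection_params()] (uses `canny_sigma`, `canny_low`,
#'   `canny_high`).
#' @return Logical matrix of edge pixels, same shape as `frame`. The gradient
#'   used is attached as attribute `"gradient"` for reuse by the Hough stage.
#' @export
compute_edge_map <- function(frame, params = detection_params()) {
  g <- image_gradient(frame, params$canny_sigma)
  mag <- g$mag
  mx <- max(mag)
  # guard against pure numerical noise from the FFT convolution on
  # (near-)constant frames: such gradients are not edges
  if (mx <= 1e-9 || !is.finite(mx)) {
    out <- matrix(FALSE, nrow(mag), ncol(mag))
    attr(out, "gradient") <- g
    return(out)
  }
  nmag <- mag / mx

  # non-maximum suppression: quantise direction into 4 sectors
  ang <- atan2(g$gy, g$gx)                # radians, y = rows
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: x, 1: diag, 2: y, 3: anti-diag
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2; s3 <- sector == 3
  sh <- function(dy, dx) .shift(mag, dy, dx)
  n1[s0] <- sh(0, 1)[s0];   n2[s0] <- sh(0, -1)[s0]
  n1[s1] <- sh(1, 1)[s1];   n2[s1] <- sh(-1, -1)[s1]
  n1[s2] <- sh(1, 0)[s2];   n2[s2] <- sh(-1, 0)[s2]
  n1[s3] <- sh(1, -1)[s3];  n2[s3] <- sh(-1, 1)[s3]
  is_max <- mag >= n1 & mag >= n2

  weak <- is_max & (nmag >= params$canny_low)
  strong <- is_max & (nmag >= params$canny_high)
  if (!any(strong)) {
    out <- matrix(FALSE, nrow(mag), ncol(mag))
    attr(out, "gradient") <- g
    return(out)
  }
  # hysteresis: keep weak components that contain at least one strong pixel
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  lab <- as.matrix(lab)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  out <- lab %in% keep
  dim(out) <- dim(mag)
  attr(out, "gradient") <- g
  out
}
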