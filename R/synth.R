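# Synthetic multi-channel T-cell motility movies with exhaustive ground
# truth: persistent random walks with inverse speed-turn coupling, rendered
# as transmitted-light edge contrast, dark irregular reflection footprints
# for the attached subset, and per-type fluorescent disks.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic movie generator
#'
#' Defaults emulate chemokine-driven T-cell chemokinesis as imaged in the
#' motivating experiments: a 225 um square field (512 px at 0.439 um/px),
#' 33.3 s between frames, two vital-dye-labelled populations mixed in equal
#' ratio with population mean speeds of 5 and 10 um/min, and about half of
#' the cells attached to the substratum with contact footprints of a few tens
#' of square microns.
#'
#' @param n_cells Number of cells in the field.
#' @param field_size_px Square field edge, px.
#' @param n_frames Number of frames.
#' @param pixel_size_um,frame_interval_s Calibration.
#' @param populations data.frame with columns `type`, `fraction`,
#'   `speed_mean_um_min`, `fluor1`, `fluor2` (dye intensities in `[0, 1]`).
#' @param speed_sdlog Between-cell log-normal spread of base speed.
#' @param step_sdlog Within-track log-normal spread of per-step speed.
#' @param turn_sd_deg Baseline SD of the wrapped-normal heading increment,
#'   degrees, at a step speed equal to the cell's population mean.
#' @param speed_turn_coupling Exponent coupling turn SD to relative step
#'   speed (`sd = turn_sd_deg * exp(coupling * v/v_pop)`); negative values
#'   enforce the inverse speed-turn relation of amoeboid motility.
#' @param attach_fraction Fraction of cells with a reflection footprint.
#' @param footprint_area_um2_mean Mean contact footprint area, um^2.
#' @param cell_radius_um_mean,cell_radius_um_sd Cell radius distribution, um.
#' @param aspect_sd Half-normal spread of per-cell aspect ratio above 1.
#' @param noise_sd Gaussian rendering noise SD (intensity units).
#' @param min_separation_px Minimum allowed inter-cell distance (soft
#'   repulsion); the default keeps cells well separated, set it lower to
#'   exercise crowding/ambiguity code paths.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   movies and truth.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_cells = 30, field_size_px = 512, n_frames = 50,
                         pixel_size_um = 0.439, frame_interval_s = 33.3,
                         populations = data.frame(
                           type = c("typeA", "typeB"),
                           fraction = c(0.5, 0.5),
                           speed_mean_um_min = c(5, 10),
                           fluor1 = c(0.80, 0.12),
                           fluor2 = c(0.12, 0.80)),
                         speed_sdlog = 0.25, step_sdlog = 0.35,
                         turn_sd_deg = 70, speed_turn_coupling = -1.2,
                         attach_fraction = 0.5, footprint_area_um2_mean = 20,
                         cell_radius_um_mean = 4.4, cell_radius_um_sd = 0.5,
                         aspect_sd = 0.25, noise_sd = 0.015,
                         min_separation_px = 36, seed = 1L) {
  stopifnot(n_cells >= 0, field_size_px >= 64, n_frames >= 1,
            pixel_size_um > 0, frame_interval_s > 0,
            all(populations$fraction >= 0), abs(sum(populations$fraction) - 1) < 1e-8,
            all(populations$speed_mean_um_min > 0),
            speed_turn_coupling <= 0, attach_fraction >= 0, attach_fraction <= 1,
            footprint_area_um2_mean > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "synth_params")
}

#' Simulate ground-truth cell tracks (positions only)
#'
#' Persistent random walk: each cell has a log-normal base speed around its
#' population mean; per step the speed varies log-normally and the heading
#' turns by a normal increment whose SD shrinks exponentially with relative
#' speed (`speed_turn_coupling < 0`), reproducing the alternation between
#' fast straight runs and slow turning. Boundaries are reflective and a soft
#' pairwise repulsion keeps cells at least `min_separation_px` apart.
#'
#' @param params A [synth_params()].
#' @return List of class `synth_truth` with elements `cells` (per-cell
#'   table: type, base speed, radius, aspect, attachment, dye means),
#'   `positions` (per cell-frame table: 0-based `frame`, continuous `x`,
#'   `y` px, orientation, realised step speed in um/min, footprint target
#'   area) and `params`.
#' @export
simulate_tracks <- function(params = synth_params()) {
  p <- params
  .with_seed(p$seed, {
    n <- p$n_cells
    W <- p$field_size_px
    margin <- 24
    pop <- p$populations
    type_idx <- if (n > 0) sample(rep(seq_len(nrow(pop)),
                                      times = round(pop$fraction * n) |>
                                        (\(k) {k[1] <- n - sum(k[-1]); k})()))
                else integer()
    cells <- data.frame(
      cell_id = seq_len(n),
      type = pop$type[type_idx],
      base_speed_um_min = rlnorm(n, log(pop$speed_mean_um_min[type_idx]) -
                                   p$speed_sdlog^2 / 2, p$speed_sdlog),
      radius_px = pmax(6, rnorm(n, p$cell_radius_um_mean, p$cell_radius_um_sd) /
                         p$pixel_size_um),
      aspect = pmin(2, 1 + abs(rnorm(n, 0, p$aspect_sd))),
      attached = rep(FALSE, n),
      fluor1 = pop$fluor1[type_idx],
      fluor2 = pop$fluor2[type_idx],
      footprint_mean_um2 = rlnorm(n, log(p$footprint_area_um2_mean) - 0.3^2 / 2, 0.3)
    )
    if (n > 0) {
      n_att <- round(p$attach_fraction * n)
      cells$attached[sample.int(n, n_att)] <- TRUE
    }

    # initial positions: rejection sampling for min separation
    pos <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      for (try in 1:2000) {
        cand <- runif(2, margin, W - margin)
        if (i == 1 ||
            min(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                              matrix(cand, i - 1, 2, byrow = TRUE))^2))) >=
            p$min_separation_px) {
          pos[i, ] <- cand
          break
        }
        if (try == 2000) stop("cannot place ", n, " cells at min separation ",
                              p$min_separation_px)
      }
    }
    heading <- runif(n, 0, 2 * pi)
    step_scale <- p$frame_interval_s / 60 / p$pixel_size_um  # um/min -> px/frame
    pop_mean <- pop$speed_mean_um_min[type_idx]

    rows <- vector("list", p$n_frames)
    speed_now <- cells$base_speed_um_min
    for (t in seq_len(p$n_frames)) {
      rows[[t]] <- data.frame(
        cell_id = cells$cell_id, frame = rep(t - 1L, n),
        x = pos[, 1], y = pos[, 2],
        orientation = heading,
        speed_um_min = speed_now,
        footprint_target_um2 = ifelse(cells$attached,
                                      cells$footprint_mean_um2 *
                                        rlnorm(n, -0.15^2 / 2, 0.15), 0))
      if (t == p$n_frames) break
      v <- cells$base_speed_um_min * rlnorm(n, -p$step_sdlog^2 / 2, p$step_sdlog)
      turn_sd <- p$turn_sd_deg * exp(p$speed_turn_coupling * v / pop_mean)
      heading <- heading + rnorm(n, 0, turn_sd * pi / 180)
      step <- v * step_scale
      # reflective boundaries: reflect the heading and retake the full step
      # so the realised chord keeps the programmed length (folding the
      # position would systematically shorten fast cells' displacements)
      prop <- pos + cbind(step * cos(heading), step * sin(heading))
      out_x <- prop[, 1] < margin | prop[, 1] > W - margin
      heading[out_x] <- pi - heading[out_x]
      out_y <- (pos[, 2] + step * sin(heading)) < margin |
               (pos[, 2] + step * sin(heading)) > W - margin
      heading[out_y] <- -heading[out_y]
      pos <- pos + cbind(step * cos(heading), step * sin(heading))
      pos[, 1] <- pmin(pmax(pos[, 1], margin), W - margin)
      pos[, 2] <- pmin(pmax(pos[, 2], margin), W - margin)
      # soft repulsion keeps cells at the stated separation so that
      # identities stay unambiguous at the default density
      if (n > 1) for (pass in 1:3) {
        dmat <- as.matrix(dist(pos))
        diag(dmat) <- Inf
        close <- which(dmat < p$min_separation_px, arr.ind = TRUE)
        close <- close[close[, 1] < close[, 2], , drop = FALSE]
        if (!nrow(close)) break
        for (k in seq_len(nrow(close))) {
          i <- close[k, 1]; j <- close[k, 2]
          dvec <- pos[j, ] - pos[i, ]
          d0 <- sqrt(sum(dvec^2))
          u <- if (d0 > 1e-6) dvec / d0 else c(1, 0)
          push <- (p$min_separation_px - d0) / 2 + 0.5
          pos[i, ] <- pmin(pmax(pos[i, ] - u * push, margin), W - margin)
          pos[j, ] <- pmin(pmax(pos[j, ] + u * push, margin), W - margin)
        }
      }
      speed_now <- v
    }
    positions <- do.call(rbind, rows)
    positions <- positions[order(positions$cell_id, positions$frame), ]
    rownames(positions) <- NULL
    structure(list(cells = cells, positions = positions, params = p),
              class = "synth_truth")
  })
}

# half-extents along image axes of a rotated ellipse with semi-axes a >= b
.ellipse_extents <- function(a, b, theta) {
  cbind(sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
        sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

# local pixel window around (cx, cy) with half-extent e, clipped to the field
.window <- function(cx, cy, e, W) {
  x0 <- max(0L, floor(cx - e)); x1 <- min(W - 1L, ceiling(cx + e))
  y0 <- max(0L, floor(cy - e)); y1 <- min(W - 1L, ceiling(cy + e))
  list(xs = x0:x1, ys = y0:y1)
}

#' Render a simulated movie into per-channel image series
#'
#' Transmitted light: mid-gray background, slightly darker elliptical cell
#' bodies and a bright difference-of-Gaussians style ring at the cell
#' boundary (the detector consumes edges, not shading physics). Reflection:
#' slowly drifting background with dark irregular contact footprints under
#' attached cells. Fluorescence: per-type disk intensities. Gaussian noise is
#' added everywhere and intensities are quantised to the 16-bit grid so that
#' TIFF round-trips are pixel-identical.
#'
#' @param truth A `synth_truth` from [simulate_tracks()].
#' @param params A [synth_params()] (defaults to `truth$params`).
#' @return List with `channels` (named list of [image_series()]) and
#'   `features` (per cell-frame ground-truth feature table: bounding box,
#'   rendered footprint area, rendered mean dye intensities under the true
#'   mask).
#' @export
render_movie <- function(truth, params = truth$params) {
  p <- params
  W <- p$field_size_px
  nf <- p$n_frames
  cells <- truth$cells
  pos <- truth$positions
  .with_seed(p$seed + 104729L, {
    ch <- list(transmitted = vector("list", nf), reflection = vector("list", nf),
               fluor1 = vector("list", nf), fluor2 = vector("list", nf))
    feat <- vector("list", nf)
    # irregular footprint shape phases, fixed per cell
    ph1 <- runif(nrow(cells), 0, 2 * pi); ph2 <- runif(nrow(cells), 0, 2 * pi)
    for (t in seq_len(nf)) {
      tm <- matrix(0.5, W, W)
      xg <- matrix(0:(W - 1), W, W, byrow = TRUE) / W
      yg <- matrix(0:(W - 1), W, W) / W
      rf <- 0.5 + 0.05 * sin(2 * pi * (xg + t / max(nf, 20))) *
                   cos(2 * pi * (yg - 0.5 * t / max(nf, 20)))
      f1 <- matrix(0.03, W, W); f2 <- matrix(0.03, W, W)
      sub <- pos[pos$frame == t - 1L, ]
      sub <- sub[order(sub$cell_id), ]
      frows <- vector("list", nrow(sub))
      for (i in seq_len(nrow(sub))) {
        ci <- match(sub$cell_id[i], cells$cell_id)
        rad <- cells$radius_px[ci]; asp <- cells$aspect[ci]
        a <- rad * sqrt(asp); b <- rad / sqrt(asp)
        th <- sub$orientation[i]
        cx <- sub$x[i]; cy <- sub$y[i]
        ext <- .ellipse_extents(a, b, th)
        win <- .window(cx, cy, max(a, rad) + 5, W)
        dx <- outer(rep(1, length(win$ys)), win$xs - cx)
        dy <- outer(win$ys - cy, rep(1, length(win$xs)))
        xr <- dx * cos(th) + dy * sin(th)
        yr <- -dx * sin(th) + dy * cos(th)
        q <- sqrt((xr / a)^2 + (yr / b)^2)
        ridx <- win$ys + 1L; cidx <- win$xs + 1L
        # transmitted: dark body + bright boundary ring
        body <- q < 1
        ring <- exp(-(((q - 1) * rad) / 1.3)^2)
        tm[ridx, cidx] <- tm[ridx, cidx] - 0.05 * body + 0.22 * ring
        # fluorescence: disk at the unpolarised radius
        disk_win <- .window(cx, cy, rad + 2, W)
        ddx <- outer(rep(1, length(disk_win$ys)), disk_win$xs - cx)
        ddy <- outer(disk_win$ys - cy, rep(1, length(disk_win$xs)))
        disk <- sqrt(ddx^2 + ddy^2) < rad
        dri <- disk_win$ys + 1L; dci <- disk_win$xs + 1L
        f1[dri, dci][disk] <- cells$fluor1[ci]
        f2[dri, dci][disk] <- cells$fluor2[ci]
        # reflection footprint: irregular dark blob of the target area
        area_px_target <- sub$footprint_target_um2[i] / p$pixel_size_um^2
        area_px <- 0L
        if (cells$attached[ci] && area_px_target >= 1) {
          r0 <- sqrt(area_px_target / (pi * (1 + (0.25^2 + 0.15^2) / 2)))
          bw <- .window(cx, cy, r0 * 1.6 + 3, W)
          bdx <- outer(rep(1, length(bw$ys)), bw$xs - cx)
          bdy <- outer(bw$ys - cy, rep(1, length(bw$xs)))
          brr <- sqrt(bdx^2 + bdy^2)
          phi <- atan2(bdy, bdx)
          rphi <- r0 * (1 + 0.25 * sin(3 * phi + ph1[ci]) +
                          0.15 * sin(5 * phi + ph2[ci]))
          blob <- brr < rphi
          area_px <- sum(blob)
          rf[bw$ys + 1L, bw$xs + 1L][blob] <- 0.22
        }
        frows[[i]] <- data.frame(
          cell_id = sub$cell_id[i], frame = t - 1L, x = cx, y = cy,
          box_x = cx - ext[1], box_y = cy - ext[2],
          box_w = 2 * ext[1], box_h = 2 * ext[2],
          radius_px = rad, aspect = asp,
          attached = cells$attached[ci],
          footprint_area_px = area_px,
          footprint_area_um2 = area_px * p$pixel_size_um^2,
          fluor1_true = cells$fluor1[ci], fluor2_true = cells$fluor2[ci],
          type = cells$type[ci])
      }
      quant <- function(m) {
        m <- m + matrix(rnorm(W * W, 0, p$noise_sd), W, W)
        round(pmin(pmax(m, 0), 1) * 65535) / 65535
      }
      tm <- quant(tm); rf <- quant(rf); f1 <- quant(f1); f2 <- quant(f2)
      fr <- do.call(rbind, frows)
      # measured dye means under the true disk mask (post-noise ground truth)
      if (!is.null(fr) && nrow(fr)) {
        fr$fluor1_mean <- NA_real_; fr$fluor2_mean <- NA_real_
        for (i in seq_len(nrow(fr))) {
          dw <- .window(fr$x[i], fr$y[i], fr$radius_px[i] + 2, W)
          ddx <- outer(rep(1, length(dw$ys)), dw$xs - fr$x[i])
          ddy <- outer(dw$ys - fr$y[i], rep(1, length(dw$xs)))
          disk <- sqrt(ddx^2 + ddy^2) < fr$radius_px[i]
          fr$fluor1_mean[i] <- mean(f1[dw$ys + 1L, dw$xs + 1L][disk])
          fr$fluor2_mean[i] <- mean(f2[dw$ys + 1L, dw$xs + 1L][disk])
        }
      }
      feat[[t]] <- fr
      ch$transmitted[[t]] <- tm; ch$reflection[[t]] <- rf
      ch$fluor1[[t]] <- f1; ch$fluor2[[t]] <- f2
    }
    channels <- lapply(names(ch), function(role)
      image_series(ch[[role]], role, p$pixel_size_um, p$frame_interval_s))
    names(channels) <- names(ch)
    features <- do.call(rbind, feat)
    if (!is.null(features)) {
      features <- features[order(features$cell_id, features$frame), ]
      rownames(features) <- NULL
    }
    list(channels = channels, features = features)
  })
}

#' Generate a complete synthetic movie with ground truth
#'
#' Convenience wrapper: [simulate_tracks()] then [render_movie()].
#'
#' @param params A [synth_params()].
#' @return A `synth_truth` list with `cells`, `positions`, `features`,
#'   `channels` and `params`.
#' @export
synth_movie <- function(params = synth_params()) {
  truth <- simulate_tracks(params)
  rend <- render_movie(truth, params)
  truth$channels <- rend$channels
  truth$features <- rend$features
  truth
}

#' Ground-truth bounding boxes of a synthetic movie
#'
#' @param truth A `synth_truth` with rendered `features`.
#' @return data.frame `gt_id`, `frame`, `x`, `y`, `w`, `h` as produced by
#'   [read_viper_ground_truth()].
#' @export
truth_boxes <- function(truth) {
  f <- truth$features
  data.frame(gt_id = f$cell_id, frame = f$frame,
             x = f$box_x, y = f$box_y, w = f$box_w, h = f$box_h)
}

#' Export synthetic ground truth to disk
#'
#' Writes the bounding boxes as ViPER-dialect XML (`ground_truth.xml`), the
#' per-cell-frame feature table (`truth_features.csv`), and the generator
#' parameters (`synth_params.json`) into a directory. Channels can be written
#' separately with [write_image_series()].
#'
#' @param truth A `synth_truth` with rendered `features`.
#' @param path Output directory (created if missing).
#' @export
export_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_viper_ground_truth(truth_boxes(truth), file.path(path, "ground_truth.xml"))
  write.csv(truth$features, file.path(path, "truth_features.csv"), row.names = FALSE)
  pl <- unclass(truth$params)
  pl$populations <- as.list(pl$populations)
  jsonlite::write_json(pl, file.path(path, "synth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all channels of a synthetic movie as multi-page TIFFs
#'
#' @param truth A `synth_truth` with rendered `channels`.
#' @param path Output directory.
#' @return A [calibration()] pointing at the written files.
#' @export
write_synth_channels <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (role in names(truth$channels)) {
    fp <- file.path(path, paste0(role, ".tif"))
    write_image_series(truth$channels[[role]], fp)
    paths[[role]] <- fp
  }
  calibration(truth$params$pixel_size_um, truth$params$frame_interval_s, paths)
}
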