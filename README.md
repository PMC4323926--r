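# cellmotr

Detection, tracking and integrative motility analysis of cells in
multi-channel 2D time-lapse microscopy.

T cells (and leukocytes generally) move fast, switch between attached and
unattached motility, and are heterogeneous within one population. Studying
them quantitatively means following each cell through a transmitted-light
series and attaching, per track position, information from the other
channels recorded in the same field: the attachment footprint from
interference reflection microscopy (IRM), dye or probe intensities from up
to two fluorescence channels, and shape polarity from the transmitted
channel itself. cellmotr implements that whole chain, plus the evaluation
metrics to score it against ground truth, plus a synthetic movie generator
so everything is testable without external data.

## What it computes

- **Detection** — cells in each transmitted-light frame by Canny edge
  extraction followed by a gradient-directed circular Hough transform over
  a radius range *r* ∈ [r_min, r_max]: each edge pixel votes along ± its
  gradient direction, accumulator maxima are cell centroids. Robust to
  partial, non-contiguous edges (low contrast, touching cells).
- **Tracking** — two tiers. Conservative nearest-neighbour linking extends
  a track only when the association within radius *r* is mutually
  unambiguous, yielding frame-contiguous *segments*; then a Hungarian
  assignment over a segment-pair similarity
  s = 0.25·s_time + 0.5·s_space + 0.25·s_speed joins segments end-to-end
  into full tracks (joins accepted only above a similarity threshold).
- **Feature extraction** — per track position, a local box in each channel
  is segmented (Otsu + watershed on the distance transform for
  reflection/fluorescence; Canny + Hough + watershed for transmitted
  light): contact area and attachment, mean dye intensities, outline and
  aspect ratio. Cell types are assigned from the dye ratio.
- **Motility metrics** — instantaneous speed (µm/min), turn angle, arrest
  coefficient (fraction of speeds < 0.5 µm/min), confinement index
  (net displacement / path length), per-track summaries and
  control-normalised group tables.
- **Evaluation** — Jaccard-based SFDA (detection) and ATA (tracking,
  raw and thresholded at J ≥ 0.4) against ViPER-style bounding-box ground
  truth, and per-frame centroid-matched feature-error tables.
- **Synthetic movies** — persistent random walks with inverse speed–turn
  coupling, rendered into transmitted/reflection/fluorescence channels with
  exhaustive ground truth (tracks, boxes, footprint areas, dye means).

## Worked example

Generate a small two-population movie, run the full pipeline in memory and
score it against the generator's ground truth:

```r
library(cellmotr)

p   <- synth_params(n_cells = 12, n_frames = 20, seed = 42)
mv  <- synth_movie(p)                      # channels + ground truth
cal <- calibration(p$pixel_size_um, p$frame_interval_s)

det <- detect_cells(mv$channels$transmitted)
tr  <- filter_short_tracks(join_segments(link_nearest_neighbor(det)),
                           link_params())
fx  <- extract_features(mv$channels, tr, cal,
                        which_channels = c("reflection", "fluor1", "fluor2"))
lab <- assign_cell_types(fx$observations)
s   <- summarize_tracks(tr, cal, fx$observations, lab)
head(s[, c("track_id", "n_frames", "mean_speed_um_min",
           "confinement_index", "mean_contact_area_um2",
           "attached", "cell_type")])
#>   track_id n_frames mean_speed_um_min confinement_index mean_contact_area_um2 attached cell_type
#> 1        1       20             10.64             0.156                 31.47     TRUE     typeB
#> 2        2       20              6.58             0.907                 13.28     TRUE     typeA
#> 3        3       20              4.05             0.741                 29.93     TRUE     typeA
#> 4        4       20              4.46             0.263                  0.00    FALSE     typeA
#> 5        5       20              9.57             0.474                  6.82     TRUE     typeB
#> 6        6       20              5.69             0.572                  0.00    FALSE     typeA

evaluate_tracking(truth_boxes(mv), points_to_boxes(tr))
#> SFDA 0.641 | ATA 0.630 | ATA(thresholded, J>=0.40) 0.967 | 12 matched pairs
```

Each row is one cell track: `mean_speed_um_min` is its average
instantaneous speed, `confinement_index` 1 means straight-line motion,
`mean_contact_area_um2` is the average IRM footprint (0 and
`attached = FALSE` for cells that never touch the glass), and `cell_type`
comes from the fluorescence dye ratio — here the fast population (typeB,
10 µm/min programmed) and slow population (typeA, 5 µm/min) are recovered.
The thresholded ATA of 0.967 says the 12 tracks match the ground truth
nearly one-to-one; the raw ATA of 0.63 additionally penalises the few
pixels of localisation jitter on every box.

On real data, build a `calibration()` whose `channels` map roles to TIFF
paths (multi-page or per-frame directories) and call the same functions, or
drive everything from a JSON config with `run_pipeline()` /
`run_batch()`. A thin command-line front end is installed with the package
(`<library>/cellmotr/exec/cellmot`) with verbs `run`, `batch`, `preview`,
`synth`, `edit` and `score`.

## Package layout

- `R/` — implementation (image I/O, detection, tracking, features,
  motility metrics, evaluation, synthetic generator, pipeline).
- `tests/testthat/` — unit, property and end-to-end tests with brute-force
  and exhaustive-enumeration oracles.
- `vignettes/cellmotr-methods.Rmd` — the methods vignette: models,
  parameters, numerical choices, generator scope, limitations.
- `inst/exec/cellmot` — command-line front end.
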