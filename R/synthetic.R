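#' Synthetic AFM scene specification
#'
#' Bundles every knob of the synthetic topography generator. Defaults
#' emulate the imaging geometry of a 10 x 10 um scan at 1024 px
#' (~9.77 nm/px); the fibril model is a discrete worm-like chain painted
#' as a ridge of the stated apparent (tip-broadened) width, oligomers are
#' hemispherical bumps, and the background is a tilted plane plus a
#' per-scan-line quadratic bow with small line-to-line offsets, i.e. the
#' artefact structure the flattening stage is built to remove.
#'
#' @param image_px image side, pixels.
#' @param scan_size physical scan side, nm.
#' @param n_fibrils,n_oligomers object counts.
#' @param length_median_nm,length_gsd log-normal fibril contour length:
#'   median (nm) and geometric standard deviation (unitless > 1).
#' @param fibril_height_nm,fibril_height_sd_nm apparent fibril peak height
#'   (mean, sd), nm.
#' @param apparent_width_nm painted (tip-broadened) fibril width, nm.
#' @param persistence_length_nm worm-like-chain persistence length, nm.
#' @param oligomer_radius_nm,oligomer_radius_sd_nm oligomer footprint
#'   radius (mean, sd), nm.
#' @param oligomer_height_nm,oligomer_height_sd_nm oligomer peak height
#'   (mean, sd), nm.
#' @param tilt_x_nm,tilt_y_nm plane tilt across the full image, nm.
#' @param bow_nm amplitude of the per-row quadratic bow, nm.
#' @param line_jitter_nm sd of per-scan-line offsets, nm.
#' @param noise_sigma_nm additive Gaussian pixel noise sd, nm.
#' @param tip_blur_px Gaussian blur sigma applied to the painted objects,
#'   pixels; 0 disables.
#' @param seed RNG seed; a fixed seed reproduces the scene bit-identically.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_px = 1024L, scan_size = 10000,
                       n_fibrils = 30L, n_oligomers = 20L,
                       length_median_nm = 250, length_gsd = 1.5,
                       fibril_height_nm = 3, fibril_height_sd_nm = 0.4,
                       apparent_width_nm = 12,
                       persistence_length_nm = 4000,
                       oligomer_radius_nm = 15, oligomer_radius_sd_nm = 2,
                       oligomer_height_nm = 1.8, oligomer_height_sd_nm = 0.25,
                       tilt_x_nm = 4, tilt_y_nm = 3, bow_nm = 3,
                       line_jitter_nm = 0.15,
                       noise_sigma_nm = 0.08, tip_blur_px = 0.5,
                       seed = 1L) {
  spec <- list(image_px = as.integer(image_px), scan_size = scan_size,
               n_fibrils = as.integer(n_fibrils),
               n_oligomers = as.integer(n_oligomers),
               length_median_nm = length_median_nm, length_gsd = length_gsd,
               fibril_height_nm = fibril_height_nm,
               fibril_height_sd_nm = fibril_height_sd_nm,
               apparent_width_nm = apparent_width_nm,
               persistence_length_nm = persistence_length_nm,
               oligomer_radius_nm = oligomer_radius_nm,
               oligomer_radius_sd_nm = oligomer_radius_sd_nm,
               oligomer_height_nm = oligomer_height_nm,
               oligomer_height_sd_nm = oligomer_height_sd_nm,
               tilt_x_nm = tilt_x_nm, tilt_y_nm = tilt_y_nm, bow_nm = bow_nm,
               line_jitter_nm = line_jitter_nm,
               noise_sigma_nm = noise_sigma_nm, tip_blur_px = tip_blur_px,
               seed = as.integer(seed))
  scales <- c("image_px", "scan_size", "length_median_nm", "length_gsd",
              "fibril_height_nm", "apparent_width_nm",
              "persistence_length_nm", "oligomer_radius_nm",
              "oligomer_height_nm")
  for (s in scales) if (spec[[s]] <= 0) stop("`", s, "` must be positive")
  structure(spec, class = "scene_spec")
}

#' Sample a worm-like-chain fibril centerline
#'
#' Discrete worm-like chain with fixed step: successive turning angles are
#' i.i.d. N(0, sqrt(2 * step / P)), which gives the tangent-correlation
#' decay exp(-s / P) of a chain with persistence length P in the plane,
#' and hence the standard closed form for the mean squared end-to-end
#' distance, <R^2> = 2 P L - 2 P^2 (1 - exp(-L / P)). Self-intersection is
#' allowed (overlapping fibrils are a feature of the imaged samples, not a
#' defect). Uses the current RNG state; seed outside for reproducibility.
#'
#' @param length_nm contour length, nm.
#' @param persistence_length_nm persistence length, nm.
#' @param step_nm discretisation step, nm; arc length lands within one
#'   step of `length_nm`.
#' @param initial_angle starting heading, radians; random by default.
#' @return numeric matrix with columns `x`, `y` (nm), one row per vertex.
#' @export
sample_fibril_path <- function(length_nm, persistence_length_nm,
                               step_nm = 2,
                               initial_angle = stats::runif(1, 0, 2 * pi)) {
  stopifnot(length_nm > 0, persistence_length_nm > 0, step_nm > 0)
  n_steps <- max(1L, round(length_nm / step_nm))
  sd_turn <- sqrt(2 * step_nm / persistence_length_nm)
  turns <- c(initial_angle, stats::rnorm(n_steps - 1L, 0, sd_turn))
  ang <- cumsum(turns)
  cbind(x = c(0, cumsum(step_nm * cos(ang))),
        y = c(0, cumsum(step_nm * sin(ang))))
}

# Paint a disc of the given radius (nm) and height profile onto `canvas`
# (matrix, nm heights), taking the pixel-wise maximum. `profile` maps
# normalised radius in [0,1] to height. Returns the updated canvas.
paint_disc <- function(canvas, cx_nm, cy_nm, radius_nm, pixel_size, profile) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  j0 <- cx_nm / pixel_size + 0.5; i0 <- cy_nm / pixel_size + 0.5
  r_px <- radius_nm / pixel_size
  jj <- max(1L, floor(j0 - r_px)):min(nc, ceiling(j0 + r_px))
  ii <- max(1L, floor(i0 - r_px)):min(nr, ceiling(i0 + r_px))
  if (length(ii) == 0L || length(jj) == 0L) return(canvas)
  d2 <- outer((ii - i0)^2, (jj - j0)^2, `+`)
  inside <- d2 <= r_px^2
  if (any(inside)) {
    h <- profile(sqrt(d2[inside]) / r_px)
    sub <- canvas[ii, jj]
    sub[inside] <- pmax(sub[inside], h)
    canvas[ii, jj] <- sub
  }
  canvas
}

#' Render a synthetic AFM scene
#'
#' Builds a height map from a [scene_spec()]: worm-like-chain fibrils are
#' painted as flat-topped ridges with round caps, oligomers as
#' hemispherical bumps; heights of overlapping objects add, capped at 1.5x
#' the tallest object; Gaussian tip blur is applied to the objects; the
#' tilted-plane + per-row quadratic bow background and N(0, noise_sigma)
#' pixel noise are added last. Ground truth (per-object kind, centerline,
#' contour length, peak height, width; per-image painted coverage
#' fraction) is recorded before blur and noise.
#'
#' @param spec a [scene_spec()].
#' @param source_id image identifier for the returned map.
#' @return list with `map` ([height_map()]) and `truth` (list with
#'   `objects` data.frame, `coverage_fraction`, `polylines`).
#' @export
render_scene <- function(spec, source_id = sprintf("scene_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$image_px
  ps <- spec$scan_size / n
  approx_fp <- spec$n_fibrils *
    (spec$length_median_nm / ps) * max(1, spec$apparent_width_nm / ps) +
    spec$n_oligomers * pi * max(1, spec$oligomer_radius_nm / ps)^2
  if (approx_fp > 0.35 * n * n)
    stop("object count infeasible for the image area (expected footprint > 35%)")
  objects <- matrix(0, n, n)
  truth <- list()
  polylines <- list()
  margin <- spec$apparent_width_nm / 2 + 2 * ps
  step_nm <- ps / 2
  for (f in seq_len(spec$n_fibrils)) {
    L <- stats::rlnorm(1, log(spec$length_median_nm), log(spec$length_gsd))
    h <- max(0.3, stats::rnorm(1, spec$fibril_height_nm, spec$fibril_height_sd_nm))
    placed <- FALSE
    for (try in 1:30) {
      path <- sample_fibril_path(L, spec$persistence_length_nm, step_nm)
      ext_x <- range(path[, 1L]); ext_y <- range(path[, 2L])
      wx <- diff(ext_x); wy <- diff(ext_y)
      if (wx > spec$scan_size - 2 * margin || wy > spec$scan_size - 2 * margin)
        next
      ox <- stats::runif(1, margin - ext_x[1L],
                         spec$scan_size - margin - ext_x[2L])
      oy <- stats::runif(1, margin - ext_y[1L],
                         spec$scan_size - margin - ext_y[2L])
      path[, 1L] <- path[, 1L] + ox
      path[, 2L] <- path[, 2L] + oy
      placed <- TRUE
      break
    }
    if (!placed) {  # very long chain: anchor at centre, let it clip
      path <- sample_fibril_path(L, spec$persistence_length_nm, step_nm)
      path[, 1L] <- path[, 1L] - mean(range(path[, 1L])) + spec$scan_size / 2
      path[, 2L] <- path[, 2L] - mean(range(path[, 2L])) + spec$scan_size / 2
    }
    canvas <- matrix(0, n, n)
    flat_top <- function(u) rep(h, length(u))
    # radius floor of 0.8 px keeps sub-pixel-wide ridges gap-free: path
    # vertices are ps/2 apart, so the union of discs covers a sausage of
    # effective radius sqrt(r^2 - (ps/4)^2) = 0.76 px, above the
    # sqrt(2)/2 px worst-case distance from a pixel centre to the path
    paint_r <- max(spec$apparent_width_nm / 2, 0.8 * ps)
    for (v in seq_len(nrow(path)))
      canvas <- paint_disc(canvas, path[v, 1L], path[v, 2L],
                           paint_r, ps, flat_top)
    objects <- objects + canvas
    seglen <- sum(sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2))
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "fibril", true_length_nm = seglen, true_peak_height_nm = h,
      true_width_nm = spec$apparent_width_nm,
      clipped = !placed)
    polylines[[length(polylines) + 1L]] <- path
  }
  for (o in seq_len(spec$n_oligomers)) {
    # floors keep the oligomer population firmly above the detection
    # threshold: marginally visible specks are not part of the emulated
    # surface density
    R <- max(10, stats::rnorm(1, spec$oligomer_radius_nm, spec$oligomer_radius_sd_nm))
    h <- max(1.2, stats::rnorm(1, spec$oligomer_height_nm, spec$oligomer_height_sd_nm))
    cx <- stats::runif(1, R + 2 * ps, spec$scan_size - R - 2 * ps)
    cy <- stats::runif(1, R + 2 * ps, spec$scan_size - R - 2 * ps)
    canvas <- paint_disc(matrix(0, n, n), cx, cy, R, ps,
                         function(u) h * sqrt(pmax(0, 1 - u^2)))
    objects <- objects + canvas
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "oligomer", true_length_nm = 2 * R, true_peak_height_nm = h,
      true_width_nm = 2 * R, clipped = FALSE)
    polylines[[length(polylines) + 1L]] <- cbind(x = cx, y = cy)
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), true_length_nm = numeric(),
               true_peak_height_nm = numeric(), true_width_nm = numeric(),
               clipped = logical())
  if (nrow(truth_df)) truth_df$object_id <- seq_len(nrow(truth_df))
  coverage_fraction <- mean(objects > 0)
  peak_cap <- if (nrow(truth_df)) 1.5 * max(truth_df$true_peak_height_nm) else Inf
  objects <- pmin(objects, peak_cap)
  if (spec$tip_blur_px > 0)
    objects <- matrix(EBImage::gblur(objects, sigma = spec$tip_blur_px), n, n)
  x <- seq_len(n); y <- seq_len(n)
  bow_shape <- ((2 * (x - 1) / (n - 1)) - 1)^2 - 1 / 3   # zero-mean quadratic
  bow_amp <- spec$bow_nm * stats::runif(n, 0.8, 1.2)
  line_offsets <- stats::rnorm(n, 0, spec$line_jitter_nm)
  bg <- outer(y, x, function(yy, xx)
    spec$tilt_x_nm * (xx - 1) / (n - 1) + spec$tilt_y_nm * (yy - 1) / (n - 1)) +
    outer(bow_amp, bow_shape) +
    matrix(line_offsets, n, n)
  heights <- objects + bg
  if (spec$noise_sigma_nm > 0)
    heights <- heights + matrix(stats::rnorm(n * n, 0, spec$noise_sigma_nm), n, n)
  list(map = height_map(heights, pixel_size = ps, source_id = source_id),
       truth = list(objects = truth_df, coverage_fraction = coverage_fraction,
                    polylines = polylines))
}

#' Default condition grid configuration
#'
#' The generator's emulation of the study design: a 3 x 3 grid of DHA
#' concentration (0, 30, 100 uM) by incubation time (1, 6, 24 h) with 8
#' images per condition. Median true fibril lengths follow the reported
#' series — the 30 uM arm at 64, 88, 126 nm across 1/6/24 h, the control
#' reaching 250 nm and the 100 uM arm 421 nm at 24 h — with monotone
#' growth in time, the 30 < 0 < 100 uM ordering of length and coverage at
#' every time point, and wider length spread in the 100 uM arm. Scenes are
#' 5 x 5 um at 512 px — the same ~9.77 nm/px sampling as a 10 x 10 um
#' scan at 1024 px; object counts are set for the sparse, individually
#' resolvable surface density a 1:10-diluted deposition is chosen to
#' produce. The 100 uM arm grows mainly in length and coverage; its
#' counts rise only mildly so that its long fibrils remain mostly
#' separable.
#'
#' @param n_images images per condition; default 8.
#' @param image_px,scan_size scene geometry; defaults 512 px, 5000 nm.
#' @return nested list used by [generate_condition_grid()].
#' @export
grid_config <- function(n_images = 8L, image_px = 512L, scan_size = 5000) {
  list(
    n_images = as.integer(n_images),
    image_px = as.integer(image_px),
    scan_size = scan_size,
    dha = c(0, 30, 100),
    time = c(1, 6, 24),
    # rows: dha 0/30/100; cols: 1/6/24 h
    length_median_nm = matrix(c(110, 170, 250,
                                64, 88, 126,
                                150, 280, 421), 3, 3, byrow = TRUE),
    length_gsd = matrix(c(1.35, 1.45, 1.55,
                          1.35, 1.45, 1.55,
                          1.60, 1.70, 1.80), 3, 3, byrow = TRUE),
    n_fibrils = matrix(c(16, 22, 28,
                         10, 14, 18,
                         14, 15, 16), 3, 3, byrow = TRUE),
    n_oligomers = matrix(c(20, 24, 28,
                           12, 15, 18,
                           25, 32, 40), 3, 3, byrow = TRUE))
}

#' Generate the full synthetic condition grid
#'
#' Renders `n_images` scenes for each of the 9 DHA x time conditions with
#' per-image seeds derived deterministically from `seed`. Optionally
#' writes the images (32-bit float TIFF), a manifest CSV linking files to
#' conditions, and a per-object ground-truth CSV.
#'
#' @param config a [grid_config()] list.
#' @param seed integer master seed; fixed seed gives a bit-identical
#'   dataset.
#' @param out_dir if non-`NULL`, directory to write images + manifest +
#'   truth tables into (created if needed).
#' @return list of entries, each with `map`, `condition`
#'   ([condition_label()]) and `truth`; plus attributes `manifest`
#'   (data.frame) and `truth_table` (per-object data.frame).
#' @export
generate_condition_grid <- function(config = grid_config(), seed = 1L,
                                    out_dir = NULL) {
  set.seed(seed)
  n_cond <- length(config$dha) * length(config$time)
  image_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_cond * config$n_images)
  entries <- vector("list", n_cond * config$n_images)
  manifest <- NULL
  truth_table <- NULL
  k <- 0L
  for (ci in seq_along(config$dha)) {
    for (ti in seq_along(config$time)) {
      for (r in seq_len(config$n_images)) {
        k <- k + 1L
        cond <- condition_label(config$dha[ci], config$time[ti], r)
        id <- format(cond)
        spec <- scene_spec(
          image_px = config$image_px, scan_size = config$scan_size,
          n_fibrils = config$n_fibrils[ci, ti],
          n_oligomers = config$n_oligomers[ci, ti],
          length_median_nm = config$length_median_nm[ci, ti],
          length_gsd = config$length_gsd[ci, ti],
          seed = image_seeds[k])
        sc <- render_scene(spec, source_id = id)
        entries[[k]] <- list(map = sc$map, condition = cond, truth = sc$truth)
        manifest <- rbind(manifest, data.frame(
          source_id = id, file = paste0(id, ".tif"),
          dha_concentration = cond$dha_concentration,
          incubation_time = cond$incubation_time, replicate = r,
          pixel_size_nm = sc$map$pixel_size, seed = image_seeds[k]))
        tt <- sc$truth$objects
        if (nrow(tt)) {
          tt$source_id <- id
          truth_table <- rbind(truth_table, tt)
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (e in entries)
      write_height_map(e$map, file.path(out_dir, paste0(e$map$source_id, ".tif")),
                       format = "tiff")
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_table, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  attr(entries, "manifest") <- manifest
  attr(entries, "truth_table") <- truth_table
  entries
}
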