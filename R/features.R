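#' Threshold a flattened image to detect features
#'
#' Pixels more than `k_detect` background standard deviations above the
#' fitted background level (0 nm after [flatten_pipeline()]) are feature
#' pixels. This is the detection analogue of the user-chosen cutoff in
#' interactive analysis, made reproducible by expressing it in units of
#' the fitted background sigma.
#'
#' @param map flattened [height_map()] with background centred at 0.
#' @param model `background_model` from [flatten_pipeline()].
#' @param k_detect threshold multiplier (> 0); default 5.
#' @return logical detection mask.
#' @export
threshold_features <- function(map, model, k_detect = 5) {
  stopifnot(inherits(map, "height_map"), k_detect > 0)
  if (!is.finite(model$sigma) || model$sigma <= 0)
    stop("background sigma must be > 0 to set a detection threshold")
  map$heights > k_detect * model$sigma
}

#' Label connected features
#'
#' 8-connected component labelling of the detection mask; components
#' smaller than `min_area_px` are discarded entirely (not labelled and not
#' counted in coverage). Touching or overlapping objects deliberately form
#' a single feature: separating them is not attempted, and the same rule
#' is applied to every image so between-condition trends remain
#' comparable. Labels are renumbered contiguously from 1 in order of each
#' component's first pixel (column-major), which makes labelling
#' deterministic.
#'
#' @param mask logical detection mask.
#' @param min_area_px minimum component area in pixels; default 4.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `n_features`.
#' @export
label_features <- function(mask, min_area_px = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 0L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # bwlabel is 4-connected; union labels that touch diagonally
    p <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
      cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))
    p <- p[p[, 1L] > 0L & p[, 2L] > 0L & p[, 1L] != p[, 2L], , drop = FALSE]
    if (nrow(p)) {
      parent <- seq_len(nlab)
      find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
      for (r in seq_len(nrow(p))) {
        ra <- find(p[r, 1L]); rb <- find(p[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    remap <- integer(max(lab))
    # order of first occurrence, column-major: deterministic ids
    first <- vapply(keep, function(k) match(k, lab), integer(1))
    keep <- keep[order(first)]
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    nlab <- length(keep)
  }
  list(labels = lab, n_features = as.integer(nlab))
}

#' Measure one detected feature
#'
#' Computes the morphometry of feature `id`:
#' \itemize{
#'   \item `length_nm`: geodesic skeleton length (thinning + traced chords,
#'     [skeleton_chord_length()]); branches of a branched object are
#'     summed, so the object still counts as a single feature. Compact
#'     features whose skeleton collapses to two pixels or fewer use the
#'     maximum Feret diameter instead — for a round blob the long axis is
#'     its diameter.
#'   \item `width_nm`: `2 * mean(EDT) - 1` pixels sampled on skeleton
#'     pixels (exact for odd-width rods); falls back to
#'     `area * pixel_size^2 / length` if no skeleton pixel exists.
#'   \item `max_height_nm`: maximum in-cluster height. The maximum, not the
#'     cluster mean, is used deliberately: averaging over the whole
#'     footprint would underestimate the fibril's true height.
#'   \item `klass`: `"fibril"` when length >= 2 * width, else
#'     `"oligomer"`.
#'   \item `touches_edge`: whether the feature touches the image border
#'     (its true length is unknowable; flagged so summaries can exclude it).
#' }
#'
#' @param labels result of [label_features()].
#' @param id feature id in `1:n_features`.
#' @param map flattened [height_map()] (background at 0 nm).
#' @param model `background_model` (unused beyond validation; heights are
#'   already relative to the fitted background peak).
#' @return one-row `data.frame` (a feature record).
#' @export
measure_feature <- function(labels, id, map, model = NULL) {
  stopifnot(inherits(map, "height_map"))
  if (id < 1L || id > labels$n_features) stop("feature id out of range: ", id)
  lab <- labels$labels
  px <- which(lab == id, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("empty label: ", id)
  nr <- nrow(lab); nc <- ncol(lab)
  touches <- any(px[, 1L] == 1L | px[, 1L] == nr | px[, 2L] == 1L | px[, 2L] == nc)
  # crop to bounding box with 1-px pad so the EDT sees background all around
  r0 <- max(1L, min(px[, 1L]) - 1L); r1 <- min(nr, max(px[, 1L]) + 1L)
  c0 <- max(1L, min(px[, 2L]) - 1L); c1 <- min(nc, max(px[, 2L]) + 1L)
  sub <- lab[r0:r1, c0:c1, drop = FALSE] == id
  subpad <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  subpad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  edt <- matrix(EBImage::distmap(subpad), nrow(subpad), ncol(subpad))
  sk <- thin_mask(subpad)
  ps <- map$pixel_size
  area <- nrow(px)
  n_sk <- sum(sk)
  topo <- skeleton_topology(sk)
  if (n_sk > 2L) {
    length_px <- skeleton_chord_length(sk, edt)
    # unbranched features: thinning erodes short objects more than their
    # end-to-end extent shrinks, so the footprint Feret extent is the
    # better estimate there; take the larger of the two. The detected
    # footprint overhangs the object by the blur-to-threshold transition,
    # about half a pixel per end, hence the -1 on the centre-to-centre
    # Feret distance.
    if (length(trace_skeleton_paths(sk)) == 1L)
      length_px <- max(length_px,
                       feret_diameter_px(which(subpad, arr.ind = TRUE)) - 2)
    # degenerate tracing (e.g. dense junction cluster): fall back to Feret
    if (length_px <= 0) length_px <- feret_diameter_px(which(subpad, arr.ind = TRUE))
  } else {
    length_px <- feret_diameter_px(which(subpad, arr.ind = TRUE))
  }
  # compact features (collapsed skeleton): the EDT half-thickness and the
  # area-per-length width are both lower bounds on the true width — the
  # first degrades on diagonal-cut blobs, the second on round ones — so
  # take the larger
  width_px <- if (n_sk > 2L) max(2 * mean(edt[sk]) - 1, 1)
  else max(2 * max(edt) - 1, area / length_px, 1)
  length_nm <- length_px * ps
  width_nm <- width_px * ps
  hvals <- map$heights[lab == id]
  # a footprint no larger than 3 x 3 px cannot exhibit a credible 2:1
  # aspect ratio at this sampling; such sub-resolution blobs are compact
  # aggregates by definition
  bbox_max <- max(diff(range(px[, 1L])), diff(range(px[, 2L]))) + 1L
  data.frame(
    feature_id = as.integer(id),
    length_nm = length_nm,
    width_nm = width_nm,
    max_height_nm = max(hvals),
    area_px = as.integer(area),
    n_branches = topo$n_branches,
    klass = if (length_nm >= 2 * width_nm && bbox_max > 3L) "fibril"
            else "oligomer",
    touches_edge = touches,
    stringsAsFactors = FALSE
  )
}

#' Surface coverage
#'
#' Percentage of image pixels above the detection threshold after
#' minimum-area filtering; fibrils and oligomers both contribute.
#'
#' @param mask logical detection mask (post filtering), or a label matrix
#'   where > 0 means feature.
#' @return coverage in percent.
#' @export
surface_coverage <- function(mask) {
  100 * mean(mask > 0)
}

#' Analyze one AFM image end to end
#'
#' Runs the full measurement chain on a raw height map: flattening
#' ([flatten_pipeline()]), detection thresholding, 8-connected labelling,
#' per-feature morphometry and surface coverage. Deterministic for a fixed
#' configuration.
#'
#' For noise-free images the fitted background sigma can be exactly zero
#' (there is no noise distribution to threshold against); detection then
#' falls back to a tiny positive height floor so that ideal synthetic
#' scenes remain analyzable.
#'
#' @param map raw [height_map()].
#' @param condition a [condition_label()] or `NULL`.
#' @param config a [pipeline_config()] list (defaults used when omitted).
#' @return an `image_measurement`: list with `source_id`, `condition`,
#'   `features` (data.frame of feature records), `coverage_percent`,
#'   `n_fibrils`, `n_oligomers`, `model`, and `skeleton` (logical overlay
#'   of all traced skeletons, for Figure-style overlays).
#' @export
analyze_image <- function(map, condition = NULL, config = pipeline_config()) {
  fp <- flatten_pipeline(map, k_mask = config$mask_k, n_passes = config$n_passes,
                         order = config$poly_order, n_bins = config$n_bins)
  flat <- fp$map
  model <- fp$model
  if (model$sigma > 0) {
    det <- threshold_features(flat, model, config$k_detect)
  } else {
    det <- flat$heights > 1e-9 * max(abs(flat$heights), 1)
  }
  labs <- label_features(det, min_area_px = config$min_area_px)
  cov <- surface_coverage(labs$labels)
  feats <- if (labs$n_features > 0L)
    do.call(rbind, lapply(seq_len(labs$n_features), measure_feature,
                          labels = labs, map = flat, model = model))
  else
    data.frame(feature_id = integer(), length_nm = numeric(),
               width_nm = numeric(), max_height_nm = numeric(),
               area_px = integer(), n_branches = integer(),
               klass = character(), touches_edge = logical(),
               stringsAsFactors = FALSE)
  skel <- thin_mask(labs$labels > 0L)
  structure(
    list(source_id = map$source_id, condition = condition,
         features = feats, coverage_percent = cov,
         n_fibrils = sum(feats$klass == "fibril"),
         n_oligomers = sum(feats$klass == "oligomer"),
         model = model, labels = labs$labels, skeleton = skel,
         flattened = flat),
    class = "image_measurement")
}

#' @export
print.image_measurement <- function(x, ...) {
  cat(sprintf("<image_measurement> %s: %d fibrils, %d oligomers, coverage %.2f%%\n",
              x$source_id, x$n_fibrils, x$n_oligomers, x$coverage_percent))
  invisible(x)
}

#' Overlay traced skeletons on the topography
#'
#' Draws the flattened topography in grayscale and the traced skeleton of
#' every detected feature on top, the standard visual check that the
#' routine detects and traces the long axis of all fibrils and oligomers.
#'
#' @param measurement an `image_measurement` from [analyze_image()].
#' @param trace_col overlay colour; default blue.
#' @param ... passed to [graphics::image()].
#' @export
plot_overlay <- function(measurement, trace_col = "blue", ...) {
  m <- measurement$flattened$heights
  nr <- nrow(m); nc <- ncol(m)
  # orient so row 1 is the top scan line
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = t(m[nr:1, ]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  useRaster = TRUE, asp = 1, xlab = "x (px)", ylab = "y (px)",
                  main = measurement$source_id, ...)
  sk <- which(measurement$skeleton, arr.ind = TRUE)
  if (nrow(sk))
    graphics::points(sk[, 2L], nr + 1L - sk[, 1L], pch = ".", cex = 1.2,
                     col = trace_col)
  invisible(measurement)
}
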