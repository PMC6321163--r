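# Geometric fixtures built in code: binary masks with known morphometry,
# and a wrapper that measures a mask as a lone feature on a flat image.

rod_mask <- function(nr = 60, nc = 60, rows = 28:32, cols = 10:50) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

disc_mask <- function(nr = 30, nc = 30, cx = 15, cy = 15, r = 4) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

# three ~20 px arms meeting at one junction, dilated to 3 px thickness
y_mask <- function() {
  m <- matrix(FALSE, 60, 60)
  m[30, 10:30] <- TRUE
  m[10:30, 30] <- TRUE
  for (k in 0:20) m[30 + round(k * 0.7), 30 + round(k * 0.7)] <- TRUE
  matrix(EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0, 60, 60)
}

# measure a mask as one feature on an otherwise flat map
measure_mask <- function(mask, height = 10, pixel_size = 10, min_area = 4) {
  heights <- matrix(0, nrow(mask), ncol(mask))
  heights[mask] <- height
  labs <- label_features(mask, min_area)
  stopifnot(labs$n_features >= 1)
  measure_feature(labs, 1L, height_map(heights, pixel_size = pixel_size))
}

# rotate a matrix 90 degrees clockwise
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
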