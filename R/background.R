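#' Plane and line-by-line flatten
#'
#' First-stage background removal: subtract the least-squares best-fit
#' plane from the whole image, then subtract the median of each scan line
#' from that line. This removes sample tilt and gross line-to-line offsets
#' before any feature is identified.
#'
#' On a complete pixel grid the plane coefficients have a closed form
#' because the column and row coordinates are orthogonal regressors, so no
#' general least-squares solver is needed.
#'
#' @param map a [height_map()], at least 2 x 2.
#' @return a flattened [height_map()].
#' @export
plane_and_line_flatten <- function(map) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  if (nrow(h) < 2L || ncol(h) < 2L)
    stop("degenerate image: plane flattening needs at least 2 rows and 2 columns")
  nr <- nrow(h); nc <- ncol(h)
  x <- seq_len(nc) - (nc + 1) / 2          # column coordinate, centred
  y <- seq_len(nr) - (nr + 1) / 2          # row coordinate, centred
  bx <- drop(colMeans(h) %*% x) / sum(x^2) # nm per px along x
  by <- drop(y %*% rowMeans(h)) / sum(y^2) # nm per px along y
  a <- mean(h)
  h <- h - (a + outer(y * by, x * bx, `+`))
  h <- h - apply(h, 1L, stats::median)
  out <- map
  out$heights <- h
  attr(out, "plane_coeffs") <- c(offset = a, x_slope = bx, y_slope = by)
  out
}

#' Mask topographic features above the background
#'
#' Marks pixels sitting significantly above the substrate so they can be
#' excluded from background fitting. The threshold is
#' `median + k * 1.4826 * MAD` of all pixel heights — a reproducible,
#' robust surrogate for the operator-chosen cutoff such a masking step
#' traditionally relies on.
#'
#' @param map a flattened [height_map()].
#' @param k threshold multiplier in robust-sigma units (> 0); default 3.
#' @return logical matrix, `TRUE` = feature pixel (excluded from
#'   background fits).
#' @export
make_feature_mask <- function(map, k = 3) {
  stopifnot(inherits(map, "height_map"), k > 0)
  h <- map$heights
  thr <- stats::median(h) + k * stats::mad(h)
  mask <- h > thr
  frac <- mean(mask)
  if (frac > 0.9)
    stop(sprintf(
      "feature mask covers %.1f%% of pixels; threshold too low or image unusable",
      100 * frac))
  mask
}

#' Row-wise polynomial background subtraction
#'
#' For each scan line, fits a polynomial of the given order (default 2) in
#' the column coordinate to the *unmasked* pixels only, then subtracts the
#' fitted polynomial from the entire line. Masking the features first keeps
#' tall objects from dragging the background fit up and creating shadow
#' artefacts around them.
#'
#' Rows with fewer than `order + 2` unmasked pixels (e.g. a line crossed
#' entirely by a fibril) reuse the element-wise median of the successfully
#' fitted rows' coefficients rather than destroying the line.
#'
#' The polynomial basis is `1, x, x^2` with `x` the centred column index
#' (pixels); coefficients are reported in that basis, nm.
#'
#' @param map a [height_map()].
#' @param mask logical feature mask of the same shape (`TRUE` = excluded),
#'   or `NULL` for no masking.
#' @param order polynomial order, >= 0; default 2.
#' @return list with `map` (flattened [height_map()]) and `row_coeffs`
#'   (matrix, one row of `order + 1` coefficients per scan line).
#' @export
rowwise_poly_flatten <- function(map, mask = NULL, order = 2L) {
  stopifnot(inherits(map, "height_map"))
  if (order < 0) stop("`order` must be >= 0")
  h <- map$heights
  nr <- nrow(h); nc <- ncol(h)
  if (is.null(mask)) mask <- matrix(FALSE, nr, nc)
  if (!is.logical(mask) || !identical(dim(mask), dim(h)))
    stop("`mask` must be a logical matrix with the same shape as the image")
  if (mean(mask) > 0.9)
    stop("less than 10% of pixels remain background; cannot fit background")
  x <- seq_len(nc) - (nc + 1) / 2
  X <- outer(x, 0:order, `^`)            # Vandermonde in centred pixel units
  coefs <- matrix(NA_real_, nr, order + 1L)
  for (i in seq_len(nr)) {
    use <- !mask[i, ]
    if (sum(use) >= order + 2L) {
      fit <- stats::lm.fit(X[use, , drop = FALSE], h[i, use])
      coefs[i, ] <- fit$coefficients
    }
  }
  bad <- !stats::complete.cases(coefs)
  if (all(bad)) stop("no row had enough unmasked pixels for the polynomial fit")
  if (any(bad)) {
    med <- apply(coefs[!bad, , drop = FALSE], 2L, stats::median)
    coefs[bad, ] <- matrix(med, sum(bad), order + 1L, byrow = TRUE)
  }
  out <- map
  out$heights <- h - coefs %*% t(X)
  list(map = out, row_coeffs = coefs)
}

#' Fit a Gaussian to the background pixel-height histogram
#'
#' Histograms the unmasked pixel heights (256 bins over the 0.1-99.9
#' percentile range by default) and fits `A * exp(-(h - mu)^2 / (2 sigma^2))`
#' by Levenberg-Marquardt nonlinear least squares, starting from the sample
#' moments. The fitted peak `mu` is the background level all subsequent
#' height measurements are taken relative to; this is far more robust than
#' local height references on a noisy substrate. If the fit fails to
#' converge the sample median and scaled MAD are returned with a warning.
#'
#' @param map a flattened [height_map()].
#' @param mask logical feature mask (`TRUE` = excluded) or `NULL`.
#' @param n_bins histogram bins; default 256.
#' @return list with `mu`, `sigma` (nm) and `method`
#'   (`"gaussian_fit"` or `"median_mad_fallback"`).
#' @export
fit_background_gaussian <- function(map, mask = NULL, n_bins = 256L) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  vals <- if (is.null(mask)) as.numeric(h) else h[!mask]
  if (length(vals) < 1000L)
    stop("need at least 1000 unmasked pixels to model the background")
  rng <- stats::quantile(vals, c(0.001, 0.999), names = FALSE)
  # spreads below 1e-9 nm are numerical residue, not a noise distribution
  if (rng[2] - rng[1] < 1e-9)
    stop("degenerate background: pixel heights are (nearly) constant")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  inside <- vals[vals >= rng[1] & vals <= rng[2]]
  counts <- graphics::hist(inside, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  m0 <- mean(inside); s0 <- stats::sd(inside); a0 <- max(counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(mids - mu)^2 / (2 * sigma^2)),
      start = list(A = a0, mu = m0, sigma = s0),
      lower = c(A = 0, mu = -Inf, sigma = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("background Gaussian fit did not converge; using median/MAD fallback")
    med <- stats::median(vals); s <- stats::mad(vals)
    if (s <= 0) stop("degenerate background: zero spread, no Gaussian model")
    return(list(mu = med, sigma = s, method = "median_mad_fallback"))
  }
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
       method = "gaussian_fit")
}

#' Full flattening pipeline
#'
#' Runs the complete background-removal sequence on a raw height map:
#' plane + line-by-line flatten, then `n_passes` iterations of
#' (feature mask -> masked row-wise polynomial subtraction), then a
#' Gaussian fit to the background histogram. Masking the tallest features
#' before the polynomial flatten minimises shadow artefacts; a second pass
#' re-derives the mask from the improved flatten. The returned map is
#' recentred so the fitted background peak sits at exactly 0 nm.
#'
#' @param map raw [height_map()].
#' @param k_mask masking threshold multiplier; default 3.
#' @param n_passes mask -> flatten iterations; default 2.
#' @param order polynomial order for the row-wise fit; default 2.
#' @param n_bins histogram bins for the Gaussian fit; default 256.
#' @return list with `map` (flattened, background at 0) and `model`, a
#'   `background_model` list: `plane_coeffs`, `row_poly_coeffs`, `mu`
#'   (fitted peak before recentring), `sigma`, `fit_method`.
#' @export
flatten_pipeline <- function(map, k_mask = 3, n_passes = 2L, order = 2L,
                             n_bins = 256L) {
  flat <- plane_and_line_flatten(map)
  plane <- attr(flat, "plane_coeffs")
  coefs <- NULL
  mask <- NULL
  for (p in seq_len(n_passes)) {
    mask <- make_feature_mask(flat, k = k_mask)
    res <- rowwise_poly_flatten(flat, mask, order = order)
    flat <- res$map
    coefs <- res$row_coeffs
  }
  mask <- make_feature_mask(flat, k = k_mask)
  # a noise-free, perfectly flattened background has (numerically) zero
  # spread; there is no Gaussian to fit, the background level is the median
  bg <- tryCatch(
    fit_background_gaussian(flat, mask, n_bins = n_bins),
    error = function(e) {
      if (grepl("degenerate background", conditionMessage(e)))
        list(mu = stats::median(flat$heights[!mask]), sigma = 0,
             method = "degenerate")
      else stop(e)
    })
  flat$heights <- flat$heights - bg$mu
  model <- structure(
    list(plane_coeffs = plane, row_poly_coeffs = coefs,
         mu = bg$mu, sigma = bg$sigma, fit_method = bg$method),
    class = "background_model")
  list(map = flat, model = model)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mu = %.4g nm, sigma = %.4g nm (%s)\n",
              x$mu, x$sigma, x$fit_method))
  invisible(x)
}
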