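#' Summarize all measurements for one condition
#'
#' Aggregates the image measurements of a single (DHA concentration,
#' incubation time) cell. Fibril length and height statistics pool the
#' individual feature records across images (features are the measurement
#' unit; SEM = sd / sqrt(n_fibrils)); surface coverage is a per-image
#' quantity, so its mean and SEM use images as the replication unit.
#' Edge-touching features and oligomers are excluded from length/height
#' statistics. If a condition has no usable fibrils, the means are
#' reported as an explicit "no fibrils" marker (`NA` with
#' `no_fibrils = TRUE`), never as zero.
#'
#' @param measurements list of `image_measurement` objects for one
#'   condition (>= 1 image).
#' @param kde_points grid points for the length KDE; default 128.
#' @return a `condition_summary` list.
#' @export
summarize_condition <- function(measurements, kde_points = 128L) {
  stopifnot(length(measurements) >= 1L)
  cond <- measurements[[1L]]$condition
  feats <- do.call(rbind, lapply(measurements, `[[`, "features"))
  fib <- feats[feats$klass == "fibril" & !feats$touches_edge, , drop = FALSE]
  n_fib <- nrow(fib)
  cov <- vapply(measurements, `[[`, numeric(1), "coverage_percent")
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  no_fibrils <- n_fib == 0L
  kde <- NULL
  if (!no_fibrils && length(unique(fib$length_nm)) >= 2L)
    kde <- kde_density(fib$length_nm, grid_points = kde_points)
  structure(
    list(
      dha_concentration = if (!is.null(cond)) cond$dha_concentration else NA_real_,
      incubation_time = if (!is.null(cond)) cond$incubation_time else NA_real_,
      n_images = length(measurements),
      n_fibrils = n_fib,
      n_oligomers = sum(feats$klass == "oligomer"),
      no_fibrils = no_fibrils,
      mean_length = if (no_fibrils) NA_real_ else mean(fib$length_nm),
      sem_length = if (no_fibrils) NA_real_ else sem(fib$length_nm),
      mean_height = if (no_fibrils) NA_real_ else mean(fib$max_height_nm),
      sem_height = if (no_fibrils) NA_real_ else sem(fib$max_height_nm),
      mean_coverage = mean(cov),
      sem_coverage = sem(cov),
      length_kde = kde),
    class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %g uM DHA, %g h: %d images, %d fibrils\n",
              x$dha_concentration, x$incubation_time, x$n_images, x$n_fibrils))
  if (x$no_fibrils) cat("  no fibrils\n")
  else cat(sprintf("  length %.1f +/- %.1f nm, height %.2f +/- %.2f nm, coverage %.2f +/- %.2f %%\n",
                   x$mean_length, x$sem_length, x$mean_height, x$sem_height,
                   x$mean_coverage, x$sem_coverage))
  invisible(x)
}

#' Kernel density estimate for violin-style summaries
#'
#' Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth, evaluated
#' on an even grid spanning the data range extended by three bandwidths on
#' each side (so the density decays to ~0 at the grid ends and its
#' trapezoid integral is 1 to within 1%).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param grid_points number of grid points; default 128.
#' @return data.frame with columns `value`, `density`.
#' @export
kde_density <- function(values, grid_points = 128L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("KDE needs at least 2 distinct values")
  bw <- stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = grid_points,
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  data.frame(value = d$x, density = d$y)
}

#' Contrast two condition summaries
#'
#' Ratio of the two conditions' means for one quantity, plus the derived
#' percent change and the percent reduction of the smaller mean relative
#' to the larger. This is the arithmetic behind statements like a "50%
#' reduction in fibril length" between two samples.
#'
#' @param num,den `condition_summary` objects (numerator, denominator),
#'   or any lists carrying `mean_<quantity>` fields.
#' @param quantity `"length"`, `"height"` or `"coverage"`.
#' @return a `contrast_result` list with `ratio`, `percent_change`
#'   (`100 * (ratio - 1)`) and `percent_reduction_small_vs_large`
#'   (`100 * (1 - min/max)`).
#' @export
contrast <- function(num, den, quantity = c("length", "height", "coverage")) {
  quantity <- match.arg(quantity)
  key <- paste0("mean_", quantity)
  a <- num[[key]]; b <- den[[key]]
  if (!is.finite(a) || !is.finite(b))
    stop("both summaries must have a defined mean for ", quantity)
  if (b <= 0) stop("denominator mean must be > 0")
  ratio <- a / b
  structure(
    list(quantity = quantity,
         numerator = c(dha = num$dha_concentration, time = num$incubation_time),
         denominator = c(dha = den$dha_concentration, time = den$incubation_time),
         mean_num = a, mean_den = b,
         ratio = ratio,
         percent_change = 100 * (ratio - 1),
         percent_reduction_small_vs_large = 100 * (1 - min(a, b) / max(a, b))),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast> %s: %.4g / %.4g = %.3f (%+.1f%%)\n",
              x$quantity, x$mean_num, x$mean_den, x$ratio, x$percent_change))
  invisible(x)
}

#' Condition-grid report
#'
#' Turns a set of condition summaries into a tidy table (one row per
#' condition) plus, for each incubation time with more than one
#' concentration, all pairwise length contrasts and the ordering of mean
#' fibril length across concentrations.
#'
#' @param summaries list of `condition_summary` objects.
#' @return list with `table` (data.frame), `contrasts` (data.frame of
#'   pairwise within-time length contrasts) and `orderings` (data.frame:
#'   per time, the concentrations ordered by increasing mean length).
#' @export
grid_report <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(dha_concentration = s$dha_concentration,
               incubation_time = s$incubation_time,
               n_images = s$n_images, n_fibrils = s$n_fibrils,
               n_oligomers = s$n_oligomers,
               mean_length_nm = s$mean_length, sem_length_nm = s$sem_length,
               mean_height_nm = s$mean_height, sem_height_nm = s$sem_height,
               mean_coverage_pct = s$mean_coverage,
               sem_coverage_pct = s$sem_coverage)))
  tab <- tab[order(tab$incubation_time, tab$dha_concentration), , drop = FALSE]
  rownames(tab) <- NULL
  contrasts <- NULL
  orderings <- NULL
  for (tt in unique(tab$incubation_time)) {
    ss <- summaries[vapply(summaries, function(s)
      s$incubation_time == tt && !s$no_fibrils, logical(1))]
    if (length(ss) >= 2L) {
      ss <- ss[order(vapply(ss, `[[`, numeric(1), "dha_concentration"))]
      for (i in seq_along(ss)) for (j in seq_along(ss)) {
        if (i >= j) next
        ct <- contrast(ss[[j]], ss[[i]], "length")
        contrasts <- rbind(contrasts, data.frame(
          incubation_time = tt,
          dha_num = ss[[j]]$dha_concentration,
          dha_den = ss[[i]]$dha_concentration,
          ratio = ct$ratio, percent_change = ct$percent_change,
          percent_reduction = ct$percent_reduction_small_vs_large))
      }
      ord <- order(vapply(ss, `[[`, numeric(1), "mean_length"))
      orderings <- rbind(orderings, data.frame(
        incubation_time = tt,
        length_ordering = paste(
          vapply(ss[ord], `[[`, numeric(1), "dha_concentration"),
          collapse = " < ")))
    }
  }
  list(table = tab, contrasts = contrasts, orderings = orderings)
}
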