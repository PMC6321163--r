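#' Pipeline configuration
#'
#' All tunable parameters of the measurement chain in one list. The two
#' thresholds are expressed in robust-sigma units so they transfer across
#' images with different noise levels: `mask_k` controls which pixels are
#' excluded from background fitting, `k_detect` which pixels count as
#' feature after flattening.
#'
#' @param pixel_size default nm-per-pixel for file readers; `NULL` means
#'   it must come from the manifest or call site.
#' @param mask_k feature-mask threshold multiplier; default 3.
#' @param k_detect detection threshold multiplier; default 5.
#' @param min_area_px minimum feature area, pixels; default 4.
#' @param poly_order row-wise background polynomial order; default 2.
#' @param n_passes mask -> flatten iterations; default 2.
#' @param n_bins background histogram bins; default 256.
#' @param kde_grid KDE grid points for length distributions; default 128.
#' @param seed RNG seed recorded with the run.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = NULL, mask_k = 3, k_detect = 5,
                            min_area_px = 4L, poly_order = 2L, n_passes = 2L,
                            n_bins = 256L, kde_grid = 128L, seed = 1L) {
  if (mask_k <= 0 || k_detect <= 0) stop("threshold multipliers must be > 0")
  structure(
    list(pixel_size = pixel_size, mask_k = mask_k, k_detect = k_detect,
         min_area_px = as.integer(min_area_px),
         poly_order = as.integer(poly_order), n_passes = as.integer(n_passes),
         n_bins = as.integer(n_bins), kde_grid = as.integer(kde_grid),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML)
#'
#' Round-trip stable: `load_config(save_config(cfg, path))` reproduces
#' `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Analyze a dataset of images
#'
#' Runs [analyze_image()] over a list of `(map, condition)` entries (the
#' in-memory form produced by [generate_condition_grid()]) and collects
#' tidy result tables.
#'
#' @param entries list; each element has `map` ([height_map()]) and
#'   `condition` ([condition_label()] or `NULL`).
#' @param config a [pipeline_config()].
#' @param verbose log one line per image to stderr.
#' @return list with `measurements` (list of `image_measurement`),
#'   `features` (per-feature data.frame) and `images` (per-image
#'   data.frame).
#' @export
analyze_dataset <- function(entries, config = pipeline_config(),
                            verbose = FALSE) {
  measurements <- vector("list", length(entries))
  feat_rows <- vector("list", length(entries))
  img_rows <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    m <- analyze_image(e$map, e$condition, config)
    measurements[[k]] <- m
    cond <- e$condition
    meta <- data.frame(
      source_id = m$source_id,
      dha_concentration = if (!is.null(cond)) cond$dha_concentration else NA_real_,
      incubation_time = if (!is.null(cond)) cond$incubation_time else NA_real_,
      replicate = if (!is.null(cond)) cond$replicate else NA_integer_)
    if (nrow(m$features))
      feat_rows[[k]] <- cbind(meta[rep(1L, nrow(m$features)), , drop = FALSE],
                              m$features)
    img_rows[[k]] <- cbind(meta, data.frame(
      n_features = nrow(m$features), n_fibrils = m$n_fibrils,
      n_oligomers = m$n_oligomers, coverage_percent = m$coverage_percent,
      background_sigma_nm = m$model$sigma, fit_method = m$model$fit_method))
    if (verbose)
      message(sprintf("[%d/%d] %s: %d features, coverage %.2f%%",
                      k, length(entries), m$source_id, nrow(m$features),
                      m$coverage_percent))
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  images <- do.call(rbind, img_rows)
  rownames(images) <- NULL
  list(measurements = measurements, features = features, images = images)
}

#' Analyze images listed in a manifest
#'
#' File-based counterpart of [analyze_dataset()]: reads a manifest CSV
#' (columns `source_id`, `file`, `dha_concentration`, `incubation_time`,
#' `replicate`, `pixel_size_nm`) and analyzes each referenced image.
#' Manifest rows whose file is missing are skipped with a warning rather
#' than aborting the run.
#'
#' @param manifest_path manifest CSV path; image paths are resolved
#'   relative to its directory.
#' @param config a [pipeline_config()].
#' @param verbose log progress to stderr.
#' @return as [analyze_dataset()].
#' @export
analyze_manifest <- function(manifest_path, config = pipeline_config(),
                             verbose = FALSE) {
  man <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  entries <- list()
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) {
      warning("manifest file missing, skipped: ", man$file[i], call. = FALSE)
      next
    }
    ps <- if ("pixel_size_nm" %in% names(man)) man$pixel_size_nm[i]
    else config$pixel_size
    entries[[length(entries) + 1L]] <- list(
      map = read_height_map(path, pixel_size = ps,
                            source_id = man$source_id[i]),
      condition = condition_label(man$dha_concentration[i],
                                  man$incubation_time[i], man$replicate[i]))
  }
  if (length(entries) == 0L) stop("no readable images in manifest")
  analyze_dataset(entries, config, verbose = verbose)
}

#' Summarize an analyzed dataset per condition
#'
#' Groups the measurements by (DHA concentration, incubation time) and
#' runs [summarize_condition()] on each group.
#'
#' @param result output of [analyze_dataset()].
#' @param kde_points KDE grid points.
#' @return list of `condition_summary` objects, ordered by time then
#'   concentration.
#' @export
summarize_dataset <- function(result, kde_points = 128L) {
  keys <- vapply(result$measurements, function(m)
    paste(m$condition$dha_concentration, m$condition$incubation_time),
    character(1))
  groups <- split(result$measurements, keys)
  sums <- lapply(groups, summarize_condition, kde_points = kde_points)
  ord <- order(vapply(sums, `[[`, numeric(1), "incubation_time"),
               vapply(sums, `[[`, numeric(1), "dha_concentration"))
  unname(sums[ord])
}

#' Write result tables
#'
#' CSV writers for the per-feature and per-image tables and a JSON writer
#' for condition summaries (KDE included). Output is deterministic for a
#' fixed input.
#'
#' @param result output of [analyze_dataset()].
#' @param path output file.
#' @export
write_feature_csv <- function(result, path) {
  utils::write.csv(result$features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
write_image_csv <- function(result, path) {
  utils::write.csv(result$images, path, row.names = FALSE)
  invisible(path)
}

#' @param summaries list of `condition_summary` objects.
#' @rdname write_feature_csv
#' @export
write_summary_json <- function(summaries, path) {
  out <- lapply(summaries, function(s) {
    s <- unclass(s)
    if (!is.null(s$length_kde)) s$length_kde <- as.list(s$length_kde)
    s
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compare pipeline output against generator ground truth
#'
#' For a dataset produced by [generate_condition_grid()] and analyzed by
#' [analyze_dataset()], computes per-condition recovery statistics: the
#' pipeline's pooled mean fibril length against the mean true contour
#' length of the generated fibrils, and the mean measured coverage against
#' the mean painted coverage.
#'
#' @param entries dataset from [generate_condition_grid()].
#' @param result output of [analyze_dataset()] on those entries.
#' @return data.frame, one row per condition, with `mean_length_measured`,
#'   `mean_length_true`, `length_err_pct`, `coverage_measured_pct`,
#'   `coverage_true_pct`, `coverage_err_abs_pct`.
#' @export
recovery_report <- function(entries, result) {
  key <- function(d, t) paste(d, t)
  cond_of <- vapply(entries, function(e)
    key(e$condition$dha_concentration, e$condition$incubation_time),
    character(1))
  sums <- summarize_dataset(result)
  rows <- lapply(sums, function(s) {
    kk <- key(s$dha_concentration, s$incubation_time)
    es <- entries[cond_of == kk]
    tl <- unlist(lapply(es, function(e) {
      tt <- e$truth$objects
      tt$true_length_nm[tt$kind == "fibril" & !tt$clipped]
    }))
    tc <- 100 * mean(vapply(es, function(e) e$truth$coverage_fraction,
                            numeric(1)))
    data.frame(
      dha_concentration = s$dha_concentration,
      incubation_time = s$incubation_time,
      n_fibrils_measured = s$n_fibrils,
      n_fibrils_true = length(tl),
      mean_length_measured = s$mean_length,
      mean_length_true = mean(tl),
      length_err_pct = 100 * (s$mean_length - mean(tl)) / mean(tl),
      coverage_measured_pct = s$mean_coverage,
      coverage_true_pct = tc,
      coverage_err_abs_pct = s$mean_coverage - tc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
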