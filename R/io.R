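read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(x) > 1L) {
      stop("expected a single-channel 2-D image, got a ", length(x),
           "-directory TIFF stack: ", path)
    }
    bits <- attr(x[[1]], "bits.per.sample")
    x <- if (!is.null(bits) && bits <= 16L) {
      # integer TIFF: recover the stored integers exactly
      tiff::readTIFF(path, as.is = TRUE)
    } else {
      x[[1]]  # 32-bit TIFFs are float; values are already real
    }
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    x <- x * (2^depth - 1)
  } else {
    stop("unsupported raster format '", ext, "' (expected TIFF or PNG): ",
         path)
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else {
      stop("expected a single-channel grayscale image, got ", dim(x)[3],
           " channels: ", path)
    }
  }
  x
}

#' Read a grayscale intensity image
#'
#' Reads an 8/16-bit single-channel grayscale TIFF or PNG, preserving the
#' stored integer values exactly (exposed as doubles). Multi-channel
#' images and TIFF stacks are rejected with an explicit error; maximum
#' projection of Z-stacks is assumed to have happened upstream.
#'
#' @param path file path.
#' @return numeric matrix (rows = y, columns = x), values >= 0.
#' @export
read_intensity_image <- function(path) {
  x <- read_raster(path)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("intensity image must be finite and nonnegative: ", path)
  }
  x
}

#' Validate a label mask
#'
#' Reports the label set, any gaps in the label sequence, and which labels
#' touch the image border. Masks are never relabeled: gapped or
#' non-contiguous ids (as Cellpose can emit after manual edits) are
#' reported but preserved.
#'
#' @param mask integer matrix, 0 = background.
#' @return list with `n_cells`, `labels`, `gaps`, `border_labels`.
#' @export
validate_label_mask <- function(mask) {
  labels <- setdiff(sort(unique(as.vector(mask))), 0L)
  gaps <- if (length(labels)) setdiff(seq_len(max(labels)), labels) else
    integer(0)
  h <- nrow(mask)
  w <- ncol(mask)
  border <- unique(c(mask[1, ], mask[h, ], mask[, 1], mask[, w]))
  list(n_cells = length(labels), labels = labels, gaps = as.integer(gaps),
       border_labels = sort(setdiff(border, 0L)))
}

#' Read a cell label mask
#'
#' Reads an integer-valued single-channel raster in the Cellpose output
#' convention (0 = background, cells 1..N, gaps allowed). Non-integral
#' pixel values are an error. The returned mask carries a validation
#' report (see [validate_label_mask()]) in attribute `"report"`.
#'
#' @param path file path (TIFF or PNG).
#' @return integer matrix with attribute `"report"`.
#' @export
read_label_mask <- function(path) {
  x <- read_raster(path)
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < 0)) {
    stop("label mask must contain nonnegative integer values: ", path)
  }
  storage.mode(x) <- "integer"
  attr(x, "report") <- validate_label_mask(x)
  x
}

#' Write an intensity image or label mask as 16-bit grayscale TIFF
#'
#' Values must be integers in `[0, 65535]`; they are stored exactly, so a
#' write-then-read roundtrip is bitwise identical.
#'
#' @param x numeric or integer matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  v <- round(x)
  if (any(v < 0) || any(v > 65535)) {
    stop("values out of 16-bit range [0, 65535]")
  }
  ok <- tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  if (!isTRUE(ok == 1L)) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable knob of the pipeline with its default, so a
#' minimal configuration is the empty list. See the package vignette for
#' the rationale behind each default.
#'
#' @param threshold_method `"otsu"` (default) or `"quantile"`.
#' @param threshold_quantile foreground quantile in (0, 1) for the
#'   quantile method.
#' @param min_cluster_area,max_cluster_area inclusive size-filter bounds
#'   in pixels.
#' @param connectivity 4 or 8 (default) for cluster labeling.
#' @param weight_mode `"area"` (default) or `"intensity"` weighting of the
#'   per-cell polarity vector.
#' @param n_bins rose-plot bin count, >= 2.
#' @param reference_mode `"fixed_angle"` or `"target_point"`.
#' @param reference_angle_deg global reference direction (fixed_angle).
#' @param reference_point `(x, y)` target in pixels (target_point).
#' @param include_border_cells include cells touching the image edge
#'   (default TRUE; wound-margin cells are typically border-adjacent).
#' @param normalize_percentiles lower/upper clip percentiles for
#'   [log_normalize()].
#' @param cell_weight `"equal"` (default: one cell, one histogram unit) or
#'   `"weight_total"` (weight cells by total cluster size/intensity).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(threshold_method = c("otsu", "quantile"),
                            threshold_quantile = 0.95,
                            min_cluster_area = 4, max_cluster_area = 400,
                            connectivity = 8,
                            weight_mode = c("area", "intensity"),
                            n_bins = 8L,
                            reference_mode = c("fixed_angle", "target_point"),
                            reference_angle_deg = 0,
                            reference_point = NULL,
                            include_border_cells = TRUE,
                            normalize_percentiles = c(1, 99.9),
                            cell_weight = c("equal", "weight_total")) {
  cfg <- list(
    threshold_method = match.arg(threshold_method),
    threshold_quantile = threshold_quantile,
    min_cluster_area = min_cluster_area,
    max_cluster_area = max_cluster_area,
    connectivity = as.integer(connectivity),
    weight_mode = match.arg(weight_mode),
    n_bins = as.integer(n_bins),
    reference_mode = match.arg(reference_mode),
    reference_angle_deg = wrap_angle(reference_angle_deg),
    reference_point = if (is.null(reference_point)) NULL else
      as.numeric(reference_point),
    include_border_cells = isTRUE(include_border_cells),
    normalize_percentiles = as.numeric(normalize_percentiles),
    cell_weight = match.arg(cell_weight)
  )
  if (cfg$threshold_quantile <= 0 || cfg$threshold_quantile >= 1) {
    stop("threshold_quantile must be in (0, 1)")
  }
  if (cfg$min_cluster_area > cfg$max_cluster_area) {
    stop("min_cluster_area must be <= max_cluster_area")
  }
  if (!cfg$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (cfg$n_bins < 2L) stop("n_bins must be >= 2")
  if (cfg$reference_mode == "target_point" &&
      (is.null(cfg$reference_point) || length(cfg$reference_point) != 2L)) {
    stop("target_point mode requires a length-2 reference_point")
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file is a single flat document; fields not present fall back to the
#' [analysis_config()] defaults, so `{}` is a valid configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::fromJSON(path) else
    yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

reference_from_config <- function(config) {
  if (config$reference_mode == "fixed_angle") {
    reference_field("fixed_angle", angle_deg = config$reference_angle_deg)
  } else {
    reference_field("target_point", target = config$reference_point)
  }
}

#' Write pipeline results to disk
#'
#' Writes the per-cell results table as RFC-4180 CSV
#' (`<prefix>_cells.csv`) and a JSON summary (`<prefix>_summary.json`)
#' containing the histogram bin edges/counts/weights, the chi-square
#' statistic, df and p-value, the configuration echo, the run manifest and
#' the package version.
#'
#' @param results per-cell data.frame (pooled across fields, with a
#'   `field` column) as produced by [run_pipeline()].
#' @param histogram an [bin_angles()] result.
#' @param test a [chi_square_uniformity()] result.
#' @param path_prefix output path prefix.
#' @param config the [analysis_config()] used.
#' @param manifest optional run manifest list.
#' @return named character vector of the files written, invisibly.
#' @export
write_results <- function(results, histogram, test, path_prefix,
                          config = NULL, manifest = NULL) {
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  csv_path <- paste0(path_prefix, "_cells.csv")
  json_path <- paste0(path_prefix, "_summary.json")
  utils::write.csv(results, csv_path, row.names = FALSE, quote = TRUE)
  summary <- list(
    software = "punctapolar",
    version = as.character(utils::packageVersion("punctapolar")),
    n_cells = if (is.null(results)) 0L else nrow(results),
    histogram = list(
      n_bins = histogram$n_bins,
      bin_edges_deg = histogram$bin_edges_deg,
      bin_centers_deg = histogram$bin_centers_deg,
      counts = histogram$counts,
      weights = histogram$weights,
      total_cells = histogram$total_cells
    ),
    chi_square = list(
      statistic = test$statistic, df = test$df, p_value = test$p_value,
      expected_per_bin = test$expected_per_bin,
      low_expected_warning = test$low_expected_warning,
      defined = test$defined
    ),
    config = if (is.null(config)) NULL else unclass(config),
    manifest = manifest
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(cells = csv_path, summary = json_path))
}
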