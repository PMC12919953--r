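as_image_list <- function(x, reader) {
  if (is.matrix(x)) return(list(reader(NULL, x)))
  if (is.character(x)) return(lapply(x, function(p) reader(p, NULL)))
  if (is.list(x)) {
    return(lapply(x, function(e) {
      if (is.matrix(e)) reader(NULL, e) else reader(e, NULL)
    }))
  }
  stop("expected a matrix, a path, or a list of either")
}

#' Run the polarity quantification pipeline end to end
#'
#' For each image/mask pair: log-normalize, threshold, label clusters,
#' size-filter, assign clusters to cells and compute per-cell polarity
#' relative to the reference; then pool the defined cells across pairs,
#' bin them into a rose-plot histogram and run the chi-square uniformity
#' test. Optionally writes the per-cell CSV, the JSON summary and a rose
#' plot.
#'
#' @param images character vector of image paths, a numeric matrix, or a
#'   list of matrices/paths.
#' @param masks label masks, same forms and length as `images`.
#' @param config an [analysis_config()].
#' @param output_prefix optional path prefix; when given,
#'   `<prefix>_cells.csv`, `<prefix>_summary.json` and
#'   `<prefix>_rose.png` are written.
#' @return list with `results` (pooled per-cell table with a `field`
#'   column), `per_field` (per-field tables), `pooled` (defined cells used
#'   for the histogram), `histogram`, `test` and `manifest` (per-stage
#'   counts that reconcile: clusters found = kept + size-filtered +
#'   background-dropped; cells = defined + undefined + excluded).
#' @export
run_pipeline <- function(images, masks, config = analysis_config(),
                         output_prefix = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  imgs <- as_image_list(images, function(p, m) {
    if (is.null(p)) m else read_intensity_image(p)
  })
  msks <- as_image_list(masks, function(p, m) {
    if (is.null(p)) m else read_label_mask(p)
  })
  if (length(imgs) != length(msks)) {
    stop("got ", length(imgs), " images but ", length(msks), " masks")
  }
  if (length(imgs) == 0L) stop("need at least one image/mask pair")
  reference <- reference_from_config(config)
  per_field <- vector("list", length(imgs))
  counts <- list(cells = 0L, clusters_found = 0L, clusters_kept = 0L,
                 size_filtered = 0L, background_dropped = 0L,
                 defined = 0L, undefined = 0L, excluded = 0L)
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]
    mask <- msks[[i]]
    if (!identical(dim(img), dim(mask))) {
      stop("field ", i, ": image shape ", paste(dim(img), collapse = "x"),
           " does not match mask shape ", paste(dim(mask), collapse = "x"))
    }
    norm <- log_normalize(img, config$normalize_percentiles)
    bin <- threshold_image(norm, config$threshold_method,
                           config$threshold_quantile)
    cl <- find_clusters(bin, norm, config$connectivity)
    clf <- filter_clusters_by_size(cl, config$min_cluster_area,
                                   config$max_cluster_area)
    cla <- assign_clusters_to_cells(clf, mask)
    pol <- compute_polarities(cla, mask, img, reference,
                              weight_mode = config$weight_mode,
                              include_border_cells =
                                config$include_border_cells)
    counts$cells <- counts$cells + nrow(pol)
    counts$clusters_found <- counts$clusters_found + nrow(cl)
    counts$clusters_kept <- counts$clusters_kept + nrow(cla)
    counts$size_filtered <- counts$size_filtered + attr(clf, "n_removed")
    counts$background_dropped <- counts$background_dropped +
      attr(cla, "n_dropped_background")
    counts$defined <- counts$defined + sum(pol$defined & !pol$excluded)
    counts$excluded <- counts$excluded + sum(pol$excluded)
    counts$undefined <- counts$undefined + sum(!pol$defined & !pol$excluded)
    per_field[[i]] <- pol
  }
  pooled <- pool_fields(per_field, cell_weight = config$cell_weight)
  histogram <- bin_angles(pooled$relative_angle_deg, pooled$weight,
                          config$n_bins)
  test <- chi_square_uniformity(histogram)
  results <- do.call(rbind, lapply(seq_along(per_field), function(i) {
    cbind(field = rep(i, nrow(per_field[[i]])), per_field[[i]])
  }))
  manifest <- list(
    n_fields = length(imgs),
    counts = counts,
    per_field_defined = attr(pooled, "per_field_n"),
    config = unclass(config),
    version = as.character(utils::packageVersion("punctapolar"))
  )
  if (!is.null(output_prefix)) {
    files <- write_results(results, histogram, test, output_prefix,
                           config = config, manifest = manifest)
    render_rose_plot(histogram, test, paste0(output_prefix, "_rose.png"))
    manifest$output_files <- c(files, rose = paste0(output_prefix,
                                                    "_rose.png"))
  }
  out <- list(results = results, per_field = per_field, pooled = pooled,
              histogram = histogram, test = test, manifest = manifest)
  invisible(out)
}

#' Generate synthetic fields and write them to disk
#'
#' Writes, per field, the intensity image and label mask as 16-bit TIFF,
#' the ground-truth puncta table as CSV (cell_id, punctum_index,
#' angle_deg, x, y, reference_angle_deg), and one JSON sidecar with the
#' field specification and the derived per-field seeds.
#'
#' @param spec a [field_spec()].
#' @param reference optional [reference_field()] (default: fixed angle at
#'   `spec$bias_mu`).
#' @param n_fields number of fields, >= 1.
#' @param out_dir output directory (created if needed).
#' @return data.frame listing the files written per field, invisibly.
#' @export
run_simulation <- function(spec, reference = NULL, n_fields = 1L,
                           out_dir = ".") {
  stopifnot(inherits(spec, "field_spec"))
  if (n_fields < 1L) stop("n_fields must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fields <- generate_dataset(spec, reference, n_fields)
  seeds <- spec$seed + seq_len(n_fields) - 1L
  message("derived per-field seeds: ", paste(seeds, collapse = ", "))
  files <- lapply(seq_along(fields), function(i) {
    base <- file.path(out_dir, sprintf("field%02d", i))
    img <- pmin(round(fields[[i]]$image), 65535)
    write_image_tiff(img, paste0(base, "_image.tif"))
    write_image_tiff(fields[[i]]$mask, paste0(base, "_mask.tif"))
    utils::write.csv(fields[[i]]$truth$puncta, paste0(base, "_truth.csv"),
                     row.names = FALSE)
    data.frame(field = i, seed = seeds[i],
               image = paste0(base, "_image.tif"),
               mask = paste0(base, "_mask.tif"),
               truth = paste0(base, "_truth.csv"))
  })
  files <- do.call(rbind, files)
  sidecar <- file.path(out_dir, "simulation_spec.json")
  jsonlite::write_json(
    list(spec = unclass(spec),
         reference = if (is.null(reference)) NULL else unclass(reference),
         n_fields = n_fields, derived_seeds = seeds),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(files)
}

#' Per-cell polarity angles from the generator's angular model
#'
#' Draws the ground-truth angular layer of the synthetic generator without
#' rasterizing images: each cell receives a Poisson number of puncta whose
#' angles are von Mises distributed about the reference (here 0 degrees),
#' and the cell's polarity angle is the direction of the mean unit vector.
#' Cells with no puncta or a resultant below the degeneracy tolerance are
#' dropped, as in the full pipeline.
#'
#' @param n_cells number of cells.
#' @param mean_puncta_per_cell Poisson mean of puncta per cell.
#' @param kappa von Mises concentration (0 = uniform).
#' @param degeneracy_tol resultant magnitude below which a cell is
#'   undefined.
#' @return numeric vector of defined relative polarity angles in degrees.
#' @export
simulate_polarity_angles <- function(n_cells, mean_puncta_per_cell = 6,
                                     kappa = 0, degeneracy_tol = 1e-6) {
  np <- stats::rpois(n_cells, mean_puncta_per_cell)
  total <- sum(np)
  if (total == 0L) return(numeric(0))
  a <- rvonmises(total, 0, kappa) * pi / 180
  cell <- rep(seq_len(n_cells), np)
  C <- rowsum(cos(a), cell)
  S <- rowsum(sin(a), cell)
  m <- np[np > 0L]
  R <- sqrt(C^2 + S^2) / m
  keep <- R >= degeneracy_tol
  wrap_angle(atan2(S[keep], C[keep]) * 180 / pi)
}

#' Calibration of the uniformity test on simulated polarity angles
#'
#' Repeatedly simulates per-cell polarity angles under the generator's
#' angular model and records how often the chi-square uniformity test
#' rejects at level `alpha`. With `kappa = 0` this measures the type-I
#' error rate (should sit near `alpha`); with `kappa > 0` it measures
#' power.
#'
#' @param n_reps number of simulated replicates.
#' @param n_cells cells per replicate.
#' @param mean_puncta_per_cell Poisson mean of puncta per cell.
#' @param kappa von Mises concentration of the puncta bias.
#' @param alpha test level.
#' @param n_bins histogram bin count.
#' @param seed integer seed.
#' @return list with `rejection_rate`, `n_reps`, `alpha`, `kappa` and the
#'   vector of `p_values`.
#' @export
calibrate_uniformity <- function(n_reps = 500, n_cells = 200,
                                 mean_puncta_per_cell = 6, kappa = 0,
                                 alpha = 0.05, n_bins = 8L, seed = 1L) {
  set.seed(seed)
  pvals <- vapply(seq_len(n_reps), function(i) {
    ang <- simulate_polarity_angles(n_cells, mean_puncta_per_cell, kappa)
    chi_square_uniformity(bin_angles(ang, n_bins = n_bins))$p_value
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), n_reps = n_reps, alpha = alpha,
       kappa = kappa, p_values = pvals)
}
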