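#' Reference (force) direction field
#'
#' The direction against which per-cell polarity is measured. In
#' `fixed_angle` mode every cell shares one global direction (e.g. toward
#' the dorsal midline of a neural plate); in `target_point` mode the
#' reference at each cell points from the cell centroid toward a fixed
#' point (e.g. a wound site), so 0 degrees of relative angle always means
#' "toward the target".
#'
#' @param mode `"fixed_angle"` or `"target_point"`.
#' @param angle_deg reference direction in degrees (fixed_angle mode).
#' @param target length-2 numeric `(x, y)` in pixels (target_point mode).
#' @return an object of class `reference_field`.
#' @export
reference_field <- function(mode = c("fixed_angle", "target_point"),
                            angle_deg = 0, target = NULL) {
  mode <- match.arg(mode)
  if (mode == "target_point") {
    if (is.null(target) || length(target) != 2L || any(!is.finite(target))) {
      stop("target_point mode requires a finite (x, y) target")
    }
    out <- list(mode = mode, target = as.numeric(target))
  } else {
    out <- list(mode = mode, angle_deg = wrap_angle(angle_deg))
  }
  class(out) <- "reference_field"
  out
}

#' Reference direction at a cell
#'
#' @param reference a [reference_field()].
#' @param cell_centroid length-2 numeric `(x, y)`.
#' @return angle in degrees in (-180, 180]; NA when the target coincides
#'   with the centroid (undefined reference; the cell is excluded
#'   downstream).
#' @export
reference_angle_at <- function(reference, cell_centroid) {
  stopifnot(inherits(reference, "reference_field"))
  if (reference$mode == "fixed_angle") {
    return(reference$angle_deg)
  }
  dx <- reference$target[1] - cell_centroid[1]
  dy <- reference$target[2] - cell_centroid[2]
  if (dx == 0 && dy == 0) return(NA_real_)
  angle_of(dx, dy)
}

#' Centroid of one labeled cell
#'
#' Unweighted mean of the cell's pixel coordinates (x = column, y = row,
#' both 1-based).
#'
#' @param mask integer label mask.
#' @param cell_id label present in the mask.
#' @return length-2 numeric `(x, y)`.
#' @export
cell_centroid <- function(mask, cell_id) {
  idx <- which(mask == cell_id)
  if (!length(idx)) stop("label ", cell_id, " absent from mask")
  h <- nrow(mask)
  c(x = mean((idx - 1L) %/% h + 1L), y = mean((idx - 1L) %% h + 1L))
}

#' Centroids of all cells in a label mask
#'
#' @param mask integer label mask (0 = background).
#' @return data.frame with cell_id, x, y, area (pixels) and `border`
#'   (whether the cell touches the image edge).
#' @export
cell_centroids <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  idx <- which(mask > 0L)
  if (!length(idx)) {
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), border = logical(0)))
  }
  lab <- mask[idx]
  col <- (idx - 1L) %/% h + 1L
  row <- (idx - 1L) %% h + 1L
  sums_x <- rowsum(as.numeric(col), lab)
  sums_y <- rowsum(as.numeric(row), lab)
  n <- as.vector(table(lab))
  on_border <- rowsum(as.numeric(row == 1L | row == h | col == 1L | col == w),
                      lab)
  ids <- as.integer(rownames(sums_x))
  data.frame(cell_id = ids, x = as.vector(sums_x) / n,
             y = as.vector(sums_y) / n, area = as.integer(n),
             border = as.vector(on_border) > 0)
}

#' Weighted polarity vector of one cell
#'
#' For each cluster belonging to the cell, the unit vector from the cell
#' centroid to the cluster centroid is formed; the polarity vector is the
#' weighted mean of these unit vectors, with weights either cluster pixel
#' areas or integrated intensities. Its magnitude is therefore in
#' `[0, 1]`. A cluster whose centroid coincides with the cell centroid is
#' skipped; a cell with no usable clusters or a near-zero resultant
#' (`|v| < degeneracy_tol`) is flagged `defined = FALSE` rather than
#' assigned a noise angle.
#'
#' @param centroid length-2 numeric `(x, y)` cell centroid.
#' @param clusters data.frame of this cell's clusters with columns `x`,
#'   `y`, `area`, `integrated_intensity` (as from [find_clusters()]).
#' @param weight_mode `"area"` or `"intensity"`.
#' @param degeneracy_tol resultant magnitude below which the polarity is
#'   reported undefined.
#' @return list with `dx`, `dy`, `magnitude`, `angle_deg` (NA when
#'   undefined), `weight_total`, `n_clusters`, `n_skipped`, `defined`.
#' @export
cell_polarity_vector <- function(centroid, clusters,
                                 weight_mode = c("area", "intensity"),
                                 degeneracy_tol = 1e-6) {
  weight_mode <- match.arg(weight_mode)
  empty <- list(dx = NA_real_, dy = NA_real_, magnitude = NA_real_,
                angle_deg = NA_real_, weight_total = 0,
                n_clusters = 0L, n_skipped = 0L, defined = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0L) return(empty)
  ux <- clusters$x - centroid[1]
  uy <- clusters$y - centroid[2]
  len <- sqrt(ux^2 + uy^2)
  keep <- len > 1e-12
  n_skipped <- sum(!keep)
  if (!any(keep)) {
    empty$n_skipped <- n_skipped
    return(empty)
  }
  w <- switch(weight_mode, area = clusters$area,
              intensity = clusters$integrated_intensity)
  w <- w[keep]
  if (sum(w) <= 0) {
    empty$n_clusters <- sum(keep)
    empty$n_skipped <- n_skipped
    return(empty)
  }
  ux <- ux[keep] / len[keep]
  uy <- uy[keep] / len[keep]
  dx <- sum(w * ux) / sum(w)
  dy <- sum(w * uy) / sum(w)
  mag <- sqrt(dx^2 + dy^2)
  defined <- mag >= degeneracy_tol
  list(dx = dx, dy = dy, magnitude = mag,
       angle_deg = if (defined) angle_of(dx, dy) else NA_real_,
       weight_total = sum(w), n_clusters = sum(keep),
       n_skipped = n_skipped, defined = defined)
}

#' Per-cell polarity table for one field
#'
#' Combines cell-assigned clusters, the label mask, the raw image and the
#' reference field into one row per cell present in the mask: centroid,
#' cluster count, polarity vector and angle, reference and relative
#' angles, raw mean intensity, total cluster area/weight and an exclusion
#' flag with reason. Cells touching the image border are included by
#' default.
#'
#' @param clusters cell-assigned cluster table from
#'   [assign_clusters_to_cells()].
#' @param mask integer label mask.
#' @param image raw (pre-normalization) intensity image, for per-cell mean
#'   intensity; may be NULL to skip that column.
#' @param reference a [reference_field()].
#' @param weight_mode `"area"` or `"intensity"`.
#' @param include_border_cells if FALSE, cells touching the image edge are
#'   excluded (reason `"border"`).
#' @param degeneracy_tol see [cell_polarity_vector()].
#' @return data.frame (one row per cell) with attribute `"config"` echoing
#'   the analysis settings, used by [pool_fields()] to refuse pooling
#'   across inconsistent runs.
#' @export
compute_polarities <- function(clusters, mask, image = NULL, reference,
                               weight_mode = c("area", "intensity"),
                               include_border_cells = TRUE,
                               degeneracy_tol = 1e-6) {
  weight_mode <- match.arg(weight_mode)
  cents <- cell_centroids(mask)
  mean_int <- if (is.null(image)) NULL else cell_mean_intensity(image, mask)
  n <- nrow(cents)
  out <- data.frame(
    cell_id = cents$cell_id, centroid_x = cents$x, centroid_y = cents$y,
    cell_area = cents$area, border = cents$border,
    n_clusters = integer(n), polarity_dx = rep(NA_real_, n),
    polarity_dy = rep(NA_real_, n), polarity_magnitude = rep(NA_real_, n),
    polarity_angle_deg = rep(NA_real_, n),
    reference_angle_deg = rep(NA_real_, n),
    relative_angle_deg = rep(NA_real_, n),
    weight_total = numeric(n), total_cluster_area = numeric(n),
    mean_intensity = rep(NA_real_, n), defined = logical(n),
    excluded = logical(n), exclude_reason = character(n),
    stringsAsFactors = FALSE
  )
  if (!is.null(mean_int)) {
    out$mean_intensity <- mean_int$mean_intensity[
      match(out$cell_id, mean_int$cell_id)]
  }
  for (i in seq_len(n)) {
    cid <- out$cell_id[i]
    if (!include_border_cells && out$border[i]) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "border"
      next
    }
    ref_ang <- reference_angle_at(reference,
                                  c(out$centroid_x[i], out$centroid_y[i]))
    out$reference_angle_deg[i] <- ref_ang
    if (is.na(ref_ang)) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "undefined_reference"
      next
    }
    cl <- clusters[!is.na(clusters$cell_id) & clusters$cell_id == cid, ,
                   drop = FALSE]
    pv <- cell_polarity_vector(c(out$centroid_x[i], out$centroid_y[i]), cl,
                               weight_mode, degeneracy_tol)
    out$n_clusters[i] <- pv$n_clusters
    out$polarity_dx[i] <- pv$dx
    out$polarity_dy[i] <- pv$dy
    out$polarity_magnitude[i] <- pv$magnitude
    out$polarity_angle_deg[i] <- pv$angle_deg
    out$weight_total[i] <- pv$weight_total
    out$total_cluster_area[i] <- if (nrow(cl)) sum(cl$area) else 0
    out$defined[i] <- pv$defined
    if (pv$defined) {
      out$relative_angle_deg[i] <- relative_angle(pv$angle_deg, ref_ang)
    }
  }
  attr(out, "config") <- list(
    weight_mode = weight_mode, reference = unclass(reference),
    include_border_cells = include_border_cells,
    degeneracy_tol = degeneracy_tol)
  out
}

#' Pool per-cell polarities across fields
#'
#' Concatenates the defined, non-excluded cells of several fields (e.g.
#' several embryos) for a single pooled rose plot and uniformity test,
#' mirroring pooled-embryo rose plots. Fields must have been analyzed with
#' the same configuration. By default each cell contributes weight 1 to
#' the histogram (so fields with brighter or larger puncta do not
#' dominate); `cell_weight = "weight_total"` instead weights each cell by
#' its total cluster size or intensity.
#'
#' @param results_list list of tables from [compute_polarities()].
#' @param cell_weight `"equal"` or `"weight_total"`.
#' @return data.frame with field, cell_id, relative_angle_deg, weight;
#'   attribute `"per_field_n"` gives the number of contributing cells per
#'   field (zero-cell fields are still listed).
#' @export
pool_fields <- function(results_list, cell_weight = c("equal", "weight_total")) {
  cell_weight <- match.arg(cell_weight)
  stopifnot(length(results_list) >= 1L)
  configs <- lapply(results_list, attr, "config")
  ref_cfg <- configs[[1]]
  same <- vapply(configs, function(cf) {
    identical(cf[setdiff(names(cf), "reference")],
              ref_cfg[setdiff(names(ref_cfg), "reference")]) &&
      identical(cf$reference$mode, ref_cfg$reference$mode)
  }, logical(1))
  if (!all(same)) {
    stop("cannot pool fields analyzed with different configurations")
  }
  pieces <- vector("list", length(results_list))
  per_field_n <- integer(length(results_list))
  for (i in seq_along(results_list)) {
    r <- results_list[[i]]
    keep <- r$defined & !r$excluded
    per_field_n[i] <- sum(keep)
    if (!any(keep)) next
    wts <- if (cell_weight == "equal") rep(1, sum(keep)) else
      r$weight_total[keep]
    pieces[[i]] <- data.frame(field = i, cell_id = r$cell_id[keep],
                              relative_angle_deg = r$relative_angle_deg[keep],
                              weight = wts)
  }
  pooled <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(pooled)) {
    pooled <- data.frame(field = integer(0), cell_id = integer(0),
                         relative_angle_deg = numeric(0), weight = numeric(0))
  }
  attr(pooled, "per_field_n") <- per_field_n
  attr(pooled, "config") <- ref_cfg
  pooled
}
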