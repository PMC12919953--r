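#' Log-transform and percentile-normalize an intensity image
#'
#' Applies `log(1 + I)` and then a linear rescale so that the lower/upper
#' clip percentiles of the log image map to 0/1, clipping to `[0, 1]`.
#' Percentile clipping (defaults 1st and 99.9th) makes the normalization
#' robust to hot pixels. Pixel rank order is weakly preserved. A constant
#' image normalizes to all zeros (documented degenerate result).
#'
#' @param image nonnegative numeric matrix.
#' @param percentiles length-2 numeric, lower and upper clip percentiles
#'   in `[0, 100]`.
#' @return numeric matrix in `[0, 1]` with the same shape.
#' @export
log_normalize <- function(image, percentiles = c(1, 99.9)) {
  stopifnot(length(percentiles) == 2L, percentiles[1] < percentiles[2])
  if (any(image < 0)) stop("intensity image must be nonnegative")
  lg <- log1p(image)
  qs <- stats::quantile(lg, probs = percentiles / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  out <- (lg - qs[1]) / (qs[2] - qs[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Otsu threshold over a 256-level histogram
#'
#' Exhaustively maximizes the between-class variance over the 256 evenly
#' spaced gray levels of a `[0, 1]` image. Ties are broken toward the
#' lowest level. Returns the threshold value (upper edge of the chosen
#' level's bin, so `value > threshold` selects exactly the levels above
#' the split); a constant image yields `max(image)`, i.e. an empty
#' foreground.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @return threshold value with attribute `"level"` (the 0-based histogram
#'   level below the split, NA for a constant image).
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(image)
  lev <- pmin(as.integer(floor(v * 256)), 255L)
  counts <- tabulate(lev + 1L, nbins = 256L)
  n <- length(v)
  p <- counts / n
  mids <- (0:255 + 0.5) / 256
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  k <- 1:255
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, 0)
  if (max(sigma_b) <= 0) {
    thr <- max(v)
    attr(thr, "level") <- NA_integer_
    return(thr)
  }
  kbest <- which.max(sigma_b)   # first maximum: lowest level wins ties
  thr <- kbest / 256
  attr(thr, "level") <- kbest - 1L
  thr
}

#' Threshold a normalized image into a binary puncta mask
#'
#' `method = "otsu"` maximizes between-class variance over a 256-level
#' histogram; `method = "quantile"` puts pixels strictly above the given
#' intensity quantile in the foreground. In both cases foreground means
#' `value > threshold`, so a constant image yields an empty mask.
#'
#' @param image numeric matrix in `[0, 1]` (output of [log_normalize()]).
#' @param method `"otsu"` or `"quantile"`.
#' @param quantile foreground quantile in (0, 1), used by the quantile
#'   method.
#' @return logical matrix with attribute `"threshold"`.
#' @export
threshold_image <- function(image, method = c("otsu", "quantile"),
                            quantile = 0.95) {
  method <- match.arg(method)
  thr <- switch(method,
    otsu = as.numeric(otsu_threshold(image)),
    quantile = {
      if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
      stats::quantile(as.vector(image), probs = quantile, names = FALSE)
    })
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Label connected foreground components as puncta clusters
#'
#' Connected components of the binary mask under 4- or 8-connectivity
#' (default 8: puncta are blobs and diagonal contact should not split
#' them), built as an igraph pixel-adjacency graph. Each cluster gets its
#' pixel area, subpixel centroid (unweighted mean of member pixel
#' coordinates) and integrated intensity summed over the pre-threshold
#' normalized image. Cluster ids are assigned in raster-scan order of each
#' component's first pixel, so labeling is deterministic.
#'
#' @param mask logical matrix from [threshold_image()].
#' @param image numeric matrix the mask came from (for integrated
#'   intensity); same shape.
#' @param connectivity 4 or 8.
#' @return data.frame with cluster_id, cell_id (NA, see
#'   [assign_clusters_to_cells()]), x, y, area, integrated_intensity and a
#'   list column `pixels` of member linear indices (column-major).
#' @export
find_clusters <- function(mask, image, connectivity = 8) {
  stopifnot(identical(dim(mask), dim(image)), connectivity %in% c(4, 8))
  h <- nrow(mask)
  w <- ncol(mask)
  idx <- which(mask)
  empty <- data.frame(cluster_id = integer(0), cell_id = integer(0),
                      x = numeric(0), y = numeric(0), area = integer(0),
                      integrated_intensity = numeric(0))
  empty$pixels <- list()
  if (!length(idx)) return(empty)
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ed <- list()
  for (o in offs) {
    r2 <- row + o[1]
    c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nidx <- (c2[ok] - 1L) * h + r2[ok]
    nb <- vid[nidx]
    hit <- nb > 0L
    if (any(hit)) {
      ed[[length(ed) + 1L]] <- rbind(vid[idx[ok]][hit], nb[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ed)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, ed)))
  }
  memb <- igraph::components(g)$membership
  # relabel components by first member pixel in raster (column-major) order
  first_px <- vapply(split(idx, memb), min, numeric(1))
  new_id <- match(memb, as.integer(names(sort(first_px))))
  px_split <- split(idx, new_id)
  area <- lengths(px_split)
  cx <- vapply(split(as.numeric(col), new_id), mean, numeric(1))
  cy <- vapply(split(as.numeric(row), new_id), mean, numeric(1))
  ii <- vapply(px_split, function(p) sum(image[p]), numeric(1))
  out <- data.frame(cluster_id = seq_along(px_split), cell_id = NA_integer_,
                    x = as.vector(cx), y = as.vector(cy),
                    area = as.integer(area),
                    integrated_intensity = as.vector(ii))
  out$pixels <- unname(px_split)
  out
}

#' Filter clusters by pixel area
#'
#' Keeps clusters with `min_area <= area <= max_area` (inclusive on both
#' ends), preserving order. The defaults (4 and 400 px) exclude
#' single-pixel noise and junction-scale smears.
#'
#' @param clusters table from [find_clusters()].
#' @param min_area,max_area inclusive area bounds in pixels.
#' @return the filtered table; attribute `"n_removed"` reports how many
#'   clusters were dropped.
#' @export
filter_clusters_by_size <- function(clusters, min_area = 4, max_area = 400) {
  stopifnot(min_area <= max_area)
  keep <- clusters$area >= min_area & clusters$area <= max_area
  out <- clusters[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assign clusters to cells by pixel plurality
#'
#' Each cluster is assigned to the cell label holding the plurality of its
#' pixels; ties break toward the smaller label. Clusters whose plurality
#' label is background (0) are dropped and counted.
#'
#' @param clusters table from [find_clusters()] /
#'   [filter_clusters_by_size()].
#' @param mask integer label mask, same shape as the source image.
#' @return the table with `cell_id` filled in, background-plurality
#'   clusters removed; attribute `"n_dropped_background"` counts the
#'   removals.
#' @export
assign_clusters_to_cells <- function(clusters, mask) {
  n <- nrow(clusters)
  if (n == 0L) {
    out <- clusters
    attr(out, "n_dropped_background") <- 0L
    return(out)
  }
  assigned <- integer(n)
  for (i in seq_len(n)) {
    labs <- mask[clusters$pixels[[i]]]
    tab <- table(labs)
    winners <- as.integer(names(tab)[tab == max(tab)])
    assigned[i] <- min(winners)   # tie toward the smaller label
  }
  keep <- assigned > 0L
  out <- clusters[keep, , drop = FALSE]
  out$cell_id <- assigned[keep]
  attr(out, "n_dropped_background") <- sum(!keep)
  out
}

#' Per-cell mean raw intensity
#'
#' Arithmetic mean of the raw (pre-normalization) image over each cell's
#' pixels, for acquisition-scaled group comparisons of signal level.
#'
#' @param image numeric matrix (raw intensities).
#' @param mask integer label mask, same shape.
#' @return data.frame with cell_id and mean_intensity, one row per label
#'   present in the mask.
#' @export
cell_mean_intensity <- function(image, mask) {
  stopifnot(identical(dim(image), dim(mask)))
  idx <- which(mask > 0L)
  if (!length(idx)) {
    return(data.frame(cell_id = integer(0), mean_intensity = numeric(0)))
  }
  lab <- mask[idx]
  m <- rowsum(image[idx], lab) / as.vector(table(lab))
  data.frame(cell_id = as.integer(rownames(m)), mean_intensity = as.vector(m))
}
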