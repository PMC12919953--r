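#' Bin relative angles into a circular (rose-plot) histogram
#'
#' Bins have width `360 / n_bins` with the first bin centered on 0 degrees
#' (the reference direction), i.e. edges at +/- `180 / n_bins`. Bins are
#' left-closed, right-open; an angle exactly on an interior edge falls in
#' the higher bin, and the wrap seam at +/-180 closes the circle. Both
#' unweighted counts and weighted mass are accumulated; the chi-square
#' test uses the counts, the weights affect only rendering.
#'
#' @param angles_deg numeric vector of relative angles in (-180, 180].
#' @param weights optional per-angle weights (default 1 per cell).
#' @param n_bins number of bins, >= 2 (default 8, i.e. 45-degree sectors).
#' @return object of class `angular_histogram`: list with `n_bins`,
#'   `bin_edges_deg` (length `n_bins + 1`, ascending, spanning 360),
#'   `bin_centers_deg`, `counts`, `weights`, `total_cells`.
#' @export
bin_angles <- function(angles_deg, weights = NULL, n_bins = 8L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (is.null(weights)) {
    weights <- rep(1, length(angles_deg))
  } else {
    weights <- weights[seq_along(angles_deg)]
  }
  stopifnot(length(weights) == length(angles_deg))
  width <- 360 / n_bins
  half <- width / 2
  edges <- -half + (0:n_bins) * width
  centers <- wrap_angle(edges[-length(edges)] + half)
  counts <- integer(n_bins)
  wsum <- numeric(n_bins)
  if (length(angles_deg)) {
    shifted <- (angles_deg + half) %% 360
    bin <- pmin(as.integer(floor(shifted / width + 1e-9)) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    agg <- rowsum(weights, bin)
    wsum[as.integer(rownames(agg))] <- as.vector(agg)
  }
  out <- list(n_bins = as.integer(n_bins), bin_edges_deg = edges,
              bin_centers_deg = centers, counts = counts, weights = wsum,
              total_cells = length(angles_deg))
  class(out) <- "angular_histogram"
  out
}

#' Chi-square test of angular uniformity
#'
#' Pearson chi-square goodness-of-fit of the unweighted per-cell bin
#' counts against the uniform circular distribution: with `O_b` observed
#' and `E = n / n_bins` expected per bin, the statistic is
#' `sum((O_b - E)^2 / E)` on `n_bins - 1` degrees of freedom; the p-value
#' is the upper tail of the chi-square distribution. One cell is one
#' observation regardless of histogram weighting, keeping the test's
#' distributional assumptions intact. A warning flag is set when the
#' expected count per bin falls below 5.
#'
#' @param histogram an [bin_angles()] result.
#' @return object of class `uniformity_test`: list with `statistic`, `df`,
#'   `p_value`, `expected_per_bin`, `low_expected_warning`, `n`,
#'   `defined`. With zero pooled cells the test is undefined (`defined =
#'   FALSE`, NA statistic and p).
#' @export
chi_square_uniformity <- function(histogram) {
  stopifnot(inherits(histogram, "angular_histogram"))
  k <- histogram$n_bins
  n <- histogram$total_cells
  if (n < 1L) {
    out <- list(statistic = NA_real_, df = k - 1L, p_value = NA_real_,
                expected_per_bin = 0, low_expected_warning = FALSE,
                n = 0L, defined = FALSE)
    class(out) <- "uniformity_test"
    return(out)
  }
  e <- n / k
  stat <- sum((histogram$counts - e)^2 / e)
  out <- list(statistic = stat, df = k - 1L,
              p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
              expected_per_bin = e, low_expected_warning = e < 5,
              n = n, defined = TRUE)
  class(out) <- "uniformity_test"
  out
}

#' @export
print.uniformity_test <- function(x, ...) {
  if (!x$defined) {
    cat("Chi-square uniformity test: undefined (no pooled cells)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Chi-square uniformity test: X2 = %.4g, df = %d, p = %.4g (n = %d)\n",
    x$statistic, x$df, x$p_value, x$n))
  if (x$low_expected_warning) {
    cat("  warning: expected count per bin < 5\n")
  }
  invisible(x)
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("Angular histogram: %d bins of %.3g deg, n = %d cells\n",
              x$n_bins, 360 / x$n_bins, x$total_cells))
  print(data.frame(center_deg = x$bin_centers_deg, count = x$counts,
                   weight = x$weights))
  invisible(x)
}

#' Render a rose plot of an angular histogram
#'
#' Polar wedge plot with 0 degrees at the right (toward the reference
#' direction) and angles increasing counterclockwise on the page (image
#' y-down angles are negated for display only). Wedge radius is
#' proportional to bin weight, or to its square root (equal-area wedges)
#' when `radius = "sqrt"`. The plot is annotated with the pooled n and,
#' when a test is supplied, its p-value.
#'
#' @param histogram an [bin_angles()] result.
#' @param test optional [chi_square_uniformity()] result for annotation.
#' @param path optional output file (written with [ggplot2::ggsave()];
#'   format from the extension, e.g. `.png`, `.pdf`, `.svg`).
#' @param radius `"weight"` or `"sqrt"`.
#' @param width,height,dpi device size passed to `ggsave`.
#' @return the ggplot object, invisibly when `path` is given.
#' @export
render_rose_plot <- function(histogram, test = NULL, path = NULL,
                             radius = c("weight", "sqrt"),
                             width = 4, height = 4, dpi = 150) {
  stopifnot(inherits(histogram, "angular_histogram"))
  radius <- match.arg(radius)
  r <- histogram$weights
  if (radius == "sqrt") r <- sqrt(r)
  width_deg <- 360 / histogram$n_bins
  half <- width_deg / 2
  # display convention: negate the image-coordinate (y-down) angle so
  # positive relative angles appear counterclockwise on the page, with the
  # reference direction (0 deg) at the right
  disp <- ((-histogram$bin_centers_deg + half) %% 360) - half
  dat <- data.frame(center = disp, mass = r)
  ann <- sprintf("n = %d", histogram$total_cells)
  if (!is.null(test) && isTRUE(test$defined)) {
    ann <- sprintf("%s, p = %.3g", ann, test$p_value)
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = center, y = mass)) +
    ggplot2::geom_col(width = width_deg, fill = "steelblue",
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "x", start = pi / 2, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(-half, 360 - half),
                                breaks = c(0, 90, 180, 270),
                                labels = c("0°", "-90°",
                                           "180°", "90°")) +
    ggplot2::labs(x = NULL, y = NULL, subtitle = ann) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}
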