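# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (loops, direct enumeration, numerical integration) and
# share no code with the implementation they check.

# stack-based flood fill labeling of a logical mask
flood_components <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in offs) {
          r <- p[1] + o[1]
          cc <- p[2] + o[2]
          if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            stack[[length(stack) + 1L]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# partition of foreground pixels as a canonical signature (relabel invariant)
component_signature <- function(lab) {
  idx <- which(lab > 0L)
  unname(lapply(split(idx, lab[idx]), sort))
}

same_partition <- function(a, b) {
  sa <- component_signature(a)
  sb <- component_signature(b)
  setequal(vapply(sa, paste, character(1), collapse = ","),
           vapply(sb, paste, character(1), collapse = ","))
}

# exhaustive Otsu: try every split of the 256-level histogram, computing
# class weights/means directly from per-pixel level assignments
otsu_oracle_level <- function(image) {
  v <- as.vector(image)
  lev <- pmin(as.integer(floor(v * 256)), 255L)
  mids <- (0:255 + 0.5) / 256
  pix <- mids[lev + 1L]
  n <- length(v)
  best <- 0
  bestk <- NA_integer_
  for (k in 0:254) {
    in0 <- lev <= k
    n0 <- sum(in0)
    if (n0 == 0L || n0 == n) next
    w0 <- n0 / n
    sb <- w0 * (1 - w0) * (mean(pix[in0]) - mean(pix[!in0]))^2
    if (sb > best + 1e-15) {
      best <- sb
      bestk <- k
    }
  }
  bestk
}

# upper tail of the chi-square distribution by numerical integration of the
# hand-coded density (independent of pchisq)
chisq_tail_oracle <- function(stat, df) {
  dens <- function(x) {
    exp((df / 2 - 1) * log(x) - x / 2 - (df / 2) * log(2) - lgamma(df / 2))
  }
  stats::integrate(dens, stat, Inf, rel.tol = 1e-10)$value
}

# exact 90-degree raster rotation: (x, y) -> (H + 1 - y, x), which adds +90
# degrees to every displacement angle under the y-down convention
rot90_raster <- function(m) {
  t(m)[, nrow(m):1, drop = FALSE]
}

circ_mean_deg <- function(a) {
  atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
}
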