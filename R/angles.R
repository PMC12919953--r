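#' Wrap angles to the half-open interval (-180, 180] degrees
#'
#' All angles in this package are in degrees, measured in image coordinates
#' (x increases rightward along columns, y increases downward along rows), so
#' that `theta = atan2(dy, dx)` and 0 degrees points along +x. The canonical
#' range is `(-180, 180]`: -180 wraps to +180.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(0, 190, -180, 540))
#' @export
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

#' Angle of a displacement in image coordinates
#'
#' @param dx,dy displacement components (x = columns, y = rows, y down).
#' @return angle in degrees in (-180, 180]; 0 = +x, 90 = +y (downward on
#'   screen).
#' @export
angle_of <- function(dx, dy) {
  wrap_angle(atan2(dy, dx) * 180 / pi)
}

#' Signed angular difference between a polarity angle and a reference
#'
#' Computes `polarity - reference`, wrapped to (-180, 180], so that 0 means
#' the cell's polarity points exactly along the reference (force) direction.
#'
#' @param polarity_angle_deg,reference_angle_deg angles in degrees.
#' @return relative angle in degrees in (-180, 180].
#' @examples
#' relative_angle(100, 90)   # +10
#' relative_angle(-170, 170) # +20, across the wrap seam
#' @export
relative_angle <- function(polarity_angle_deg, reference_angle_deg) {
  wrap_angle(polarity_angle_deg - reference_angle_deg)
}

#' Mean resultant vector of a set of angles
#'
#' Descriptive circular statistic complementing the rose plot: the mean of
#' the unit vectors of the angles. Its length R is 1 for perfectly aligned
#' angles and 0 for balanced/uniform ones.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return list with `R` (mean resultant length in `[0, 1]`),
#'   `mean_angle_deg` (direction, NA when R is numerically 0) and `n`.
#'   With no input angles, `R` and `mean_angle_deg` are NA.
#' @export
mean_resultant <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n == 0L) {
    return(list(R = NA_real_, mean_angle_deg = NA_real_, n = 0L))
  }
  rad <- angles_deg * pi / 180
  C <- mean(cos(rad))
  S <- mean(sin(rad))
  R <- sqrt(C^2 + S^2)
  ang <- if (R < 1e-12) NA_real_ else angle_of(C, S)
  list(R = R, mean_angle_deg = ang, n = n)
}

#' Draw from the von Mises distribution
#'
#' Circular analog of the Gaussian with mean direction `mu_deg` and
#' concentration `kappa` (`kappa = 0` is the circular uniform). Uses the
#' Best-Fisher wrapped-Cauchy rejection sampler.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, >= 0.
#' @return angles in degrees in (-180, 180].
#' @references Best, D.J. and Fisher, N.I. (1979). Efficient simulation of
#'   the von Mises distribution. Applied Statistics 28, 152-157.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 0) {
  stopifnot(length(n) == 1L, n >= 0, kappa >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, n - got)            # batch rejection
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    kacc <- which(ok)
    if (length(kacc)) {
      take <- kacc[seq_len(min(length(kacc), n - got))]
      u3 <- stats::runif(length(take))
      theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[take])))
      out[got + seq_along(take)] <- theta
      got <- got + length(take)
    }
  }
  wrap_angle(mu_deg + out * 180 / pi)
}
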