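#' Twisted-torus geometry
#'
#' The E and I populations are arranged on a twisted torus: a rectangular
#' sheet of \code{n_x} by \code{n_y} neurons whose horizontal edges wrap
#' periodically and whose vertical wrap additionally shifts the horizontal
#' coordinate by half a period (\code{n_x / 2}).  The twist removes the seam
#' that a plain torus would introduce into the attractor's firing-field
#' lattice: the deck transformations of the twisted torus generate a
#' near-hexagonal lattice of images for 34 x 30 sheets.
#'
#' @param n_x Number of neurons along the first (twisted) dimension.
#' @param n_y Number of neurons along the second dimension.
#' @return An object of class \code{torus_geometry} with fields \code{n_x},
#'   \code{n_y} and \code{n} (\code{n_x * n_y}).
#' @examples
#' geom <- torus_geometry()
#' geom$n  # 1020 neurons per population
#' @export
torus_geometry <- function(n_x = 34L, n_y = 30L) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (is.na(n_x) || is.na(n_y) || n_x < 2L || n_y < 2L)
    stop("degenerate geometry: n_x and n_y must both be >= 2")
  structure(list(n_x = n_x, n_y = n_y, n = n_x * n_y),
            class = "torus_geometry")
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat(sprintf("Twisted torus: %d x %d neurons (%d per population)\n",
              x$n_x, x$n_y, x$n))
  invisible(x)
}

#' Torus coordinates of neuron indices
#'
#' Neuron indices are flattened row-wise with respect to the torus: index 1
#' maps to coordinate (0, 0), index 2 to (1, 0), index \code{n_x + 1} to
#' (0, 1), and so on.  Raster plots and bump fits use this mapping.
#'
#' @param idx Integer vector of 1-based neuron indices.
#' @param geometry A \code{\link{torus_geometry}}.
#' @return A two-column matrix of (x, y) coordinates in torus units.
#' @export
torus_coords <- function(idx, geometry) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > geometry$n))
    stop("neuron index outside population")
  cbind(x = (idx - 1L) %% geometry$n_x,
        y = (idx - 1L) %/% geometry$n_x)
}

#' Distance on the twisted torus
#'
#' Minimum Euclidean distance over the nine wrapped images of one point:
#' horizontal wraps of \code{-n_x, 0, n_x} combined with vertical wraps of
#' \code{-n_y, 0, n_y}, where each vertical wrap shifts the horizontal
#' coordinate by \code{n_x / 2} (the half-twist).
#'
#' @param a,b Two-column matrices (or length-2 vectors) of torus coordinates.
#'   Rows are recycled to a common length.
#' @param geometry A \code{\link{torus_geometry}}.
#' @return Numeric vector of distances in torus units.
#' @examples
#' g <- torus_geometry()
#' torus_distance(c(0, 0), c(33, 0), g)  # wraps to distance 1
#' @export
torus_distance <- function(a, b, geometry) {
  if (!inherits(geometry, "torus_geometry"))
    stop("geometry must be a torus_geometry object")
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  n <- max(nrow(a), nrow(b))
  ax <- rep_len(a[, 1], n); ay <- rep_len(a[, 2], n)
  bx <- rep_len(b[, 1], n); by <- rep_len(b[, 2], n)
  nx <- geometry$n_x; ny <- geometry$n_y
  dx <- ax - bx; dy <- ay - by
  best <- rep(Inf, n)
  for (k in -1:1) {
    ddy <- dy + k * ny
    base <- dx + k * nx / 2
    for (m in -1:1) {
      ddx <- base + m * nx
      d2 <- ddx * ddx + ddy * ddy
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Synaptic profile function
#'
#' Distance-dependent peak conductance of a projection.  Two shapes are
#' supported: \code{"center_peaked"}, a Gaussian centred on the presynaptic
#' cell's (possibly direction-shifted) location, and \code{"ring"}, a
#' Gaussian annulus peaking at distance \code{mu} that implements the
#' surround inhibition required for a single stable activity bump.
#'
#' @param shape \code{"center_peaked"} or \code{"ring"}.
#' @param g_max Peak conductance in nS.
#' @param mu Distance of the profile peak from the preferred location
#'   (torus units); must be 0 for \code{center_peaked}.
#' @param sigma_p Profile width (Gaussian SD, torus units).
#' @return An object of class \code{synaptic_profile}.
#' @export
synaptic_profile <- function(shape = c("center_peaked", "ring"),
                             g_max = 1, mu = 0, sigma_p = 3) {
  shape <- match.arg(shape)
  if (!is.finite(sigma_p) || sigma_p <= 0)
    stop("sigma_p must be > 0")
  if (g_max < 0) stop("g_max must be >= 0")
  if (mu < 0) stop("mu must be >= 0")
  if (shape == "center_peaked" && mu != 0)
    stop("center_peaked profiles must have mu = 0")
  structure(list(shape = shape, g_max = g_max, mu = mu, sigma_p = sigma_p),
            class = "synaptic_profile")
}

#' Evaluate a synaptic profile at given distances
#'
#' \code{center_peaked}: \eqn{g_{max} \exp(-d^2 / 2\sigma_p^2)};
#' \code{ring}: \eqn{g_{max} \exp(-(d - \mu)^2 / 2\sigma_p^2)}.  The value at
#' \code{d = mu} is exactly \code{g_max}.
#'
#' @param d Non-negative distances (torus units).
#' @param profile A \code{\link{synaptic_profile}}.
#' @return Conductances in nS.
#' @export
profile_conductance <- function(d, profile) {
  if (!inherits(profile, "synaptic_profile"))
    stop("profile must be a synaptic_profile object")
  if (any(d < 0)) stop("distances must be >= 0")
  profile$g_max * exp(-(d - profile$mu)^2 / (2 * profile$sigma_p^2))
}

# map an arena position (cm) to the implied twisted-torus coordinate, given
# cm-per-torus-unit scale; the vertical wrap applies the half-twist shift
arena_to_torus <- function(x_cm, y_cm, geometry, scale_cm) {
  X <- x_cm / scale_cm
  Y <- y_cm / scale_cm
  k <- floor(Y / geometry$n_y)
  u <- (X + k * geometry$n_x / 2) %% geometry$n_x
  v <- Y %% geometry$n_y
  cbind(u = u, v = v)
}
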