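# Spatial firing-field analyses: occupancy-normalized rate maps, spatial
# autocorrelograms, the rotational gridness score, grid spacing, Skaggs
# spatial information and spatial sparsity.

#' Occupancy-normalized, smoothed rate map
#'
#' Spikes are assigned to square spatial bins by linear interpolation of
#' the trajectory at spike times; occupancy is accumulated from the
#' trajectory sampling interval.  Spike counts and occupancy are smoothed
#' with the same Gaussian kernel before division, so the total spike count
#' is conserved before smoothing and zero-occupancy bins are invalid (NA).
#'
#' @param spike_times Spike times (s) of one cell.
#' @param trajectory Trajectory data frame (\code{t}, \code{x}, \code{y}).
#' @param bin Bin side (cm).
#' @param smoothing Gaussian smoothing SD (cm); 0 disables smoothing.
#' @param arena_diameter Arena diameter (cm); bins outside the circle are
#'   masked.
#' @return An object of class \code{rate_map}: \code{rate} (matrix, Hz;
#'   NA outside the arena or in unvisited bins), \code{occupancy}
#'   (seconds), \code{bin}, \code{x}, \code{y} (bin centres),
#'   \code{max_rate}, \code{n_spikes}.
#' @export
compute_rate_map <- function(spike_times, trajectory, bin = 3,
                             smoothing = 3, arena_diameter = 180) {
  if (nrow(trajectory) < 2) stop("empty trajectory")
  R <- arena_diameter / 2
  br <- seq(-R, R + bin, by = bin) - bin / 2
  nb <- length(br) - 1L
  ctr <- br[-length(br)] + bin / 2
  traj_dt <- stats::median(diff(trajectory$t))

  bin_of <- function(x, y) {
    ix <- findInterval(x, br, rightmost.closed = TRUE)
    iy <- findInterval(y, br, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
    list(ix = ix[ok], iy = iy[ok])
  }

  occ <- matrix(0, nb, nb)
  b <- bin_of(trajectory$x, trajectory$y)
  for (k in seq_along(b$ix))
    occ[b$ix[k], b$iy[k]] <- occ[b$ix[k], b$iy[k]] + traj_dt

  cnt <- matrix(0, nb, nb)
  spike_times <- spike_times[spike_times >= min(trajectory$t) &
                               spike_times <= max(trajectory$t)]
  if (length(spike_times)) {
    sx <- stats::approx(trajectory$t, trajectory$x, spike_times)$y
    sy <- stats::approx(trajectory$t, trajectory$y, spike_times)$y
    bs <- bin_of(sx, sy)
    for (k in seq_along(bs$ix))
      cnt[bs$ix[k], bs$iy[k]] <- cnt[bs$ix[k], bs$iy[k]] + 1
  }

  if (smoothing > 0) {
    cnt_s <- gauss_smooth2(cnt, smoothing / bin)
    occ_s <- gauss_smooth2(occ, smoothing / bin)
  } else { cnt_s <- cnt; occ_s <- occ }

  rate <- cnt_s / occ_s
  rate[occ_s <= 0 | !is.finite(rate)] <- NA
  mask <- outer(ctr, ctr, function(a, b) sqrt(a^2 + b^2)) > R + bin
  rate[mask] <- NA
  structure(list(rate = rate, occupancy = occ, bin = bin, x = ctr, y = ctr,
                 smoothing = smoothing,
                 max_rate = suppressWarnings(max(rate, na.rm = TRUE)),
                 n_spikes = length(spike_times)),
            class = "rate_map")
}

# separable Gaussian smoothing with NA-free matrices; sd in bins
gauss_smooth2 <- function(m, sd_bins) {
  if (sd_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  sm_rows <- apply(m, 2, function(col) pad_conv(col, k))
  t(apply(t(sm_rows), 2, function(row) pad_conv(row, k)))
}

pad_conv <- function(x, k) {
  half <- (length(k) - 1L) / 2L
  xp <- c(rep(0, half), x, rep(0, half))
  stats::convolve(xp, rev(k), type = "filter")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("Rate map: %d x %d bins of %g cm, max %.2f Hz, %d spikes\n",
              nrow(x$rate), ncol(x$rate), x$bin, x$max_rate, x$n_spikes))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$rate, asp = 1, xlab = "x (cm)",
                  ylab = "y (cm)",
                  main = sprintf("max %.1f Hz", x$max_rate), ...)
  invisible(x)
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2-D spatial lag,
#' computed over the overlapping valid bins; lags with fewer than 20
#' overlapping bins are invalidated.  The value at zero lag is 1 and the
#' array is symmetric under lag negation.
#'
#' @param map A \code{\link{compute_rate_map}} result.
#' @param min_overlap Minimum number of overlapping valid bins per lag.
#' @param max_lag Maximum lag in bins (defaults to map size - 1).
#' @return An object of class \code{autocorrelogram}: \code{ac} (matrix of
#'   correlations), \code{lag_x}, \code{lag_y} (cm), \code{bin}.
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20, max_lag = NULL) {
  m <- map$rate
  if (sum(is.finite(m)) < 10) stop("rate map has fewer than 10 valid bins")
  if (stats::sd(m[is.finite(m)]) == 0)
    stop("constant rate map: autocorrelation undefined")
  nb <- nrow(m)
  if (is.null(max_lag)) max_lag <- nb - 1L
  lags <- -max_lag:max_lag
  ac <- matrix(NA_real_, length(lags), length(lags))
  for (a in seq_along(lags)) {
    dx <- lags[a]
    xs1 <- max(1, 1 - dx):min(nb, nb - dx)
    if (!length(xs1)) next
    for (b in seq_along(lags)) {
      dy <- lags[b]
      ys1 <- max(1, 1 - dy):min(nb, nb - dy)
      if (!length(ys1)) next
      m1 <- m[xs1, ys1, drop = FALSE]
      m2 <- m[xs1 + dx, ys1 + dy, drop = FALSE]
      ok <- is.finite(m1) & is.finite(m2)
      if (sum(ok) < min_overlap) next
      v1 <- m1[ok]; v2 <- m2[ok]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
      ac[a, b] <- stats::cor(v1, v2)
    }
  }
  structure(list(ac = ac, lag_x = lags * map$bin, lag_y = lags * map$bin,
                 bin = map$bin),
            class = "autocorrelogram")
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  graphics::image(x$lag_x, x$lag_y, x$ac, asp = 1,
                  xlab = "lag x (cm)", ylab = "lag y (cm)", ...)
  invisible(x)
}

# radial average of an autocorrelogram; returns radius (bins) and mean value
radial_profile <- function(ac) {
  nb <- nrow(ac)
  c0 <- (nb + 1) / 2
  rr <- sqrt(outer(seq_len(nb) - c0, seq_len(nb) - c0,
                   function(a, b) a^2 + b^2))
  rbin <- round(rr)
  ok <- is.finite(ac)
  prof <- tapply(ac[ok], rbin[ok], mean)
  list(r = as.numeric(names(prof)), value = as.numeric(prof))
}

# bilinear interpolation of matrix m at (possibly fractional) indices
bilinear <- function(m, xi, yi) {
  nb <- nrow(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  get <- function(i, j) {
    out <- rep(NA_real_, length(i))
    ok <- i >= 1 & i <= nb & j >= 1 & j <= nb
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Gridness score, rotation correlations and grid spacing
#'
#' The standard rotational-correlation score: an annulus is taken around
#' the centre of the autocorrelogram (inner radius at the first minimum of
#' the radially averaged autocorrelogram, outer radius 1.25 times the
#' distance to the 6th nearest off-centre peak, falling back to 90 percent
#' of the map half-width when fewer peaks exist); the annulus is correlated
#' with copies of itself rotated by 30, 60, 90, 120 and 150 degrees, and
#' the score is \code{min(corr60, corr120) - max(corr30, corr90, corr150)}.
#' Spacing is the median distance from the centre to the six nearest
#' peaks, in cm.  A score above 0.5 is the conventional grid criterion.
#'
#' @param ac An \code{\link{spatial_autocorrelogram}} result.
#' @return An object of class \code{gridness_result}: \code{score},
#'   \code{spacing} (cm, NA when no off-centre peak exists),
#'   \code{rotations} (named vector of correlations), \code{annulus}
#'   (inner/outer radii, bins).
#' @export
gridness <- function(ac) {
  m <- ac$ac
  nb <- nrow(m)
  c0 <- (nb + 1) / 2

  prof <- radial_profile(m)
  # first local minimum of the radial profile marks the central peak edge
  v <- prof$value
  inner <- NA_real_
  for (i in 2:(length(v) - 1)) {
    if (v[i] <= v[i - 1] && v[i] <= v[i + 1]) { inner <- prof$r[i]; break }
  }
  if (!is.finite(inner)) inner <- max(2, nb / 10)
  inner <- max(inner, 2)

  # off-centre local maxima (8-neighbourhood) outside the central peak
  peaks <- find_peaks2(m)
  if (nrow(peaks)) {
    pd <- sqrt((peaks$i - c0)^2 + (peaks$j - c0)^2)
    sel <- pd > inner
    peaks <- peaks[sel, , drop = FALSE]; pd <- pd[sel]
    o <- order(pd)
    peaks <- peaks[o, , drop = FALSE]; pd <- pd[o]
  }
  n6 <- min(6L, nrow(peaks))
  spacing <- if (n6 >= 1) stats::median(pd[seq_len(min(6L, length(pd)))]) * ac$bin
             else NA_real_
  outer_r <- if (n6 >= 6) 1.25 * pd[6] else 0.9 * (nb - 1) / 2
  outer_r <- min(outer_r, (nb - 1) / 2)
  if (outer_r <= inner) outer_r <- min(inner + 3, (nb - 1) / 2)

  # rotation correlations within the annulus
  ii <- rep(seq_len(nb), nb); jj <- rep(seq_len(nb), each = nb)
  rr <- sqrt((ii - c0)^2 + (jj - c0)^2)
  ann <- rr >= inner & rr <= outer_r
  base <- m[cbind(ii[ann], jj[ann])]
  angs <- c(30, 60, 90, 120, 150)
  rots <- vapply(angs, function(a) {
    th <- a * pi / 180
    xr <- c0 + cos(th) * (ii[ann] - c0) - sin(th) * (jj[ann] - c0)
    yr <- c0 + sin(th) * (ii[ann] - c0) + cos(th) * (jj[ann] - c0)
    rot <- bilinear(m, xr, yr)
    ok <- is.finite(base) & is.finite(rot)
    if (sum(ok) < 20) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, numeric(1))
  names(rots) <- paste0("r", angs)
  score <- min(rots["r60"], rots["r120"]) -
    max(rots["r30"], rots["r90"], rots["r150"])
  structure(list(score = unname(score), spacing = spacing,
                 rotations = rots,
                 annulus = c(inner = inner, outer = outer_r) * ac$bin,
                 n_peaks = nrow(peaks)),
            class = "gridness_result")
}

# strict local maxima over the 8-neighbourhood; returns bin indices
find_peaks2 <- function(m) {
  nb <- nrow(m); out_i <- integer(0); out_j <- integer(0)
  for (i in 2:(nb - 1)) for (j in 2:(nb - 1)) {
    v <- m[i, j]
    if (!is.finite(v)) next
    nbh <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    nbh[2, 2] <- -Inf
    if (all(!is.finite(nbh) | nbh < v)) { out_i <- c(out_i, i); out_j <- c(out_j, j) }
  }
  data.frame(i = out_i, j = out_j)
}

#' @export
print.gridness_result <- function(x, ...) {
  cat(sprintf("Gridness %.3f (spacing %s cm; annulus %.1f-%.1f cm)\n",
              x$score,
              if (is.finite(x$spacing)) sprintf("%.1f", x$spacing) else "NA",
              x$annulus[1], x$annulus[2]))
  invisible(x)
}

#' Skaggs spatial information
#'
#' \eqn{I = \sum_i p_i (\lambda_i / \bar\lambda) \log_2(\lambda_i /
#' \bar\lambda)} over valid bins, with \eqn{p_i} the occupancy probability
#' and \eqn{\bar\lambda = \sum_i p_i \lambda_i}, in bits per spike.
#'
#' @param map A \code{\link{compute_rate_map}} result.
#' @return Bits/spike; \code{NA} when the mean rate is zero.
#' @export
spatial_information <- function(map) {
  ok <- is.finite(map$rate) & map$occupancy > 0
  p <- map$occupancy[ok] / sum(map$occupancy[ok])
  lam <- map$rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  rel <- lam / lbar
  sum(p[rel > 0] * rel[rel > 0] * log2(rel[rel > 0]))
}

#' Spatial sparsity
#'
#' \eqn{1 - (\sum_i p_i \lambda_i)^2 / \sum_i p_i \lambda_i^2}: values near
#' 1 indicate firing concentrated in a small part of the arena, near 0 a
#' spatially uniform cell.
#'
#' @param map A \code{\link{compute_rate_map}} result.
#' @return Sparsity in [0, 1); \code{NA} when the mean rate is zero.
#' @export
spatial_sparsity <- function(map) {
  ok <- is.finite(map$rate) & map$occupancy > 0
  p <- map$occupancy[ok] / sum(map$occupancy[ok])
  lam <- map$rate[ok]
  if (sum(p * lam) <= 0) return(NA_real_)
  1 - sum(p * lam)^2 / sum(p * lam^2)
}
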