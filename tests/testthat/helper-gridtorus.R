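# shared fixtures: small geometries and analytic map constructions

small_geom <- function() torus_geometry(8L, 6L)

# brute-force twisted-torus distance: exhaustive minimum over the nine
# wrapped images, written independently of torus_distance()
brute_torus_distance <- function(a, b, geom) {
  best <- Inf
  for (k in c(-1, 0, 1)) {
    for (m in c(-1, 0, 1)) {
      dx <- a[1] - b[1] + k * geom$n_x / 2 + m * geom$n_x
      dy <- a[2] - b[2] + k * geom$n_y
      best <- min(best, sqrt(dx^2 + dy^2))
    }
  }
  best
}

# rate_map object built directly from a rate matrix with uniform occupancy
manual_rate_map <- function(rate, bin = 3, occupancy = NULL) {
  nb <- nrow(rate)
  if (is.null(occupancy)) occupancy <- matrix(1, nb, nb)
  ctr <- (seq_len(nb) - (nb + 1) / 2) * bin
  structure(list(rate = rate, occupancy = occupancy, bin = bin,
                 x = ctr, y = ctr, smoothing = 0,
                 max_rate = max(rate, na.rm = TRUE), n_spikes = NA),
            class = "rate_map")
}

# ideal hexagonal lattice of Gaussian firing fields over a square window
hex_lattice_map <- function(spacing = 60, bin = 3, half = 90, amp = 10,
                            field_sd = 6, angle = 0) {
  v1 <- spacing * c(cos(angle), sin(angle))
  v2 <- spacing * c(cos(angle + pi / 3), sin(angle + pi / 3))
  centers <- do.call(rbind, lapply(-4:4, function(i)
    t(sapply(-4:4, function(j) i * v1 + j * v2))))
  ctr <- seq(-half, half, by = bin)
  rate <- matrix(0, length(ctr), length(ctr))
  for (r in seq_len(nrow(centers))) {
    dx2 <- outer((ctr - centers[r, 1])^2, (ctr - centers[r, 2])^2, "+")
    rate <- rate + amp * exp(-dx2 / (2 * field_sd^2))
  }
  manual_rate_map(rate, bin = bin)
}

# Gaussian bump snapshot on the torus with known parameters
gauss_snapshot <- function(center, width, amp, geom) {
  co <- torus_coords(seq_len(geom$n), geom)
  d <- torus_distance(co, center, geom)
  amp * exp(-d^2 / (2 * width^2))
}

# compact configuration for fast end-to-end engine tests
tiny_config <- function(...) {
  network_config(geometry = torus_geometry(10L, 8L),
                 profiles = list(e_to_i = list(mu = 5, sigma_p = 1.5),
                                 i_to_e = list(sigma_p = 2)),
                 ...)
}
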