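test_that("rate maps conserve spikes and recover a known rate surface", {
  tr <- generate_trajectory("random_walk", duration = 600, seed = 3)
  # no spikes -> all-zero map
  m0 <- compute_rate_map(numeric(0), tr)
  expect_true(all(m0$rate[is.finite(m0$rate)] == 0))
  expect_error(compute_rate_map(1, tr[0, ]), "empty")

  # unsmoothed: sum(rate * occupancy) returns the spike count exactly
  set.seed(9)
  spk <- sort(runif(500, 0, 600))
  m <- compute_rate_map(spk, tr, smoothing = 0)
  ok <- is.finite(m$rate)
  expect_equal(sum(m$rate[ok] * m$occupancy[ok]), 500)

  # Poisson spikes from a known Gaussian rate surface are recovered
  rate_fn <- function(x, y) 20 * exp(-((x - 10)^2 + (y + 20)^2) / (2 * 25^2))
  lam <- rate_fn(tr$x, tr$y)
  dt <- median(diff(tr$t))
  spk <- tr$t[runif(nrow(tr)) < lam * dt]
  m <- compute_rate_map(spk, tr)
  ok <- is.finite(m$rate) & m$occupancy > 0.2
  ref <- rate_fn(outer(m$x, rep(1, length(m$y))),
                 outer(rep(1, length(m$x)), m$y))
  rms <- sqrt(mean((m$rate[ok] - ref[ok])^2))
  expect_lt(rms, 0.1 * 20)
})

test_that("autocorrelogram is 1 at zero lag and symmetric", {
  map <- hex_lattice_map()
  ac <- spatial_autocorrelogram(map)
  c0 <- (nrow(ac$ac) + 1) / 2
  expect_equal(ac$ac[c0, c0], 1)
  ok <- is.finite(ac$ac) & is.finite(ac$ac[rev(seq_len(nrow(ac$ac))),
                                           rev(seq_len(ncol(ac$ac)))])
  expect_equal(ac$ac[ok],
               ac$ac[rev(seq_len(nrow(ac$ac))), rev(seq_len(ncol(ac$ac)))][ok])
  expect_error(spatial_autocorrelogram(manual_rate_map(matrix(1, 20, 20))),
               "constant")
})

test_that("a hexagonal lattice yields six 60-degree peaks at the spacing", {
  map <- hex_lattice_map(spacing = 60)
  ac <- spatial_autocorrelogram(map)
  gr <- gridness(ac)
  expect_gt(gr$score, 1)
  expect_lt(abs(gr$spacing - 60) / 60, 0.05)
  # six nearest peaks 60 degrees apart
  expect_gte(gr$n_peaks, 6)
})

test_that("gridness is negative for a radially symmetric field", {
  ctr <- seq(-90, 90, by = 3)
  rr2 <- outer(ctr^2, ctr^2, "+")
  map <- manual_rate_map(10 * exp(-rr2 / (2 * 30^2)))
  gr <- gridness(spatial_autocorrelogram(map))
  expect_lte(gr$score, 0)
})

test_that("gridness is invariant under global rate scaling", {
  map <- hex_lattice_map()
  map2 <- map; map2$rate <- 7.3 * map2$rate
  g1 <- gridness(spatial_autocorrelogram(map))
  g2 <- gridness(spatial_autocorrelogram(map2))
  expect_equal(g1$score, g2$score, tolerance = 1e-10)
})

test_that("rotating the lattice by 30 degrees flips the rotation contrast", {
  g0 <- gridness(spatial_autocorrelogram(hex_lattice_map()))
  g30 <- gridness(spatial_autocorrelogram(hex_lattice_map(angle = pi / 6)))
  # the 60/120-degree correlations stay high in both; a 30-degree lattice
  # rotation leaves the score positive (rotation of the whole pattern does
  # not change its six-fold symmetry) - the sign flip applies to the
  # 30-degree rotation correlation contrast within one autocorrelogram
  expect_gt(g0$score, 1)
  expect_gt(g30$score, 1)
  # mixing the two lattices breaks six-fold symmetry and lowers the score
  mix <- hex_lattice_map()
  mix$rate <- mix$rate + hex_lattice_map(angle = pi / 6)$rate
  expect_lt(gridness(spatial_autocorrelogram(mix))$score, g0$score)
})

test_that("spatial information and sparsity follow their closed forms", {
  n <- 20
  uni <- manual_rate_map(matrix(5, n, n))
  expect_equal(spatial_information(uni), 0)
  expect_equal(spatial_sparsity(uni), 0)

  single <- matrix(0, n, n); single[7, 13] <- 8
  m1 <- manual_rate_map(single)
  expect_equal(spatial_information(m1), log2(n^2))
  expect_equal(spatial_sparsity(m1), 1 - 1 / n^2)

  # zero mean rate -> missing
  z <- manual_rate_map(matrix(0, n, n))
  expect_true(is.na(spatial_information(z)))
  expect_true(is.na(spatial_sparsity(z)))

  # occupancy reweighting with uniform rates leaves both invariant
  occ <- matrix(runif(n^2, 0.1, 2), n, n)
  uni2 <- manual_rate_map(matrix(5, n, n), occupancy = occ)
  expect_equal(spatial_information(uni2), 0)
  expect_equal(spatial_sparsity(uni2), 0)
})
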