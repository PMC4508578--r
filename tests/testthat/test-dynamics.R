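test_that("gamma estimation recovers sinusoid frequencies exactly", {
  tt <- seq(0, 2, by = 1e-3)
  for (f in c(30, 40, 60, 80, 100, 120)) {
    g <- gamma_from_current(sin(2 * pi * f * tt), dt = 1e-3)
    expect_true(g$detected)
    lag_ref <- round(1000 / f)              # nearest sample of the period
    expect_lte(abs(1000 / g$frequency - 1000 / f), 1.0)  # one lag sample
    expect_equal(1000 / g$frequency, lag_ref, tolerance = 1e-9)
    expect_gt(g$strength, 0.8)
  }
})

test_that("gamma detection returns the first, not the global, maximum", {
  tt <- seq(0, 2, by = 1e-3)
  x <- 1.0 * sin(2 * pi * 80 * tt) + 0.6 * sin(2 * pi * 40 * tt)
  g <- gamma_from_current(x, dt = 1e-3)
  expect_equal(1000 / g$frequency, 12.5, tolerance = 0.6)
})

test_that("gamma detection is honest about aperiodic traces", {
  g <- gamma_from_current(rep(3.3, 2000), dt = 1e-3)
  expect_false(g$detected)
  expect_true(is.na(g$strength))

  set.seed(8)
  strengths <- replicate(100, {
    g <- gamma_from_current(rnorm(1500), dt = 1e-3)
    if (g$detected) g$strength else NA_real_
  })
  expect_lt(median(strengths, na.rm = TRUE), 0.1)
})

test_that("population gamma averages only detected cells", {
  tt <- seq(0, 1.6, by = 1e-3)
  one <- sin(2 * pi * 60 * tt)
  traces <- cbind(one, one, one)
  g <- population_gamma(traces, dt = 1e-3, settle = 0.1)
  g1 <- gamma_from_current(one[-(1:100)], dt = 1e-3)
  expect_equal(g$frequency, g1$frequency)
  expect_equal(g$strength, g1$strength)
  expect_identical(g$n_detected, 3L)
})

test_that("bump fits recover constructed Gaussian bumps", {
  geom <- torus_geometry()
  set.seed(11)
  for (k in 1:5) {
    ctr <- c(runif(1, 0, 34), runif(1, 0, 30))
    w <- runif(1, 2, 5)
    snap <- gauss_snapshot(ctr, w, amp = 20, geom)
    fit <- fit_bump(snap, geom)
    expect_true(fit$is_bump)
    expect_lt(torus_distance(fit$center, ctr, geom), 0.2)
    expect_lt(abs(fit$width - w) / w, 0.05)
  }
})

test_that("bump fitting is equivariant under torus translations", {
  geom <- torus_geometry()
  base_ctr <- c(9, 14)
  snap <- gauss_snapshot(base_ctr, 3, amp = 10, geom)
  f0 <- fit_bump(snap, geom)
  set.seed(3)
  for (k in 1:8) {
    sh <- c(runif(1, 0, 34), runif(1, 0, 30))
    snap_t <- gauss_snapshot((base_ctr + sh) %% c(34, 30), 3, amp = 10, geom)
    ft <- fit_bump(snap_t, geom)
    expect_lt(torus_distance(ft$center, (base_ctr + sh) %% c(34, 30), geom),
              0.25)
  }
})

test_that("non-bumps are classified as such", {
  geom <- torus_geometry()
  expect_false(fit_bump(rep(0, geom$n), geom)$is_bump)
  f <- fit_bump(rep(5, geom$n) + runif(geom$n, -0.01, 0.01), geom)
  expect_false(f$is_bump)   # fitted width exceeds the shorter torus side
})

test_that("sliding-window population rate matches a brute-force oracle", {
  set.seed(5)
  for (trial in 1:100) {
    n_cells <- 20
    times <- sort(runif(rpois(1, 60), 0, 1))
    pr <- population_rate(times, n_cells, duration = 1)
    # brute force on 5 random windows
    idx <- sample(nrow(pr), 5)
    for (i in idx) {
      t0 <- pr$t[i]
      cnt <- sum(times >= t0 & times < t0 + 0.002)
      expect_equal(pr$rate[i], cnt / (n_cells * 0.002))
    }
  }
})

test_that("seizure metrics implement the 2 ms / 0.5 ms window contract", {
  # 612 of 1020 cells firing within one 2 ms window -> exactly 300 Hz
  spk <- data.frame(t = 0.6 + seq(0, 0.00199, length.out = 612),
                    neuron = 1:612)
  m <- seizure_metrics(spk, n_cells = 1020, duration = 1)
  expect_equal(m$e_rate_max, 300)

  silent <- data.frame(t = numeric(0), neuron = integer(0))
  m0 <- seizure_metrics(silent, n_cells = 1020, duration = 2)
  expect_equal(m0$e_rate_max, 0)
  expect_equal(m0$p_erate_300, 0)
  expect_false(m0$excluded)

  # synchronous volleys in 3 of 10 cycles (theta at 8 Hz)
  th <- theta_drive()
  cyc <- 1 / 8
  volley_at <- 0.5 + c(1, 4, 7) * cyc + 0.01
  spk <- data.frame(t = rep(volley_at, each = 1400) +
                      rep(seq(0, 0.0019, length.out = 1400), 3),
                    neuron = rep(rep(1:700, 2), 3))
  m3 <- seizure_metrics(spk, theta = th, n_cells = 1020,
                        duration = 0.5 + 10 * cyc)
  expect_equal(m3$n_cycles, 10L)
  expect_equal(m3$p_erate_300, 0.3)
  expect_true(m3$excluded)   # 1400 spikes in 2 ms is above 500 Hz
})

test_that("bump drift measures the torus distance between 1 s and 9 s", {
  geom <- torus_geometry()
  trk <- data.frame(t = seq(0, 9.9, by = 0.1), cx = 5, cy = 5,
                    width = 3, amplitude = 1, is_bump = TRUE)
  expect_equal(bump_drift(trk, geom), 0)
  # scripted translation by 4 units in y
  trk2 <- trk
  trk2$cy <- 5 + 4 * (trk2$t >= 5)
  expect_equal(bump_drift(trk2, geom), 4)
  # no bump fit anywhere near the final anchor -> missing
  trk3 <- trk; trk3$is_bump[abs(trk3$t - 9) <= 0.5] <- FALSE
  expect_true(is.na(bump_drift(trk3, geom)))
})

test_that("place-reset effectivity measures the mean torus offset", {
  geom <- torus_geometry()
  track <- data.frame(cx = rep(10, 20), cy = rep(10, 20),
                      is_bump = TRUE)
  implied <- cbind(rep(10, 20), rep(10, 20))
  expect_equal(place_reset_effectivity(track = track, implied = implied,
                                       geometry = geom), 0)
  implied_k <- cbind(rep(10, 20), rep(13, 20))
  expect_equal(place_reset_effectivity(track = track, implied = implied_k,
                                       geometry = geom), 3)
})

test_that("bump classification is invariant under torus translations", {
  geom <- torus_geometry()
  run_like <- data.frame(t = rep(c(0.05, 0.15, 0.25), each = 40),
                         neuron = rep(1:40, 3))
  snaps <- bump_snapshots(run_like, window = 0.1, geometry = geom,
                          duration = 0.3)
  fits <- apply(snaps, 1, fit_bump, geometry = geom)
  cls <- vapply(fits, `[[`, logical(1), "is_bump")
  # translating every spike's neuron coordinate by a fixed torus offset
  # preserves the classification of every snapshot
  co <- torus_coords(run_like$neuron, geom)
  co_t <- cbind((co[, 1] + 11) %% geom$n_x, (co[, 2] + 7) %% geom$n_y)
  run_t <- data.frame(t = run_like$t,
                      neuron = co_t[, 1] + geom$n_x * co_t[, 2] + 1)
  snaps_t <- bump_snapshots(run_t, window = 0.1, geometry = geom,
                            duration = 0.3)
  cls_t <- vapply(apply(snaps_t, 1, fit_bump, geometry = geom),
                  `[[`, logical(1), "is_bump")
  expect_identical(cls, cls_t)
})
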