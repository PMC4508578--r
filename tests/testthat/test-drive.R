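test_that("theta drive is a raised sinusoid with the stated mean", {
  d <- theta_drive(A_const = 300, A_theta = 375)
  expect_equal(theta_current(0.3, theta_drive(A_const = 120, A_theta = 0)),
               120)
  # time average over an integer number of cycles equals the disabled mode
  tt <- seq(0, 1, by = 1 / 8 / 1000)[-1]
  m <- mean(theta_current(tt, d))
  d_off <- theta_drive(A_const = 300, A_theta = 375, enabled = FALSE)
  expect_lt(abs(m - theta_current(0.123, d_off)), 1e-9)
  # successive maxima are 125 ms apart at 8 Hz
  tt <- seq(0, 0.5, by = 1e-5)
  y <- theta_current(tt, d)
  pk <- tt[which(diff(sign(diff(y))) == -2) + 1]
  expect_equal(diff(pk), rep(0.125, length(pk) - 1), tolerance = 1e-3)
})

test_that("velocity input is the rectified projection on preferred dirs", {
  expect_equal(velocity_current(c(0, 0), c(1, 0), 2), 0)
  expect_equal(velocity_current(c(0, 10), c(1, 0), 2), 0)   # orthogonal
  expect_equal(velocity_current(c(10, 0), c(-1, 0), 2), 0)  # anti-preferred
  expect_equal(velocity_current(c(10, 0), c(1, 0), 2), 20)
  dirs <- preferred_directions(torus_geometry())
  expect_true(all(rowSums(abs(dirs)) == 1))
  expect_equal(colSums(dirs), c(0, 0))  # four directions balanced
})

test_that("place-cell spikes follow the Gaussian rate surface", {
  # parked at the field centre: count ~ Poisson(r_max * T)
  parked <- data.frame(t = seq(0, 20, by = 0.02), x = 0, y = 0)
  f <- place_field(c(0, 0), r_max = 100, sigma_field = 80)
  spk <- place_cell_spikes(parked, list(f), dt = 1e-3, seed = 2)[[1]]
  expect_lt(abs(length(spk) - 100 * 20), 3 * sqrt(100 * 20))
  f0 <- place_field(c(0, 0), r_max = 0, sigma_field = 80)
  expect_length(place_cell_spikes(parked, list(f0), seed = 2)[[1]], 0)

  # empirical rate vs distance histogram along a slow straight pass
  tr <- generate_trajectory("constant_velocity", duration = 32, speed = 10,
                            direction = c(1, 0))
  tr$x <- tr$x - 160  # pass through the centre
  fld <- place_field(c(0, 0), r_max = 100, sigma_field = 20)
  counts <- numeric(7)
  n_pass <- 40
  for (s in seq_len(n_pass)) {
    spk <- place_cell_spikes(tr, list(fld), dt = 1e-3, seed = s)[[1]]
    xs <- abs(approx(tr$t, tr$x, spk)$y)
    counts <- counts + hist(xs[xs < 70], breaks = seq(0, 70, by = 10),
                            plot = FALSE)$counts
  }
  ctr <- seq(5, 65, by = 10)
  occupancy_s <- 2 * 10 / 10  # both signs, 10 cm bins at 10 cm/s
  rate <- counts / n_pass / occupancy_s
  ref <- 100 * exp(-ctr^2 / (2 * 20^2))
  expect_lt(max(abs(rate - ref)) / 100, 0.1)
})

test_that("constant-velocity trajectories are straight-line kinematics", {
  tr <- generate_trajectory("constant_velocity", duration = 10, speed = 10,
                            direction = c(0, 1))
  expect_equal(max(tr$y) - min(tr$y), 100)
  expect_equal(unique(tr$x), 0)
  expect_equal(unique(tr$vy), 10)
})

test_that("random walks stay in the arena and are reproducible", {
  tr <- generate_trajectory("random_walk", duration = 60, seed = 5)
  expect_true(all(sqrt(tr$x^2 + tr$y^2) <= 90))
  sp <- sqrt(tr$vx^2 + tr$vy^2)
  expect_true(all(sp >= 5 - 1e-9 & sp <= 45 + 1e-9))
  tr2 <- generate_trajectory("random_walk", duration = 60, seed = 5)
  expect_identical(tr, tr2)
})

test_that("600 s random walks cover at least 90% of interior 3 cm bins", {
  cov <- vapply(1:5, function(s)
    gridtorus:::trajectory_coverage(
      generate_trajectory("random_walk", duration = 600, seed = s)),
    numeric(1))
  expect_true(all(cov >= 0.9))
})

test_that("trajectories round-trip through the columnar text format", {
  tr <- generate_trajectory("random_walk", duration = 5, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$y, tr$y, tolerance = 1e-9)
  # velocities are reconstructed as discrete derivatives
  expect_equal(back$vx[-length(back$vx)],
               diff(tr$x) / diff(tr$t), tolerance = 1e-9)
  unlink(path)
})
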