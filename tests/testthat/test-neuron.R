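# membrane-dynamics contracts checked on the single-neuron integrator and
# the full engine

eif_E <- function(dt = 0.1) {
  p <- network_config()$neurons$E
  c(p, list(tref_steps = as.integer(round(p$t_ref / dt))))
}

test_that("resting potential is a fixed point up to the exponential term", {
  p <- eif_E()
  out <- gridtorus:::.gt_eif_single(p, p$EL, rep(0, 10000), 0.1)
  expect_lt(max(abs(out$V - p$EL)), 1e-6)
})

test_that("subthreshold step response matches the RC closed form", {
  p <- eif_E()
  I <- 100  # pA, keeps V far below threshold
  out <- gridtorus:::.gt_eif_single(p, p$EL, rep(I, 5000), 0.1)
  tt <- seq(0, 500, by = 0.1)
  tau <- p$C / p$gL
  v_ref <- p$EL + (I / p$gL) * (1 - exp(-tt / tau))
  expect_lt(max(abs(out$V - v_ref)) / (I / p$gL), 0.01)
})

test_that("suprathreshold firing matches a high-accuracy reference", {
  p <- eif_E()
  I <- 600  # pA, tonic suprathreshold drive
  out <- gridtorus:::.gt_eif_single(p, p$EL, rep(I, 20000), 0.1)
  out_fine <- gridtorus:::.gt_eif_single(eif_E(0.02), p$EL, rep(I, 100000),
                                         0.02)
  isi <- diff(out$spikes)
  expect_gt(length(isi), 3)

  # independent RK4 integration of the same equations at dt = 1 us
  dt <- 1e-3
  f <- function(v) (-p$gL * (v - p$EL) +
                      p$gL * p$DT * exp(min((v - p$VT) / p$DT, 40)) + I) / p$C
  v <- p$EL; t <- 0; spikes <- numeric(0)
  while (t < 500 && length(spikes) < 6) {
    k1 <- f(v); k2 <- f(v + dt / 2 * k1)
    k3 <- f(v + dt / 2 * k2); k4 <- f(v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (v >= p$Vpeak) {
      spikes <- c(spikes, t); v <- p$Vreset; t <- t + p$t_ref
    }
  }
  isi_ref <- diff(spikes)
  isi_fine <- diff(out_fine$spikes)
  expect_lt(abs(median(isi_fine) - median(isi_ref)) / median(isi_ref), 0.01)
  # the production step (0.1 ms) stays within a few percent
  expect_lt(abs(median(isi) - median(isi_ref)) / median(isi_ref), 0.03)
})

test_that("halving dt changes subthreshold traces by far less than 0.1 mV", {
  p <- eif_E()
  set.seed(1)
  I <- approx(seq(0, 1000, by = 10), runif(101, 0, 250),
              seq(0, 1000, by = 0.05))$y
  v1 <- gridtorus:::.gt_eif_single(p, p$EL, I[seq(1, length(I), by = 2)], 0.1)$V
  v2 <- gridtorus:::.gt_eif_single(eif_E(0.05), p$EL, I, 0.05)$V
  v2 <- v2[seq(1, length(v2), by = 2)]
  n <- min(length(v1), length(v2))
  expect_lt(sqrt(mean((v1[seq_len(n)] - v2[seq_len(n)])^2)), 0.1)
})

test_that("noise samples have the requested SD and are independent", {
  expect_true(all(noise_current(3, 100, 0) == 0))
  x <- noise_current(2, 1e6, 150, seed = 4)
  expect_lt(abs(sd(x[, 1]) - 150) / 150, 0.01)
  expect_lt(abs(cor(x[, 1], x[, 2])), 0.01)
})

test_that("the network trajectory is reproducible and noise breaks ties", {
  cfg <- tiny_config(sigma_noise = 0)
  r1 <- run_stationary(cfg, duration = 0.6, seed = 3, n_record = 2)
  r2 <- run_stationary(cfg, duration = 0.6, seed = 3, n_record = 2)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$currents$I_inh, r2$currents$I_inh)

  cfgn <- tiny_config(sigma_noise = 150)
  n1 <- run_stationary(cfgn, duration = 0.6, seed = 3, n_record = 0)
  n1b <- run_stationary(cfgn, duration = 0.6, seed = 3, n_record = 0)
  n2 <- run_stationary(cfgn, duration = 0.6, seed = 4, n_record = 0)
  expect_identical(n1$spikes, n1b$spikes)
  expect_false(identical(n1$spikes, n2$spikes))
})

test_that("a disconnected, undriven, noise-free network stays silent", {
  cfg <- tiny_config(g_E = 0, g_I = 0, sigma_noise = 0,
                     theta = list(A_const_E = 0, A_theta_E = 0,
                                  A_const_I = 0, A_theta_I = 0))
  run <- run_stationary(cfg, duration = 0.5, seed = 1, n_record = 0)
  expect_identical(nrow(run$spikes$E), 0L)
  expect_identical(nrow(run$spikes$I), 0L)
})

test_that("every presynaptic spike lands on the connected conductances", {
  # event-log oracle on a tiny network: one E cell driven to fire, its
  # outgoing ring weights must raise I-cell conductances and fire the
  # I cells with the largest weights first
  cfg <- tiny_config(g_E = 3, g_I = 0, sigma_noise = 0,
                     theta = list(A_const_E = 800, A_theta_E = 0,
                                  A_const_I = 280, A_theta_I = 0))
  run <- run_stationary(cfg, duration = 0.3, seed = 2, n_record = 0,
                        theta_onset_s = 0)
  expect_gt(nrow(run$spikes$E), 0)
  expect_gt(nrow(run$spikes$I), 0)
  # I cells fire strictly after the first E volley plus the 1 ms delay
  expect_gte(min(run$spikes$I$t), min(run$spikes$E$t) + 0.001)
})
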