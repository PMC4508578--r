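test_that("relationship statistics reproduce closed-form cases", {
  x <- seq_len(50)
  s <- suppressWarnings(relationship_stats(x, 2 * x + 1))
  expect_equal(s$r_squared, 1)
  expect_equal(s$mic, 1, tolerance = 2e-3)
  # deterministic nonlinear monotone relation still has MIC 1
  expect_equal(mic(x, exp(x / 10)), 1, tolerance = 2e-3)
  # degenerate variance
  expect_true(is.na(relationship_stats(x, rep(3, 50))$r_squared))
  expect_error(relationship_stats(1:5, 1:5), "at least 10")
})

test_that("independent samples score near the sampling baseline", {
  set.seed(21)
  x <- runif(500); y <- runif(500)
  s <- relationship_stats(x, y)
  expect_lt(s$r_squared, 0.05)
  # permutation baseline of the MIC at this n
  null_mic <- replicate(20, mic(x, sample(y)))
  expect_lt(s$mic, max(null_mic) + 0.05)
  expect_lt(s$mic, 0.4)
})

test_that("mini-sweeps produce per-cell records with derived seeds", {
  spec <- sweep_spec(g_E_values = c(2, 4), g_I_values = c(1, 2),
                     sigma_values = 150, trials = 1, duration = 1.2,
                     master_seed = 3,
                     config_fn = function(...) tiny_config(...))
  rec <- run_sweep(spec)
  expect_identical(nrow(rec), 4L)
  expect_true(all(rec$ok))
  expect_identical(anyDuplicated(rec$seed), 0L)
  expect_true(all(c("p_bumps", "e_rate_max", "gamma_detected") %in%
                    names(rec)))
})

test_that("noise-free sweep cells are bit-reproducible", {
  spec <- sweep_spec(g_E_values = 2, g_I_values = 1.5, sigma_values = 0,
                     trials = 1, duration = 1, master_seed = 11,
                     config_fn = function(...) tiny_config(...))
  r1 <- run_sweep(spec)
  r2 <- run_sweep(spec)
  expect_identical(r1$e_rate_max, r2$e_rate_max)
  expect_identical(r1$p_bumps, r2$p_bumps)
})

test_that("aggregation averages trials and masks missing cells", {
  rec <- data.frame(
    g_E = rep(c(1, 2), each = 4), g_I = rep(rep(c(1, 2), each = 2), 2),
    sigma = 150, trial = rep(1:2, 4), seed = 1:8, ok = TRUE,
    incomplete = FALSE, excluded = FALSE,
    gridness = c(0.2, 0.4, 0.7, 0.9, NA, NA, 0.6, 0.6))
  rec$ok[5:6] <- FALSE
  pm <- aggregate_sweep(rec, "gridness")
  expect_equal(pm$value["1", "1"], 0.3)
  expect_equal(pm$value["1", "2"], 0.8)
  expect_true(is.na(pm$value["2", "1"]))   # all trials failed -> masked
  expect_true(pm$mask["2", "1"])
  expect_equal(pm$value["2", "2"], 0.6)
  expect_error(aggregate_sweep(rec, "nonexistent"), "nonexistent")

  # permutation invariance in record order
  pm2 <- aggregate_sweep(rec[sample(nrow(rec)), ], "gridness")
  expect_equal(pm$value, pm2$value)

  # threshold counting and difference maps
  expect_identical(phase_map_count(pm, 0.5), 2L)
  dd <- phase_map_difference(pm, pm)
  expect_true(all(dd$value[!dd$mask] == 0))
})

test_that("threshold counts recover a constructed number of passing cells", {
  g <- expand.grid(g_E = seq(0, 6, length.out = 31),
                   g_I = seq(0, 6, length.out = 31))
  set.seed(13)
  val <- runif(961)
  rec <- data.frame(g, sigma = 150, trial = 1, seed = seq_len(961),
                    ok = TRUE, incomplete = FALSE, excluded = FALSE,
                    gridness = val)
  pm <- aggregate_sweep(rec, "gridness")
  expect_identical(phase_map_count(pm, 0.5), sum(val > 0.5))
  expect_identical(length(pm$value), 961L)
})

test_that("population summaries pair E and I statistics", {
  s <- population_summary(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(s$paired_diff == 0))
  s2 <- population_summary(c(0.7, 0.9), c(0.2, 0.4))
  expect_equal(s2$e_mean, 0.8)
  expect_equal(s2$i_mean, 0.3)
  expect_equal(s2$paired_diff, c(0.5, 0.5))
  expect_error(population_summary(1:3, 1:4), "unpaired")
})

test_that("configurations round-trip through YAML", {
  cfg <- network_config(g_E = 2.2, g_I = 0.8, sigma_noise = 300,
                        variant = "EII", g_II = 0.33, seed = 42,
                        synapses = list(tau_inh = 9))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$g_E, 2.2)
  expect_equal(back$g_II, 0.33)
  expect_equal(back$synapses$tau_inh, 9)
  expect_identical(back$geometry$n, 1020L)
  expect_identical(back$variant, "EII")
  unlink(path)
})

test_that("runs round-trip through the results container", {
  run <- run_stationary(tiny_config(), duration = 0.6, seed = 2,
                        n_record = 3)
  path <- tempfile(fileext = ".rds")
  save_run(run, path)
  back <- load_run(path)
  expect_identical(back$spikes, run$spikes)
  expect_identical(back$config$g_E, run$config$g_E)
  unlink(path)
})
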