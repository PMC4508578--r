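# Sweep orchestration over (g_E, g_I, sigma), aggregation into phase maps,
# and relationship statistics (R^2, maximal information coefficient).

#' Sweep specification
#'
#' @param g_E_values,g_I_values Conductance grids (nS); the full published
#'   maps use 31 values spanning 0-6 nS, desk-scale presets use coarser
#'   grids.
#' @param sigma_values Noise levels (pA).
#' @param trials Trials per cell.
#' @param protocol \code{"stationary"} (bump/gamma/seizure metrics) or
#'   \code{"exploration"} (gridness and spatial metrics).
#' @param duration Run duration (s).
#' @param master_seed Master seed; child seeds are derived per cell so any
#'   cell can be reproduced in isolation.
#' @param config_fn Function taking \code{(g_E, g_I, sigma_noise, seed)}
#'   and returning a \code{\link{network_config}}; defaults to
#'   \code{network_config}.
#' @return An object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(g_E_values = seq(0, 6, length.out = 31),
                       g_I_values = seq(0, 6, length.out = 31),
                       sigma_values = c(0, 150, 300),
                       trials = 1L,
                       protocol = c("stationary", "exploration"),
                       duration = 10,
                       master_seed = 1L,
                       config_fn = network_config) {
  protocol <- match.arg(protocol)
  stopifnot(length(g_E_values) >= 1, length(g_I_values) >= 1, trials >= 1)
  structure(list(g_E_values = g_E_values, g_I_values = g_I_values,
                 sigma_values = sigma_values, trials = as.integer(trials),
                 protocol = protocol, duration = duration,
                 master_seed = as.integer(master_seed),
                 config_fn = config_fn),
            class = "sweep_spec")
}

# deterministic child seed from cell coordinates (kept below 2^31)
child_seed <- function(master, i_gE, i_gI, sigma, trial) {
  v <- c(master, i_gE, i_gI, round(sigma), trial)
  s <- 0
  for (k in seq_along(v)) {
    s <- (s + (v[k] + k) * 2654435761) %% 2147483647
    s <- (s * 48271) %% 2147483647      # Lehmer step mixes positions
  }
  as.integer(s)
}

#' Run a parameter sweep
#'
#' Simulates and analyses every (g_E, g_I, sigma, trial) cell of the sweep specification.
#' Individual run failures are recorded and never abort the sweep; runs
#' flagged incomplete (wall-clock guard) or excluded (E-rate above 500 Hz
#' in stationary protocol) are marked so aggregation can mask them.
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @param verbose Print progress.
#' @return A data frame of per-run records (one row per trial) with the
#'   analysis statistics of the protocol, of class \code{sweep_records}.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (is in seq_along(spec$sigma_values))
    for (ie in seq_along(spec$g_E_values))
      for (ii in seq_along(spec$g_I_values))
        for (tr in seq_len(spec$trials)) {
          gE <- spec$g_E_values[ie]; gI <- spec$g_I_values[ii]
          sg <- spec$sigma_values[is]
          sd <- child_seed(spec$master_seed, ie, ii, sg, tr)
          if (verbose)
            message(sprintf("cell g_E=%.2f g_I=%.2f sigma=%g trial %d",
                            gE, gI, sg, tr))
          rec <- tryCatch(
            sweep_cell(spec, gE, gI, sg, tr, sd),
            error = function(e) data.frame(
              g_E = gE, g_I = gI, sigma = sg, trial = tr, seed = sd,
              ok = FALSE, error = conditionMessage(e)))
          rows[[length(rows) + 1L]] <- rec
        }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_records", "data.frame")
  out
}

sweep_cell <- function(spec, gE, gI, sigma, trial, seed) {
  cfg <- spec$config_fn(g_E = gE, g_I = gI, sigma_noise = sigma,
                        seed = seed)
  if (spec$protocol == "stationary") {
    run <- run_stationary(cfg, duration = spec$duration, seed = seed)
    trk <- bump_track(run)
    sz <- seizure_metrics(run)
    gm <- population_gamma(run)
    data.frame(g_E = gE, g_I = gI, sigma = sigma, trial = trial,
               seed = seed, ok = TRUE, error = NA_character_,
               incomplete = run$incomplete,
               p_bumps = p_bumps(trk),
               drift = bump_drift(trk, cfg$geometry,
                                  t_end = min(9, spec$duration - 1)),
               e_rate_max = sz$e_rate_max, p_erate_300 = sz$p_erate_300,
               excluded = sz$excluded,
               gamma_detected = gm$detected, gamma_strength = gm$strength,
               gamma_frequency = gm$frequency)
  } else {
    cal <- calibrate_velocity_gain(cfg, seed = seed)
    traj <- generate_trajectory("random_walk", duration = spec$duration,
                                seed = seed)
    run <- run_exploration(cfg, traj, cal$gain, seed = seed)
    spk <- run$spikes$E$t[run$spikes$E$neuron == 1L]
    map <- compute_rate_map(spk, traj)
    gr <- gridness(spatial_autocorrelogram(map))
    data.frame(g_E = gE, g_I = gI, sigma = sigma, trial = trial,
               seed = seed, ok = TRUE, error = NA_character_,
               incomplete = run$incomplete,
               gridness = gr$score, spacing = gr$spacing,
               max_rate = map$max_rate,
               information = spatial_information(map),
               sparsity = spatial_sparsity(map),
               cal_slope = cal$slope, cal_error = cal$fit_error)
  }
}

#' Aggregate sweep records into a phase map
#'
#' Trial-averaged map of one statistic over the (g_E, g_I) grid for a
#' given noise level.  Failed, incomplete or excluded trials are dropped;
#' cells with no completed trial are masked (NA), never averaged as zero.
#'
#' @param records A \code{\link{run_sweep}} result.
#' @param statistic Column name to aggregate.
#' @param sigma Noise level to select (default: first present).
#' @return An object of class \code{phase_map}: \code{value} (matrix with
#'   g_E on rows), \code{g_E}, \code{g_I}, \code{mask} (TRUE = missing),
#'   \code{statistic}, \code{sigma}.
#' @export
aggregate_sweep <- function(records, statistic, sigma = NULL) {
  if (!statistic %in% names(records))
    stop("statistic not present in records: ", statistic)
  if (is.null(sigma)) sigma <- records$sigma[1]
  rec <- records[records$sigma == sigma, ]
  usable <- rec$ok &
    !(if ("incomplete" %in% names(rec)) rec$incomplete %in% TRUE else FALSE) &
    !(if ("excluded" %in% names(rec)) rec$excluded %in% TRUE else FALSE)
  gE <- sort(unique(rec$g_E)); gI <- sort(unique(rec$g_I))
  val <- matrix(NA_real_, length(gE), length(gI),
                dimnames = list(format(gE), format(gI)))
  for (a in seq_along(gE)) for (b in seq_along(gI)) {
    sel <- usable & rec$g_E == gE[a] & rec$g_I == gI[b] &
      is.finite(rec[[statistic]])
    if (any(sel)) val[a, b] <- mean(rec[[statistic]][sel])
  }
  structure(list(value = val, g_E = gE, g_I = gI, mask = !is.finite(val),
                 statistic = statistic, sigma = sigma),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map of %s at sigma = %g pA (%d x %d cells, %d masked)\n",
              x$statistic, x$sigma, length(x$g_E), length(x$g_I),
              sum(x$mask)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, ...) {
  graphics::image(x$g_E, x$g_I, x$value, xlab = "g_E (nS)",
                  ylab = "g_I (nS)", main = x$statistic, ...)
  invisible(x)
}

#' Difference between two phase maps
#'
#' @param a,b \code{phase_map} objects on the same grid.
#' @return A \code{phase_map} of \code{a - b}.
#' @export
phase_map_difference <- function(a, b) {
  stopifnot(identical(a$g_E, b$g_E), identical(a$g_I, b$g_I))
  out <- a
  out$value <- a$value - b$value
  out$mask <- a$mask | b$mask
  out$statistic <- paste0("diff_", a$statistic)
  out
}

#' Count cells above a threshold
#'
#' Region-size counting, e.g. the number of (g_E, g_I) cells whose
#' gridness exceeds 0.5 out of the 961 cells of a 31 x 31 map.
#'
#' @param map A \code{phase_map}.
#' @param threshold Threshold value.
#' @return Integer count of unmasked cells with value above threshold.
#' @export
phase_map_count <- function(map, threshold = 0.5) {
  sum(map$value > threshold, na.rm = TRUE)
}

#' Maximal information coefficient
#'
#' Nonparametric dependence measure between two samples: mutual
#' information is computed on x-by-y grids built from equal-frequency bins,
#' for every grid shape with \code{nx * ny <= n^alpha} (and at least 2
#' bins per axis), normalized by \code{log2(min(nx, ny))}; the maximum
#' over grid shapes is the MIC.  Noiseless monotone relationships score 1;
#' independent samples score near the n-dependent sampling baseline.
#'
#' @param x,y Paired numeric vectors.
#' @param alpha Grid-size exponent (grids limited to \code{n^alpha} cells).
#' @return MIC in [0, 1].
#' @export
mic <- function(x, y, alpha = 0.6) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("mic requires at least 10 paired finite values")
  B <- max(4, floor(n^alpha))
  eq_bins <- function(v, k) {
    qs <- stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                          type = 1, names = FALSE)
    qs[1] <- -Inf; qs[k + 1] <- Inf
    qs <- unique(qs)
    findInterval(v, qs, rightmost.closed = TRUE)
  }
  best <- 0
  for (kx in 2:floor(B / 2)) {
    ky_max <- floor(B / kx)
    if (ky_max < 2) break
    bx <- eq_bins(x, kx)
    nbx <- max(bx)
    if (nbx < 2) next
    for (ky in 2:ky_max) {
      by <- eq_bins(y, ky)
      nby <- max(by)
      if (nby < 2) next
      tab <- table(bx, by) / n
      px <- rowSums(tab); py <- colSums(tab)
      e <- outer(px, py)
      pos <- tab > 0
      mi <- sum(tab[pos] * log2(tab[pos] / e[pos]))
      val <- mi / log2(min(nbx, nby))
      if (val > best) best <- val
    }
  }
  min(best, 1)
}

#' Linear and nonparametric relationship statistics
#'
#' Ordinary least-squares R^2 and the maximal information coefficient for
#' a pair of statistics across network configurations.
#'
#' @param x,y Paired numeric vectors (n >= 10 finite pairs).
#' @return A list with \code{r_squared} and \code{mic}; R^2 is \code{NA}
#'   under degenerate variance.
#' @examples
#' s <- relationship_stats(1:20, (1:20) * 2)
#' s$r_squared  # 1
#' @export
relationship_stats <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop("need at least 10 paired finite values")
  xs <- x[ok]; ys <- y[ok]
  r2 <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
        else summary(stats::lm(ys ~ xs))$r.squared
  list(r_squared = r2, mic = mic(xs, ys))
}

#' Paired population summaries
#'
#' Mean and standard deviation of a statistic per population together with
#' the per-network paired difference vector, the input to paired
#' comparisons such as the E-versus-I spatial sparsity contrast.
#'
#' @param e,i Paired per-network statistic vectors for the E and I
#'   populations (equal length, matched order).
#' @return A list with \code{e_mean}, \code{e_sd}, \code{i_mean},
#'   \code{i_sd}, \code{paired_diff} and \code{n}.
#' @export
population_summary <- function(e, i) {
  if (length(e) != length(i)) stop("unpaired inputs: lengths differ")
  ok <- is.finite(e) & is.finite(i)
  list(e_mean = mean(e[ok]), e_sd = stats::sd(e[ok]),
       i_mean = mean(i[ok]), i_sd = stats::sd(i[ok]),
       paired_diff = e[ok] - i[ok], n = sum(ok))
}
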