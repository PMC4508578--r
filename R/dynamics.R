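# Network-dynamics analyses: gamma oscillations from inhibitory synaptic
# currents, bump-attractor fitting and tracking, seizure metrics, and the
# effectivity of place-cell resetting.

#' Gamma strength and frequency from one current trace
#'
#' The trace is zero-phase band-pass filtered between 20 and 200 Hz
#' (3rd-order Butterworth, forward-backward), its autocorrelation is
#' normalized by the zero-lag value, and the first local maximum after lag
#' zero is located where the first difference of the autocorrelation
#' changes sign from positive to negative.  Gamma strength is the
#' correlation value at that lag and the frequency its reciprocal.  Lags
#' between 2.5 and 50 ms are searched; if no sign change occurs there the
#' oscillation is flagged undetected.
#'
#' @param trace Numeric vector: inhibitory synaptic current onto one E cell
#'   (pA), sampled at \code{dt} intervals.
#' @param dt Sampling interval (s), at most 1 ms.
#' @param band Pass band (Hz).
#' @param lag_range Lag search range (s).
#' @return A list of class \code{gamma_summary}: \code{detected},
#'   \code{strength} (autocorrelation at the first local maximum, in
#'   [-1, 1]) and \code{frequency} (Hz); strength and frequency are
#'   \code{NA} when undetected.
#' @examples
#' tt <- seq(0, 1, by = 1e-3)
#' g <- gamma_from_current(sin(2 * pi * 80 * tt), dt = 1e-3)
#' g$frequency  # 80 Hz
#' @export
gamma_from_current <- function(trace, dt = 1e-3, band = c(20, 200),
                               lag_range = c(0.0025, 0.05)) {
  stopifnot(dt <= 1e-3 + 1e-12, length(trace) > 10)
  undetected <- list(detected = FALSE, strength = NA_real_,
                     frequency = NA_real_)
  class(undetected) <- "gamma_summary"
  if (stats::sd(trace) == 0) return(undetected)

  fs <- 1 / dt
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, trace - mean(trace))
  denom <- sum(x * x)
  if (denom == 0) return(undetected)

  max_lag <- min(length(x) - 2L, ceiling(lag_range[2] / dt) + 1L)
  ac <- vapply(0:max_lag, function(l) {
    sum(x[1:(length(x) - l)] * x[(1 + l):length(x)]) / denom
  }, numeric(1))

  d <- diff(ac)
  lags <- seq_len(max_lag)        # lag in samples for ac[lag + 1]
  # local maximum at lag k: d[k] > 0 (rising into k) and d[k + 1] <= 0
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0)
  lag_s <- cand * dt
  cand <- cand[lag_s >= lag_range[1] & lag_s <= lag_range[2]]
  if (length(cand) == 0) return(undetected)
  k <- cand[1]
  structure(list(detected = TRUE, strength = ac[k + 1],
                 frequency = 1 / (k * dt)),
            class = "gamma_summary")
}

#' @export
print.gamma_summary <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Gamma: strength %.3f, frequency %.1f Hz\n",
                x$strength, x$frequency))
  else cat("Gamma: not detected\n")
  invisible(x)
}

#' Aggregate gamma over the recorded E-cell currents of a run
#'
#' Applies \code{\link{gamma_from_current}} to the inhibitory synaptic
#' current recorded from each of the run's selected E cells (after
#' excluding the settling period) and averages strength and frequency over
#' the cells in which an oscillation was detected.
#'
#' @param run A \code{gt_run}, or a matrix of current traces (one column
#'   per cell) with attribute-free sampling at \code{dt}.
#' @param dt Sampling interval (s); taken from the run when omitted.
#' @param settle Initial period to exclude (s).
#' @return A \code{gamma_summary} with an extra field \code{n_detected}.
#' @export
population_gamma <- function(run, dt = NULL, settle = 0.5) {
  if (inherits(run, "gt_run")) {
    traces <- run$currents$I_inh
    dt <- run$currents$dt
  } else {
    traces <- as.matrix(run)
    if (is.null(dt)) stop("dt required when passing a raw trace matrix")
  }
  skip <- round(settle / dt)
  if (skip >= nrow(traces) - 10) stop("trace shorter than settling period")
  traces <- traces[(skip + 1):nrow(traces), , drop = FALSE]
  gs <- apply(traces, 2, gamma_from_current, dt = dt)
  det <- vapply(gs, `[[`, logical(1), "detected")
  out <- if (!any(det)) {
    list(detected = FALSE, strength = NA_real_, frequency = NA_real_,
         n_detected = 0L)
  } else {
    list(detected = TRUE,
         strength = mean(vapply(gs[det], `[[`, numeric(1), "strength")),
         frequency = mean(vapply(gs[det], `[[`, numeric(1), "frequency")),
         n_detected = sum(det))
  }
  class(out) <- "gamma_summary"
  out
}

#' Fit a symmetric Gaussian bump to a population-activity snapshot
#'
#' Least-squares fit of \eqn{A \exp(-d(x, c)^2 / 2 w^2)} to per-cell firing
#' rates, where \eqn{d} is the twisted-torus distance.  The snapshot is
#' classified as a bump attractor when the fitted width does not exceed the
#' shorter side of the torus.
#'
#' @param snapshot Numeric vector of per-E-cell firing rates (Hz), in
#'   row-wise index order.
#' @param geometry A \code{\link{torus_geometry}}.
#' @return A list of class \code{bump_fit}: \code{center} (torus
#'   coordinates), \code{width} (Gaussian SD, torus units),
#'   \code{amplitude} (Hz), \code{is_bump}.  An all-zero snapshot yields a
#'   failed fit with \code{is_bump = FALSE} and missing centre.
#' @export
fit_bump <- function(snapshot, geometry) {
  stopifnot(length(snapshot) == geometry$n, all(snapshot >= 0))
  failed <- structure(list(center = c(NA_real_, NA_real_), width = NA_real_,
                           amplitude = NA_real_, is_bump = FALSE),
                      class = "bump_fit")
  if (all(snapshot == 0)) return(failed)
  co <- torus_coords(seq_len(geometry$n), geometry)
  i0 <- which.max(snapshot)
  # rate-weighted spread around the peak as width initialization
  d0 <- torus_distance(co, co[i0, , drop = FALSE], geometry)
  w0 <- sqrt(sum(snapshot * d0^2) / sum(snapshot) / 2)
  w0 <- min(max(w0, 0.5), min(geometry$n_x, geometry$n_y))
  obj <- function(p) {
    mu <- p[1:2]
    w <- exp(p[3]); a <- exp(p[4])
    d <- torus_distance(co, mu, geometry)
    sum((snapshot - a * exp(-d^2 / (2 * w^2)))^2)
  }
  p0 <- c(co[i0, ], log(w0), log(max(snapshot[i0], 1e-6)))
  op <- stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-8))
  ctr <- c(op$par[1] %% geometry$n_x, op$par[2] %% geometry$n_y)
  w <- exp(op$par[3])
  structure(list(center = ctr, width = w, amplitude = exp(op$par[4]),
                 is_bump = w <= min(geometry$n_x, geometry$n_y)),
            class = "bump_fit")
}

#' Per-cell firing-rate snapshots of the E population
#'
#' Spike counts in non-overlapping windows divided by the window length.
#'
#' @param run A \code{gt_run} (E-population raster is used), or a data
#'   frame with columns \code{t}, \code{neuron}.
#' @param window Window length (s); 100 ms resolves theta-cycle structure
#'   while averaging over gamma cycles.
#' @param geometry Torus geometry (taken from the run when available).
#' @param duration Total duration (s).
#' @return A matrix with one row per window (rownames = window start time)
#'   and one column per E cell, in Hz.
#' @export
bump_snapshots <- function(run, window = 0.1, geometry = NULL,
                           duration = NULL) {
  if (inherits(run, "gt_run")) {
    spikes <- run$spikes$E
    geometry <- run$config$geometry
    duration <- run$duration
  } else spikes <- run
  stopifnot(!is.null(geometry), !is.null(duration))
  n_win <- floor(duration / window)
  win <- pmin(floor(spikes$t / window) + 1L, n_win)
  keep <- spikes$t < n_win * window
  counts <- matrix(0, n_win, geometry$n)
  if (any(keep)) {
    tab <- table(factor(win[keep], levels = seq_len(n_win)),
                 factor(spikes$neuron[keep], levels = seq_len(geometry$n)))
    counts <- matrix(as.numeric(tab), n_win, geometry$n)
  }
  rates <- counts / window
  rownames(rates) <- format((seq_len(n_win) - 1L) * window)
  rates
}

#' Track the bump attractor over a run
#'
#' Fits a symmetric Gaussian to each snapshot and returns the fitted
#' trajectory of the bump together with the bump classification.  The
#' probability of bump formation, P(bumps), is the proportion of snapshots
#' after the settling period classified as bumps.
#'
#' @param run A \code{gt_run}.
#' @param window Snapshot window (s).
#' @param settle Settling period excluded from P(bumps) (s).
#' @return A data frame of class \code{bump_track} with columns \code{t}
#'   (window start, s), \code{cx}, \code{cy}, \code{width},
#'   \code{amplitude}, \code{is_bump}; attribute \code{p_bumps}.
#' @export
bump_track <- function(run, window = 0.1, settle = 0.5) {
  geometry <- run$config$geometry
  snaps <- bump_snapshots(run, window = window)
  t0 <- (seq_len(nrow(snaps)) - 1L) * window
  fits <- apply(snaps, 1, fit_bump, geometry = geometry)
  df <- data.frame(
    t = t0,
    cx = vapply(fits, function(f) f$center[1], numeric(1)),
    cy = vapply(fits, function(f) f$center[2], numeric(1)),
    width = vapply(fits, `[[`, numeric(1), "width"),
    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
    is_bump = vapply(fits, `[[`, logical(1), "is_bump"))
  attr(df, "p_bumps") <- mean(df$is_bump[df$t >= settle])
  class(df) <- c("bump_track", "data.frame")
  df
}

#' Probability of bump formation
#'
#' @param track A \code{\link{bump_track}} result.
#' @return Fraction of post-settling snapshots classified as bumps.
#' @export
p_bumps <- function(track) {
  attr(track, "p_bumps")
}

#' Spontaneous drift of the bump attractor
#'
#' Twisted-torus distance between the fitted bump centres at 1 s (initial
#' position, after attractor initialization) and 9 s (final position).
#'
#' @param track A \code{\link{bump_track}}.
#' @param geometry A \code{\link{torus_geometry}}.
#' @param t_start,t_end Times of the initial and final fix (s).
#' @param half_window Half-width (s) of the window around each fix whose
#'   medoid bump centre is used, guarding against single-snapshot outliers.
#' @return Drift distance in torus units, or \code{NA} when either
#'   endpoint has no bump fit.
#' @export
bump_drift <- function(track, geometry, t_start = 1, t_end = 9,
                       half_window = 0.5) {
  # medoid of the bump fits within +/- half_window of the anchor time:
  # robust against single-snapshot fitting outliers
  pick <- function(at) {
    sel <- which(track$is_bump & abs(track$t - at) <= half_window)
    if (!length(sel)) return(NULL)
    if (length(sel) == 1) return(c(track$cx[sel], track$cy[sel]))
    ctr <- cbind(track$cx[sel], track$cy[sel])
    dd <- vapply(seq_len(nrow(ctr)), function(i)
      sum(torus_distance(ctr, ctr[i, ], geometry)), numeric(1))
    ctr[which.min(dd), ]
  }
  a <- pick(t_start); b <- pick(t_end)
  if (is.null(a) || is.null(b)) return(NA_real_)
  torus_distance(a, b, geometry)
}

#' Sliding-window population rate of a raster
#'
#' Population-average firing rate: spike count in each window divided by
#' (number of cells x window length).
#'
#' @param times Spike times (s).
#' @param n_cells Population size.
#' @param duration Duration (s).
#' @param window Window length (s), default 2 ms.
#' @param step Window step (s), default 0.5 ms.
#' @return Data frame with window start times \code{t} and rates
#'   \code{rate} (Hz).
#' @export
population_rate <- function(times, n_cells, duration,
                            window = 0.002, step = 0.0005) {
  n_bins <- ceiling(duration / step)
  bins <- pmin(floor(times / step) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  k <- round(window / step)
  n_win <- n_bins - k + 1L
  if (n_win < 1) stop("duration shorter than one window")
  csum <- cumsum(c(0, counts))
  wcount <- csum[(k + 1):(n_bins + 1)] - csum[1:n_win]
  data.frame(t = (seq_len(n_win) - 1L) * step,
             rate = wcount / (n_cells * window))
}

#' Seizure metrics of an E-population raster
#'
#' The population-average E rate is computed in 2 ms windows sliding by
#' 0.5 ms.  \code{e_rate_max} is the maximum over all windows after the
#' first 500 ms.  Theta cycles are delimited at the minima of the theta
#' drive; \code{p_erate_300} is the fraction of cycles whose within-cycle
#' maximum exceeds 300 Hz (at the default geometry, 300 Hz corresponds to
#' at least 60 percent of the 1020 E cells firing within one 2 ms window).
#' Runs whose \code{e_rate_max} exceeds 500 Hz carry an exclusion flag
#' consumed at sweep aggregation.
#'
#' @param run A \code{gt_run}, or a data frame of E spikes (\code{t},
#'   \code{neuron}).
#' @param theta A \code{\link{theta_drive}} (taken from the run's config
#'   when omitted); when theta is disabled, artificial 125 ms cycles are
#'   used for comparability.
#' @param n_cells,duration Population size and duration (needed only for
#'   raw data-frame input).
#' @param settle Initial exclusion (s).
#' @param rate_threshold Cycle-counting threshold (Hz).
#' @param exclusion_threshold \code{e_rate_max} level above which the run
#'   is flagged excluded (Hz).
#' @return A list of class \code{seizure_metrics}: \code{e_rate_max} (Hz),
#'   \code{p_erate_300}, \code{excluded}, \code{n_cycles}.
#' @examples
#' # 612 of 1020 cells firing once within one 2 ms window -> 300 Hz
#' spk <- data.frame(t = 0.6 + seq(0, 0.0019, length.out = 612),
#'                   neuron = 1:612)
#' m <- seizure_metrics(spk, n_cells = 1020, duration = 1)
#' round(m$e_rate_max)
#' @export
seizure_metrics <- function(run, theta = NULL, n_cells = NULL,
                            duration = NULL, settle = 0.5,
                            rate_threshold = 300,
                            exclusion_threshold = 500) {
  if (inherits(run, "gt_run")) {
    spikes <- run$spikes$E
    n_cells <- run$config$geometry$n
    duration <- run$duration
    if (is.null(theta))
      theta <- theta_drive(f_theta = run$config$theta$f_theta,
                           A_const = run$config$theta$A_const_E,
                           A_theta = run$config$theta$A_theta_E,
                           phase = run$config$theta$phase,
                           enabled = run$config$theta$enabled)
  } else spikes <- run
  stopifnot(!is.null(n_cells), !is.null(duration), duration > settle)

  pr <- population_rate(spikes$t, n_cells, duration)
  pr <- pr[pr$t >= settle, ]
  e_rate_max <- if (nrow(pr)) max(pr$rate) else 0

  cycle_len <- if (!is.null(theta) && isTRUE(theta$enabled))
    1 / theta$f_theta else 0.125
  # cycles delimited at drive minima; with the default phase the minima lie
  # at integer multiples of the cycle length
  starts <- seq(settle, duration - cycle_len, by = cycle_len)
  cyc_max <- vapply(starts, function(s) {
    sel <- pr$rate[pr$t >= s & pr$t < s + cycle_len]
    if (length(sel)) max(sel) else 0
  }, numeric(1))
  structure(list(e_rate_max = e_rate_max,
                 p_erate_300 = mean(cyc_max > rate_threshold),
                 excluded = e_rate_max > exclusion_threshold,
                 n_cycles = length(starts)),
            class = "seizure_metrics")
}

#' @export
print.seizure_metrics <- function(x, ...) {
  cat(sprintf("Seizure metrics: E-rate_max %.1f Hz, P(E-rate > 300) = %.2f over %d cycles%s\n",
              x$e_rate_max, x$p_erate_300, x$n_cycles,
              if (x$excluded) " [excluded: > 500 Hz]" else ""))
  invisible(x)
}

#' Effectivity of the place-cell resetting input
#'
#' Using a sliding window (250 ms duration, 125 ms step), measures the
#' twisted-torus distance between the fitted bump centre and the
#' trajectory-implied torus position in each window and averages over
#' windows.  Smaller values mean the place input holds the bump closer to
#' the position it encodes.
#'
#' @param run A \code{gt_run} from an exploration protocol with place
#'   input, or \code{NULL} when \code{track} and \code{implied} are given.
#' @param track Optional precomputed data frame with columns \code{t},
#'   \code{cx}, \code{cy}, \code{is_bump} (one row per window).
#' @param implied Optional matrix of implied torus coordinates per window.
#' @param geometry Torus geometry (required with \code{track}).
#' @param window,step Sliding-window duration and step (s).
#' @return Mean torus distance (torus units), \code{NA} when no window has
#'   a bump fit.
#' @export
place_reset_effectivity <- function(run = NULL, track = NULL,
                                    implied = NULL, geometry = NULL,
                                    window = 0.25, step = 0.125) {
  if (!is.null(run)) {
    stopifnot(inherits(run, "gt_run"))
    if (!isTRUE(run$place_enabled))
      stop("place inputs were not active during this run")
    geometry <- run$config$geometry
    scale <- arena_scale_cm(run$config)
    snaps <- bump_snapshots(run, window = step) # step-resolution snapshots
    n_step <- nrow(snaps)
    k <- round(window / step)
    starts <- seq_len(n_step - k + 1L)
    cx <- cy <- ok <- numeric(0)
    uu <- vv <- numeric(0)
    tr <- run$trajectory
    for (s in starts[seq(1, length(starts), by = 1)]) {
      snap <- colSums(snaps[s:(s + k - 1L), , drop = FALSE]) / k
      f <- fit_bump(snap, geometry)
      cx <- c(cx, f$center[1]); cy <- c(cy, f$center[2])
      ok <- c(ok, f$is_bump)
      tmid <- (s - 1L) * step + window / 2
      px <- stats::approx(tr$t, tr$x, tmid, rule = 2)$y
      py <- stats::approx(tr$t, tr$y, tmid, rule = 2)$y
      im <- arena_to_torus(px, py, geometry, scale)
      uu <- c(uu, im[1]); vv <- c(vv, im[2])
    }
    track <- data.frame(cx = cx, cy = cy, is_bump = as.logical(ok))
    implied <- cbind(uu, vv)
  }
  stopifnot(!is.null(track), !is.null(implied), !is.null(geometry))
  sel <- track$is_bump & is.finite(track$cx)
  if (!any(sel)) return(NA_real_)
  mean(torus_distance(cbind(track$cx, track$cy)[sel, , drop = FALSE],
                      implied[sel, , drop = FALSE], geometry))
}
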