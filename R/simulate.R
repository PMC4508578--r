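# Simulation protocols: stationary runs (bump/gamma/seizure analysis),
# exploration runs (grid firing), and velocity-gain calibration.

# assemble the engine argument list and run one simulation
run_network <- function(config, duration, seed,
                        trajectory = NULL, velocity_gain = NULL,
                        place_enabled = FALSE, theta_onset_s = 0.5,
                        init_hold_s = 0, n_record = 25L, record_dt_ms = 1) {
  stopifnot(inherits(config, "network_config"), duration > 0)
  net <- build_network(config)
  geom <- config$geometry
  dt <- config$dt_ms
  n_steps <- as.integer(round(duration * 1000 / dt))

  # initial conditions and derived seeds from the run seed
  set.seed(seed)
  nE <- list(config$neurons$E)[[1]]
  nI <- list(config$neurons$I)[[1]]
  V0_E <- stats::runif(geom$n, nE$EL, nE$VT)
  V0_I <- stats::runif(geom$n, nI$EL, nI$VT)
  if (place_enabled && !is.null(trajectory)) {
    # seed the attractor at the trajectory-implied torus position so the
    # bump starts attached to the place-cell reference frame
    scale0 <- arena_scale_cm(config)
    imp0 <- arena_to_torus(trajectory$x[1], trajectory$y[1], geom, scale0)
    d0 <- torus_distance(torus_coords(seq_len(geom$n), geom), imp0, geom)
    bump0 <- exp(-d0^2 / (2 * 3^2))
    V0_E <- V0_E + (nE$VT + 2 - V0_E) * bump0
  }
  engine_seed <- floor(stats::runif(1) * 2^31)
  rec_idx <- sort(sample.int(geom$n, min(n_record, geom$n))) - 1L

  pop_args <- function(p) list(n = geom$n, C = p$C, gL = p$gL, EL = p$EL,
                               VT = p$VT, DT = p$DT, Vpeak = p$Vpeak,
                               Vreset = p$Vreset,
                               tref_steps = as.integer(round(p$t_ref / dt)))
  d_steps <- as.integer(round(config$synapses$delay / dt))
  empty <- matrix(numeric(0), 0, 0)

  args <- list(
    dt = dt, n_steps = n_steps,
    E = pop_args(nE), I = pop_args(nI),
    V0_E = V0_E, V0_I = V0_I,
    syn = list(E_exc = config$synapses$E_exc, E_inh = config$synapses$E_inh,
               tau_exc = config$synapses$tau_exc,
               tau_inh = config$synapses$tau_inh,
               tau_nmda = config$synapses$tau_nmda,
               nmda_frac = config$synapses$nmda_frac,
               delay_steps_EI = d_steps, delay_steps_IE = d_steps,
               delay_steps_II = d_steps, delay_steps_EE = d_steps),
    tW_EI = t(net$W_EI), tW_IE = t(net$W_IE),
    tW_II = if (is.null(net$W_II)) empty else t(net$W_II),
    tW_EE = if (is.null(net$W_EE)) empty else t(net$W_EE),
    theta = list(enabled = config$theta$enabled,
                 f_theta = config$theta$f_theta,
                 A_const_E = config$theta$A_const_E,
                 A_theta_E = config$theta$A_theta_E,
                 A_const_I = config$theta$A_const_I,
                 A_theta_I = config$theta$A_theta_I,
                 phase = config$theta$phase,
                 onset_step = as.integer(round(theta_onset_s * 1000 / dt))),
    sigma = config$sigma_noise,
    noise_steps = max(1L, as.integer(round(config$noise_update_ms / dt))),
    seed = engine_seed,
    has_vel = FALSE, has_place = FALSE,
    rec_idx = rec_idx,
    rec_every = max(1L, as.integer(round(record_dt_ms / dt))))

  if (!is.null(trajectory)) {
    traj_dt <- stats::median(diff(trajectory$t))
    tt <- seq(0, duration, by = traj_dt)
    vx <- stats::approx(trajectory$t, trajectory$vx, tt, rule = 2)$y
    vy <- stats::approx(trajectory$t, trajectory$vy, tt, rule = 2)$y
    # initialization hold: the bump forms at the starting position before
    # the velocity and place cues begin to move
    hold <- tt < init_hold_s
    vx[hold] <- 0; vy[hold] <- 0
    args$has_vel <- TRUE
    args$dirs_E <- net$dirs
    args$vx <- vx
    args$vy <- vy
    if (is.null(velocity_gain)) {
      args$vel_gain <- 0; args$vel_offset <- 0
    } else if (inherits(velocity_gain, "gt_calibration")) {
      args$vel_gain <- velocity_gain$gain_lin
      args$vel_offset <- velocity_gain$offset
    } else {
      args$vel_gain <- velocity_gain[1]
      args$vel_offset <- if (length(velocity_gain) > 1) velocity_gain[2] else 0
    }
    args$vel_rect <- isTRUE(config$velocity_rectified)
    args$traj_steps <- max(1L, as.integer(round(traj_dt * 1000 / dt)))
    if (place_enabled) {
      scale <- arena_scale_cm(config)
      x <- stats::approx(trajectory$t, trajectory$x, tt, rule = 2)$y
      y <- stats::approx(trajectory$t, trajectory$y, tt, rule = 2)$y
      x[hold] <- x[which(!hold)[1]]; y[hold] <- y[which(!hold)[1]]
      imp <- arena_to_torus(x, y, geom, scale)
      args$has_place <- TRUE
      args$coords_E <- torus_coords(seq_len(geom$n), geom)
      args$imp_u <- imp[, 1]
      args$imp_v <- imp[, 2]
      args$pc_rmax <- config$place$r_max * config$place$n_per_cell
      args$pc_sigma <- config$place$sigma_field / scale
      args$pc_w <- config$place$weight
      args$n_x <- geom$n_x
      args$n_y <- geom$n_y
      pr_steps <- max(1L, as.integer(round(config$place$rate_update_ms / dt)))
      ps_steps <- max(1L, as.integer(round(config$place$spike_update_ms / dt)))
      args$place_rate_steps <- pr_steps
      args$place_spk_steps <- ps_steps
    }
  }

  t0 <- proc.time()[["elapsed"]]
  res <- .gt_engine(args)
  elapsed <- proc.time()[["elapsed"]] - t0

  out <- list(
    spikes = list(
      E = data.frame(t = res$spike_t_E / 1000, neuron = res$spike_i_E),
      I = data.frame(t = res$spike_t_I / 1000, neuron = res$spike_i_I)),
    currents = list(I_inh = res$I_inh_rec, cells = rec_idx + 1L,
                    dt = record_dt_ms / 1000),
    config = config, duration = duration, seed = seed,
    settle = 0.5, theta_onset = theta_onset_s,
    trajectory = trajectory, velocity_gain = velocity_gain,
    place_enabled = place_enabled,
    elapsed = elapsed,
    incomplete = elapsed > config$max_wall_s)
  class(out) <- "gt_run"
  out
}

#' @export
print.gt_run <- function(x, ...) {
  cat(sprintf("Network run: %.3g s, %d E / %d I spikes%s\n", x$duration,
              nrow(x$spikes$E), nrow(x$spikes$I),
              if (isTRUE(x$incomplete)) " [incomplete: wall-clock guard]" else ""))
  cat(sprintf("  g_E = %g nS, g_I = %g nS, sigma = %g pA, seed = %d\n",
              x$config$g_E, x$config$g_I, x$config$sigma_noise, x$seed))
  invisible(x)
}

#' Stationary-protocol simulation
#'
#' Simulates the network with velocity and place-cell inputs deactivated,
#' recording the full spike rasters of both populations and the inhibitory
#' synaptic currents onto \code{n_record} randomly selected E cells.  The
#' first 500 ms are treated as settling time and excluded from downstream
#' analyses; the theta drive switches on at \code{theta_onset_s} so the bump
#' attractor can form under constant drive first.
#'
#' @param config A \code{\link{network_config}}.
#' @param duration Duration (s), default 10.
#' @param seed Run seed.
#' @param theta_onset_s Theta-drive onset time (s).
#' @param n_record Number of E cells whose inhibitory input currents are
#'   recorded (sampling interval 1 ms).
#' @return A \code{gt_run} object with elements \code{spikes} (per
#'   population data frames of spike time (s) and 1-based neuron index),
#'   \code{currents} (matrix of inhibitory currents, pA), the config, and
#'   an \code{incomplete} flag set when the configured wall-clock guard was
#'   exceeded.
#' @export
run_stationary <- function(config, duration = 10, seed = 1L,
                           theta_onset_s = 0.5, n_record = 25L) {
  run_network(config, duration, seed, theta_onset_s = theta_onset_s,
              n_record = n_record)
}

#' Exploration-protocol simulation
#'
#' Simulates grid-field formation: the calibrated velocity input translates
#' the activity bump as the synthetic animal moves, and (by default)
#' place-cell resetting input anchors the bump to the trajectory-implied
#' torus position, opposing drift.  The E cell at torus position (0, 0)
#' (index 1) is always part of the recorded raster, from which rate maps
#' and gridness are computed.
#'
#' @param config A \code{\link{network_config}}.
#' @param trajectory A trajectory from \code{\link{generate_trajectory}}.
#' @param velocity_gain Calibrated gain (pA per cm/s), from
#'   \code{\link{calibrate_velocity_gain}}.
#' @param duration Duration (s); defaults to the trajectory length.
#' @param seed Run seed.
#' @param place_enabled Whether the place-cell resetting input is active.
#' @return A \code{gt_run} object (see \code{\link{run_stationary}}) with
#'   the trajectory attached.
#' @export
run_exploration <- function(config, trajectory, velocity_gain,
                            duration = NULL, seed = 1L,
                            place_enabled = TRUE, init_hold_s = 1) {
  if (is.null(duration)) duration <- max(trajectory$t)
  run_network(config, duration, seed, trajectory = trajectory,
              velocity_gain = velocity_gain, place_enabled = place_enabled,
              theta_onset_s = 0.5, init_hold_s = init_hold_s)
}

#' Calibrate the velocity-input gain
#'
#' Runs constant-velocity simulations at several velocity-current levels,
#' measures the bump-attractor speed from fitted bump centres in 100 ms
#' snapshots between 1 s and the end of each run, and fits a least-squares
#' line through (velocity current, bump speed).  The gain is then chosen so
#' that the integrated bump motion maps \code{grid_spacing} cm of arena
#' travel (60 cm by default) onto one torus period:
#' required bump speed = \eqn{v \cdot n_x / \mathrm{spacing}} torus units/s.
#'
#' @param config A \code{\link{network_config}}.
#' @param currents Velocity-current levels to probe (pA); at least 4,
#'   spanning the operating range of the exploration protocol.
#' @param duration Duration of each calibration run (s).
#' @param seed Run seed (incremented per level).
#' @param target_speed Running speed (cm/s) at which the gain is solved
#'   from the fitted line; the bump-speed response is mildly nonlinear, so
#'   the gain is anchored at the typical speed of the exploration walk.
#' @return A list of class \code{gt_calibration}: \code{gain} (effective
#'   pA per cm/s at the target speed), \code{gain_lin} and \code{offset}
#'   (the affine current map \code{I = gain_lin * v + offset} solved from
#'   the fitted line), \code{slope} (torus units/s per pA),
#'   \code{intercept}, \code{fit_error} (RMS residual), and the per-level
#'   measurements.  Pass the whole object as \code{velocity_gain} to
#'   \code{\link{run_exploration}} to use the affine map.
#' @export
calibrate_velocity_gain <- function(config, currents = c(250, 350, 450, 550),
                                    duration = 4, seed = 1L,
                                    target_speed = 17) {
  stopifnot(length(currents) >= 4)
  geom <- config$geometry
  speeds <- numeric(length(currents))
  for (k in seq_along(currents)) {
    # constant northward motion; gain 1 delivers `currents[k]` pA at peak
    traj <- generate_trajectory("constant_velocity", duration = duration,
                                speed = currents[k], direction = c(0, 1))
    run <- run_network(config, duration, seed + k - 1L, trajectory = traj,
                       velocity_gain = 1, place_enabled = FALSE,
                       theta_onset_s = 0.5, n_record = 0L)
    trk <- bump_track(run, window = 0.1)
    ok <- trk$is_bump & trk$t >= 1
    if (sum(ok) < 5)
      stop("calibration error: no stable bump at velocity current ",
           currents[k], " pA")
    # unwrap successive vertical displacements on the torus; aliased steps
    # (larger than half a typical displacement budget) are dropped
    v <- trk$cy[ok]
    dv <- diff(v)
    dv <- (dv + geom$n_y / 2) %% geom$n_y - geom$n_y / 2
    tms <- trk$t[ok]
    keep <- abs(dv) < 6
    speeds[k] <- sum(dv[keep]) / sum(diff(tms)[keep])
  }
  fit <- stats::lm(speeds ~ currents)
  slope <- unname(stats::coef(fit)[2])
  icept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration error: bump speed does not increase with velocity current")
  spacing <- config$arena$grid_spacing
  # solve the fitted line for the current that yields the bump speed
  # matching the target running speed, then express it as pA per cm/s
  v_bump <- geom$n_x / spacing * target_speed
  gain <- ((v_bump - icept) / slope) / target_speed
  if (gain <= 0) stop("calibration error: nonpositive gain at target speed")
  structure(list(gain = gain,
                 gain_lin = (geom$n_x / spacing) / slope,
                 offset = -icept / slope,
                 slope = slope, intercept = icept,
                 fit_error = sqrt(mean(stats::resid(fit)^2)),
                 currents = currents, bump_speeds = speeds),
            class = "gt_calibration")
}

#' @export
print.gt_calibration <- function(x, ...) {
  cat(sprintf("Velocity calibration: gain %.3g pA/(cm/s), slope %.4g units/s/pA, RMS error %.3g\n",
              x$gain, x$slope, x$fit_error))
  invisible(x)
}

#' Persist and reload simulation runs
#'
#' A run is stored as a single hierarchical container (an RDS file holding
#' the nested list: spike rasters per population, recorded currents,
#' trajectory, and the complete configuration), so any analysis can be
#' recomputed from the file alone.
#'
#' @param run A \code{gt_run} object.
#' @param path File path.
#' @return \code{load_run} returns the \code{gt_run}.
#' @export
save_run <- function(run, path) {
  stopifnot(inherits(run, "gt_run"))
  saveRDS(run, path)
  invisible(path)
}

#' @rdname save_run
#' @export
load_run <- function(path) {
  run <- readRDS(path)
  stopifnot(inherits(run, "gt_run"))
  run
}
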