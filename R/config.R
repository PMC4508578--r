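#' Network configuration
#'
#' Complete parameterization of one network instance: torus geometry,
#' synaptic profile functions, inter-population conductance scalings
#' \code{g_E} (E to I) and \code{g_I} (I to E), per-cell noise amplitude,
#' connectivity variant, cell and synapse constants, and the external
#' drives.  All analysis-relevant constants live here and are serialized
#' with results, never hard-coded in the simulator.
#'
#' The default cell parameters describe stellate-like E cells and
#' fast-spiking-like I cells; together with the default profile widths and
#' drive amplitudes they are tuned so that a single stable activity bump and
#' theta-nested gamma emerge at \code{g_E = 1} nS, \code{g_I = 3} nS,
#' \code{sigma_noise = 150} pA.
#'
#' @param g_E Peak E to I conductance scaling (nS, 0-6 in sweeps).
#' @param g_I Peak I to E conductance scaling (nS, 0-6 in sweeps).
#' @param sigma_noise SD of the Gaussian current noise injected
#'   independently into every cell (pA, 0-300).
#' @param geometry A \code{\link{torus_geometry}}.
#' @param connectivity_mode \code{"scaled_weights"} (all-to-all, weight =
#'   profile) or \code{"probabilistic"} (constant weight, Bernoulli
#'   connection probability proportional to the profile).
#' @param variant Network variant: \code{"EI"} (feedback inhibition only),
#'   \code{"EII"} (adds uniform I to I coupling at \code{g_II}),
#'   \code{"EI_EE"} (adds structured E to E coupling), or \code{"EE_only"}
#'   (structured E to E with uniform E-I/I-E connectivity at probability
#'   \code{p_uniform}).
#' @param g_II Uniform I to I conductance (nS, EII variant).
#' @param g_EE E to E conductance scaling (nS, EE variants).
#' @param sigma_EE E to E profile width (torus units, EE variants).
#' @param p_uniform Connection probability of the unstructured E-I and I-E
#'   projections in the \code{EE_only} variant.
#' @param seed Master random seed for this network instance.
#' @param ... Overrides for nested parameter blocks (\code{profiles},
#'   \code{neurons}, \code{synapses}, \code{theta}, \code{place},
#'   \code{arena}, \code{dt_ms}, \code{noise_update_ms}).
#' @return An object of class \code{network_config}.
#' @examples
#' cfg <- network_config(g_E = 1, g_I = 3, sigma_noise = 150)
#' cfg$theta$f_theta
#' @export
network_config <- function(g_E = 1, g_I = 3, sigma_noise = 150,
                           geometry = torus_geometry(),
                           connectivity_mode = c("scaled_weights", "probabilistic"),
                           variant = c("EI", "EII", "EI_EE", "EE_only"),
                           g_II = 0.5, g_EE = 0.5, sigma_EE = 2.833,
                           p_uniform = 0.1, seed = 1L, ...) {
  connectivity_mode <- match.arg(connectivity_mode)
  variant <- match.arg(variant)
  if (g_E < 0 || g_I < 0) stop("conductance scalings must be >= 0")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (p_uniform < 0 || p_uniform > 1) stop("p_uniform must be in [0, 1]")

  cfg <- list(
    geometry = geometry,
    g_E = g_E, g_I = g_I, sigma_noise = sigma_noise,
    connectivity_mode = connectivity_mode,
    variant = variant,
    g_II = g_II, g_EE = g_EE, sigma_EE = sigma_EE,
    p_uniform = p_uniform,
    seed = as.integer(seed),
    dt_ms = 0.1,
    noise_update_ms = 1,
    profiles = list(
      # E -> I: annular profile, centred on the presynaptic E cell's
      # location shifted by `offset` torus units along its preferred
      # direction; E cells recruit interneurons surrounding the bump, which
      # is why the I population expresses an inverted bump
      e_to_i = list(shape = "ring", mu = 18, sigma_p = 4, offset = 1),
      # I -> E: centre-peaked Gaussian; active surround interneurons
      # suppress the E field everywhere except the bump hole
      i_to_e = list(shape = "center_peaked", mu = 0, sigma_p = 5)
    ),
    neurons = list(
      E = list(C = 211, gL = 22.7, EL = -68.5, VT = -50, DT = 0.4,
               Vpeak = -30, Vreset = -68.5, t_ref = 2),
      I = list(C = 100, gL = 22.7, EL = -60, VT = -45, DT = 0.4,
               Vpeak = -30, Vreset = -60, t_ref = 1)
    ),
    synapses = list(E_exc = 0, E_inh = -75, tau_exc = 1, tau_inh = 5,
                    tau_nmda = 100, nmda_frac = 0.05, delay = 1),
    theta = list(f_theta = 8, A_const_E = 300, A_theta_E = 500,
                 A_const_I = 100, A_theta_I = 25, phase = -pi / 2,
                 enabled = TRUE),
    place = list(r_max = 100, sigma_field = 13, weight = 6, n_per_cell = 3,
                 rate_update_ms = 10, spike_update_ms = 1),
    arena = list(diameter = 180, grid_spacing = 60),
    velocity_rectified = TRUE,
    max_wall_s = Inf
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown configuration block: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("Network config [%s, %s]\n", x$variant, x$connectivity_mode))
  cat(sprintf("  torus %d x %d, g_E = %g nS, g_I = %g nS, sigma = %g pA\n",
              x$geometry$n_x, x$geometry$n_y, x$g_E, x$g_I, x$sigma_noise))
  cat(sprintf("  theta: %g Hz (%s), seed = %d\n", x$theta$f_theta,
              if (x$theta$enabled) "enabled" else "constant-equivalent",
              x$seed))
  invisible(x)
}

# cm of arena travel per torus unit, fixed by the requirement that one
# lattice period (n_x units on a 34 x 30 twisted torus) spans grid_spacing cm
arena_scale_cm <- function(config) {
  config$arena$grid_spacing / config$geometry$n_x
}

#' Write and read network configurations
#'
#' Configurations are serialized as a single human-readable YAML document so
#' that every run can embed, and be reproduced from, its exact parameters.
#'
#' @param config A \code{\link{network_config}}.
#' @param path File path.
#' @return \code{read_config} returns a \code{network_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  lst <- unclass(config)
  lst$geometry <- list(n_x = config$geometry$n_x, n_y = config$geometry$n_y)
  lst$max_wall_s <- if (is.finite(lst$max_wall_s)) lst$max_wall_s else "inf"
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  geom <- torus_geometry(lst$geometry$n_x, lst$geometry$n_y)
  cfg <- network_config(
    g_E = lst$g_E, g_I = lst$g_I, sigma_noise = lst$sigma_noise,
    geometry = geom, connectivity_mode = lst$connectivity_mode,
    variant = lst$variant, g_II = lst$g_II, g_EE = lst$g_EE,
    sigma_EE = lst$sigma_EE, p_uniform = lst$p_uniform, seed = lst$seed,
    profiles = lst$profiles, neurons = lst$neurons, synapses = lst$synapses,
    theta = lst$theta, place = lst$place, arena = lst$arena,
    dt_ms = lst$dt_ms, noise_update_ms = lst$noise_update_ms)
  if (!is.null(lst$max_wall_s))
    cfg$max_wall_s <- if (identical(lst$max_wall_s, "inf")) Inf else lst$max_wall_s
  cfg
}
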