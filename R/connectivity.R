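# Construction of the network's connection matrices.
#
# Weight conventions: W_EI has one row per presynaptic E cell and one column
# per postsynaptic I cell; W_IE is the reverse.  Optional projections (I->I,
# E->E) are present only for the corresponding variants.  Self-connections
# are excluded in all within-population projections.

# full pairwise twisted-torus distance matrix between two coordinate sets
torus_dist_matrix <- function(A, B, geometry) {
  nx <- geometry$n_x; ny <- geometry$n_y
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  best <- matrix(Inf, nrow(A), nrow(B))
  for (k in -1:1) {
    ddy <- dy + k * ny
    ddy2 <- ddy * ddy
    base <- dx + k * nx / 2
    for (m in -1:1) {
      ddx <- base + m * nx
      best <- pmin(best, ddx * ddx + ddy2)
    }
  }
  sqrt(best)
}

#' Preferred directions of E cells
#'
#' Each E cell is assigned one of the four cardinal directions, tiled in
#' 2 x 2 blocks across the torus.  The cell's outgoing excitatory profile is
#' shifted along this direction, and its velocity input is the rectified
#' projection of the animal's velocity onto it; together these translate the
#' activity bump in proportion to movement.
#'
#' @param geometry A \code{\link{torus_geometry}}.
#' @return An \code{n x 2} matrix of unit direction vectors, one row per E
#'   cell in row-wise index order.
#' @export
preferred_directions <- function(geometry) {
  co <- torus_coords(seq_len(geometry$n), geometry)
  bx <- co[, 1] %% 2
  by <- co[, 2] %% 2
  dirs <- matrix(0, geometry$n, 2)
  dirs[bx == 0 & by == 0, 1] <- 1    # east
  dirs[bx == 1 & by == 0, 1] <- -1   # west
  dirs[bx == 0 & by == 1, 2] <- 1    # north
  dirs[bx == 1 & by == 1, 2] <- -1   # south
  dirs
}

#' Build the connection matrices of a network
#'
#' In \code{scaled_weights} mode every pair of cells in a structured
#' projection is connected with weight equal to the synaptic profile
#' evaluated at their twisted-torus distance, so the maximum weight of the
#' E to I projection is \code{g_E} and of the I to E projection \code{g_I}.
#' In \code{probabilistic} mode the weight is the constant \code{g_max} of
#' the profile and the connection is drawn Bernoulli with probability equal
#' to the profile normalized to peak 1; draws are reproducible from
#' \code{config$seed}.
#'
#' The E to I profile of each E cell is centred on its own location shifted
#' by \code{profiles$e_to_i$offset} torus units along its preferred
#' direction; the I to E profile is an annulus centred on the I cell.
#'
#' @param config A \code{\link{network_config}}.
#' @return An object of class \code{connectivity} with elements
#'   \code{W_EI}, \code{W_IE} and, depending on the variant, \code{W_II}
#'   and/or \code{W_EE}, plus the geometry and preferred directions.
#' @examples
#' net <- build_network(network_config(geometry = torus_geometry(8, 6)))
#' max(net$W_IE)  # equals g_I
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  geom <- config$geometry
  co <- torus_coords(seq_len(geom$n), geom)
  dirs <- preferred_directions(geom)
  off <- config$profiles$e_to_i$offset
  co_shift <- co + off * dirs          # direction-shifted E output centres

  pe <- config$profiles$e_to_i
  pi_ <- config$profiles$i_to_e
  prof_EI <- synaptic_profile(pe$shape, g_max = config$g_E,
                              mu = if (identical(pe$shape, "ring")) pe$mu else 0,
                              sigma_p = pe$sigma_p)
  prof_IE <- synaptic_profile(pi_$shape, g_max = config$g_I,
                              mu = if (identical(pi_$shape, "ring")) pi_$mu else 0,
                              sigma_p = pi_$sigma_p)

  probabilistic <- config$connectivity_mode == "probabilistic"
  if (probabilistic) set.seed(config$seed)

  draw <- function(W, g_max) {
    if (!probabilistic || g_max <= 0) return(W)
    p <- W / g_max
    W <- g_max * matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
    W
  }

  net <- list(geometry = geom, dirs = dirs, config = config)

  if (config$variant == "EE_only") {
    # unstructured E-I coupling at constant probability, constant weight
    set.seed(config$seed)
    net$W_EI <- config$g_E *
      matrix(stats::runif(geom$n^2) < config$p_uniform, geom$n, geom$n)
    net$W_IE <- config$g_I *
      matrix(stats::runif(geom$n^2) < config$p_uniform, geom$n, geom$n)
  } else {
    d_EI <- torus_dist_matrix(co_shift, co, geom)
    net$W_EI <- draw(profile_conductance(d_EI, prof_EI), config$g_E)
    d_IE <- torus_dist_matrix(co, co, geom)
    net$W_IE <- draw(profile_conductance(d_IE, prof_IE), config$g_I)
  }

  if (config$variant == "EII") {
    W_II <- matrix(config$g_II, geom$n, geom$n)
    diag(W_II) <- 0
    net$W_II <- W_II
  }
  if (config$variant %in% c("EI_EE", "EE_only")) {
    prof_EE <- synaptic_profile("center_peaked", g_max = config$g_EE,
                                sigma_p = config$sigma_EE)
    d_EE <- torus_dist_matrix(co, co, geom)
    W_EE <- draw(profile_conductance(d_EE, prof_EE), config$g_EE)
    diag(W_EE) <- 0
    net$W_EE <- W_EE
  }
  structure(net, class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  n_syn <- sum(vapply(x[c("W_EI", "W_IE", "W_II", "W_EE")],
                      function(w) if (is.null(w)) 0L else sum(w > 0),
                      integer(1)), na.rm = TRUE)
  cat(sprintf("Connectivity [%s]: %s synapses\n", x$config$variant,
              format(n_syn, big.mark = ",")))
  for (nm in c("W_EI", "W_IE", "W_II", "W_EE"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s: %d x %d, max %.3g nS\n", nm,
                  nrow(x[[nm]]), ncol(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Export connectivity as (pre, post, weight) triplets
#'
#' @param net A \code{connectivity} object.
#' @return A named list of data frames, one per projection, with columns
#'   \code{pre}, \code{post}, \code{weight} (nS); zero weights omitted.
#' @export
connectivity_triplets <- function(net) {
  stopifnot(inherits(net, "connectivity"))
  out <- list()
  for (nm in c("W_EI", "W_IE", "W_II", "W_EE")) {
    W <- net[[nm]]
    if (is.null(W)) next
    nz <- which(W > 0, arr.ind = TRUE)
    out[[nm]] <- data.frame(pre = nz[, 1], post = nz[, 2],
                            weight = W[nz])
  }
  out
}
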