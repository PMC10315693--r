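#' Particle state
#'
#' @param kind `"electron"`, `"positron"` or `"photon"`.
#' @param position Numeric length-3, mm; z is depth below the skin surface.
#' @param direction Numeric length-3; normalised internally.
#' @param energy Kinetic energy in MeV (photon energy for photons).
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(kind = c("electron", "positron", "photon"),
                           position = c(0, 0, 0), direction = c(0, 0, 1),
                           energy = 1) {
  kind <- match.arg(kind)
  if (!all(is.finite(position)) || !all(is.finite(direction)) ||
      !is.finite(energy) || energy < 0)
    stop("corrupted history: non-finite particle state")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(kind = kind, position = position,
                 direction = direction / nrm, energy = energy),
            class = "particle_state")
}

#' Transport one particle through a phantom
#'
#' Runs a single electron/positron (condensed-history) or photon (analog)
#' history and returns every deposition event. Positron histories include
#' the two 0.511 MeV annihilation photons emitted at track end, tallied
#' under the photon mode.
#'
#' @param state A [particle_state()] with position inside the phantom.
#' @param phantom A [skin_phantom()].
#' @param seed Integer seed.
#' @return List with `events` (data frame: `layer`, `energy_deposited` MeV,
#'   `source_mode`; layer `"out_of_footprint"` marks deposition inside the
#'   phantom but outside the tally column) and `escaped` (MeV).
#' @export
transport_particle <- function(state, phantom, seed = 1L) {
  if (!inherits(state, "particle_state")) stop("state must be a particle_state")
  zb <- phantom$z_boundaries
  z <- state$position[3]
  if (z < zb[1] || z > zb[length(zb)])
    stop("particle position outside the phantom bounding volume")
  if (state$energy == 0)
    return(list(events = data.frame(layer = character(),
                                    energy_deposited = numeric(),
                                    source_mode = character()),
                escaped = 0))
  kind <- match(state$kind, c("electron", "positron", "photon")) - 1L
  res <- cpp_transport_single(kind, state$position, state$direction,
                              state$energy, .geom_list(phantom),
                              physics_tables(), as.integer(seed))
  modes <- c("beta", "photon", "discrete_electron")
  lname <- function(i) {
    out <- rep("out_of_footprint", length(i))
    out[i >= 0] <- phantom$names[i[i >= 0] + 1]
    out
  }
  ev <- data.frame(layer = lname(res$layer),
                   energy_deposited = res$energy,
                   source_mode = modes[res$mode + 1])
  list(events = ev, escaped = res$escaped)
}

#' Mean beta penetration depth
#'
#' Mean straight-line distance from the emission point to the track end
#' (penetration depth, not CSDA path length) for beta particles sampled
#' from the nuclide's full beta spectrum, transported with condensed
#' history and multiple scattering in an infinite homogeneous medium.
#'
#' @param nuclide A [radionuclide()] (or name) with at least one beta
#'   branch.
#' @param medium A [tissue_material()]; default water-equivalent soft
#'   tissue at 1.0 g/cm^3.
#' @param n_histories Number of histories (>= 1000).
#' @param seed Integer seed.
#' @return List with `mean` (mm), `se` (mm) and `n`.
#' @export
mean_range <- function(nuclide,
                       medium = tissue_material("soft_tissue", 1.0),
                       n_histories = 1e5, seed = 1L) {
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  if (n_histories < 1e3) stop("n_histories must be >= 1000")
  tab <- .beta_sampling_table(nuclide)
  r <- cpp_beta_range(tab$E, tab$cdf, as.integer(n_histories),
                      as.integer(seed), medium$density, physics_tables())
  list(mean = mean(r), se = sd(r) / sqrt(length(r)), n = length(r))
}
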