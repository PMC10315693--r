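#' Tissue material
#'
#' Materials are water-equivalent media distinguished by density: linear
#' stopping powers and attenuation coefficients are obtained from the
#' embedded liquid-water tables scaled by density. This is the standard
#' approximation for soft tissue and adipose at these energies.
#'
#' @param name Material label.
#' @param density Density in g/cm^3 (> 0).
#' @param composition `"water"` or `"adipose"` (composition handle; both
#'   use the water tables with density scaling).
#' @return An object of class `tissue_material`.
#' @export
tissue_material <- function(name, density,
                            composition = c("water", "adipose")) {
  composition <- match.arg(composition)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  structure(list(name = name, density = density, composition = composition),
            class = "tissue_material")
}

.physics_cache <- new.env(parent = emptyenv())

# Load the embedded water physics tables (versioned CSV resources) and
# precompute the CSDA-range table by cumulative trapezoid integration of
# 1/S on a fine log grid.
physics_tables <- function() {
  if (!is.null(.physics_cache$tab)) return(.physics_cache$tab)
  spf <- system.file("extdata", "stopping_power_water.csv",
                     package = "skindose", mustWork = TRUE)
  atf <- system.file("extdata", "photon_attenuation_water.csv",
                     package = "skindose", mustWork = TRUE)
  sp <- read.csv(spf, comment.char = "#")
  at <- read.csv(atf, comment.char = "#")
  # CSDA range r(E) = r(E_min) + int_{E_min}^{E} dE'/S(E'), in g/cm^2,
  # anchored with the residual range below the 10 keV table floor
  # approximated by E_min / S(E_min).
  eg <- exp(seq(log(0.01), log(3.5), length.out = 600))
  sg <- exp(approx(log(sp$energy_mev), log(sp$stopping_power),
                   pmin(pmax(log(eg), log(min(sp$energy_mev))),
                        log(max(sp$energy_mev))), rule = 2)$y)
  invs <- 1 / sg
  dr <- diff(eg) * (invs[-1] + invs[-length(invs)]) / 2
  rg <- cumsum(c(eg[1] / sg[1], dr))
  tab <- list(
    sp_energy = sp$energy_mev, sp_value = sp$stopping_power,
    csda_energy = eg, csda_range = rg,
    att_energy = at$energy_mev, att_pe = at$mu_photoelectric,
    att_inc = at$mu_incoherent)
  .physics_cache$tab <- tab
  tab
}

#' Electron stopping power
#'
#' Collisional linear stopping power for electrons/positrons in a tissue
#' material: the embedded water mass stopping power (log-log interpolated)
#' scaled by the material density.
#'
#' @param material A [tissue_material()].
#' @param energy Kinetic energy in MeV, vectorised. Values outside the
#'   tabulated 0.01-3 MeV span are clamped with a warning.
#' @return Linear stopping power in MeV/mm.
#' @export
stopping_power <- function(material, energy) {
  if (!inherits(material, "tissue_material"))
    stop("material must be a tissue_material")
  tab <- physics_tables()
  lo <- min(tab$sp_energy); hi <- max(tab$sp_energy)
  if (any(energy < lo | energy > hi)) {
    warning(sprintf(
      "energy outside the %g-%g MeV stopping-power table; clamped", lo, hi))
    energy <- pmin(pmax(energy, lo), hi)
  }
  s_mass <- exp(approx(log(tab$sp_energy), log(tab$sp_value),
                       log(energy), rule = 2)$y)
  s_mass * material$density / 10  # MeV cm^2/g * g/cm^3 -> MeV/cm -> MeV/mm
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range obtained by integrating the
#' inverse stopping power of the embedded water table.
#'
#' @param energy Kinetic energy in MeV, vectorised.
#' @param material Optional [tissue_material()]; if supplied the range is
#'   returned in mm for that density, otherwise in g/cm^2.
#' @return CSDA range (g/cm^2, or mm when `material` is given).
#' @export
csda_range <- function(energy, material = NULL) {
  tab <- physics_tables()
  r <- exp(approx(log(tab$csda_energy), log(tab$csda_range),
                  log(pmax(energy, min(tab$csda_energy))), rule = 2)$y)
  if (is.null(material)) return(r)
  r / material$density * 10
}

#' Photon mass attenuation coefficients
#'
#' @param energy Photon energy in MeV, vectorised.
#' @return Data frame with photoelectric, incoherent and total mass
#'   attenuation coefficients (cm^2/g) for water.
#' @export
photon_attenuation <- function(energy) {
  tab <- physics_tables()
  le <- log(pmin(pmax(energy, min(tab$att_energy)), max(tab$att_energy)))
  pe <- exp(approx(log(tab$att_energy), log(tab$att_pe), le, rule = 2)$y)
  inc <- exp(approx(log(tab$att_energy), log(tab$att_inc), le, rule = 2)$y)
  data.frame(energy = energy, mu_photoelectric = pe, mu_incoherent = inc,
             mu_total = pe + inc)
}
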