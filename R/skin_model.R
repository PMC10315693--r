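#' Skin layer
#'
#' @param name One of `"epidermis"`, `"papillary_dermis"`,
#'   `"reticular_dermis"`, `"hypodermis"`, `"deep_tissue"`.
#' @param thickness Layer thickness in mm (> 0).
#' @param material A [tissue_material()].
#' @return An object of class `skin_layer`.
#' @export
skin_layer <- function(name, thickness, material) {
  name <- match.arg(name, c("epidermis", "papillary_dermis",
                            "reticular_dermis", "hypodermis", "deep_tissue"))
  if (!is.numeric(thickness) || thickness <= 0)
    stop("invalid geometry: layer thickness must be > 0")
  structure(list(name = name, thickness = thickness, material = material),
            class = "skin_layer")
}

#' Layered skin phantom
#'
#' Ordered slab layers from the surface down (z = 0 at the skin surface,
#' increasing with depth; air above the surface), a lateral extent, and an
#' infiltrate footprint centred laterally whose depth span covers the full
#' dermis plus the hypodermis. The epidermis holds no source activity.
#'
#' @param layers List of [skin_layer()] from surface to depth.
#' @param lateral_extent Phantom lateral size `c(x, y)` in mm.
#' @param footprint Infiltrate footprint `c(x, y)` in mm; must fit inside
#'   the lateral extent.
#' @return An object of class `skin_phantom`.
#' @export
skin_phantom <- function(layers, lateral_extent, footprint) {
  if (any(footprint > lateral_extent))
    stop("invalid geometry: footprint exceeds the lateral extent")
  nm <- vapply(layers, function(l) l$name, "")
  th <- vapply(layers, function(l) l$thickness, 0)
  zb <- c(0, cumsum(th))
  structure(
    list(layers = layers, names = nm, thickness = th, z_boundaries = zb,
         lateral_extent = lateral_extent, footprint = footprint),
    class = "skin_phantom")
}

#' @export
print.skin_phantom <- function(x, ...) {
  cat("<skin_phantom>\n")
  for (i in seq_along(x$layers))
    cat(sprintf("  %-17s %8.3f mm  [%.3f, %.3f)  %s %.2f g/cm3\n",
                x$names[i], x$thickness[i], x$z_boundaries[i],
                x$z_boundaries[i + 1], x$layers[[i]]$material$composition,
                x$layers[[i]]$material$density))
  cat(sprintf("  lateral extent %g x %g mm; infiltrate footprint %g x %g mm\n",
              x$lateral_extent[1], x$lateral_extent[2], x$footprint[1],
              x$footprint[2]))
  invisible(x)
}

#' Default layered skin phantom
#'
#' The default geometry of the infiltration model: epidermis (50-70 um,
#' default 60 um), papillary dermis 15 um, reticular dermis sized so the
#' dermis totals 1.2 mm, hypodermis (subcutaneous fat) 6.8 mm, and a 20 mm
#' deep-tissue backing. The infiltrate footprint is 36 x 21 mm and spans
#' the full dermis plus hypodermis. Dermis and epidermis are
#' water-equivalent at 1.09 g/cm^3, hypodermis adipose at 0.95 g/cm^3,
#' deep tissue water-equivalent at 1.04 g/cm^3.
#'
#' @param epidermis_thickness Epidermis thickness in mm; the anatomical
#'   band is 0.05-0.07 mm and values outside it warn.
#' @return A [skin_phantom()].
#' @export
build_default_phantom <- function(epidermis_thickness = 0.06) {
  if (!is.numeric(epidermis_thickness) || epidermis_thickness <= 0)
    stop("invalid geometry: epidermis thickness must be > 0")
  if (epidermis_thickness < 0.05 || epidermis_thickness > 0.07)
    warning("epidermis thickness outside the anatomical 0.05-0.07 mm band")
  derm <- tissue_material("dermis", 1.09, "water")
  fat <- tissue_material("adipose", 0.95, "adipose")
  deep <- tissue_material("soft_tissue", 1.04, "water")
  skin_phantom(
    layers = list(
      skin_layer("epidermis", epidermis_thickness, derm),
      skin_layer("papillary_dermis", 0.015, derm),
      skin_layer("reticular_dermis", 1.2 - 0.015, derm),
      skin_layer("hypodermis", 6.8, fat),
      skin_layer("deep_tissue", 20, deep)),
    lateral_extent = c(80, 60),
    footprint = c(36, 21))
}

#' Activity-partition scenario
#'
#' Total infiltrated activity split between hypodermis and dermis at a
#' fixed concentration ratio, with single-exponential effective clearance.
#'
#' @param nuclide A [radionuclide()] (or nuclide name resolved through
#'   [get_nuclide()]).
#' @param total_activity Total infiltrated activity in MBq (>= 0).
#' @param ratio Hypodermis-to-dermis activity concentration ratio (> 0).
#' @param effective_half_life Effective (physical + biological) clearance
#'   half-life in minutes; must not exceed the physical half-life.
#' @return An object of class `partition_scenario`.
#' @export
partition_scenario <- function(nuclide, total_activity, ratio,
                               effective_half_life) {
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be > 0")
  if (total_activity < 0) stop("total_activity must be >= 0")
  if (effective_half_life <= 0)
    stop("invalid kinetics: effective_half_life must be > 0")
  if (effective_half_life > nuclide$physical_half_life + 1e-9)
    stop("effective half-life cannot exceed the physical half-life")
  structure(
    list(nuclide = nuclide, total_activity = total_activity, ratio = ratio,
         effective_half_life = effective_half_life),
    class = "partition_scenario")
}

#' @export
print.partition_scenario <- function(x, ...) {
  cat(sprintf(
    "<partition_scenario> %s  %.4g MBq  hypodermis:dermis %g:1  Teff %g min\n",
    x$nuclide$name, x$total_activity, x$ratio, x$effective_half_life))
  invisible(x)
}

# Source-region geometry of a phantom: dermal span (papillary + reticular)
# and hypodermis span under the footprint, with volumes in cm^3.
.source_regions <- function(phantom) {
  idx <- function(nm) which(phantom$names == nm)
  zb <- phantom$z_boundaries
  d_lo <- zb[idx("papillary_dermis")]
  d_hi <- zb[idx("reticular_dermis") + 1]
  h_lo <- zb[idx("hypodermis")]
  h_hi <- zb[idx("hypodermis") + 1]
  area_cm2 <- prod(phantom$footprint) / 100
  data.frame(
    region = c("dermis", "hypodermis"),
    zlo = c(d_lo, h_lo), zhi = c(d_hi, h_hi),
    volume = c(area_cm2 * (d_hi - d_lo) / 10, area_cm2 * (h_hi - h_lo) / 10))
}

#' Partition infiltrated activity between hypodermis and dermis
#'
#' Solves the two linear constraints `c_h / c_d = ratio` and
#' `c_d V_d + c_h V_h = A_total` for the region concentrations. The dermal
#' activity is shared between papillary and reticular dermis at a common
#' concentration; the epidermis holds no activity.
#'
#' @param scenario A [partition_scenario()].
#' @param phantom A [skin_phantom()].
#' @return Data frame with region, volume (cm^3), concentration (Bq/cm^3)
#'   and activity (Bq) for dermis and hypodermis.
#' @export
partition_activity <- function(scenario, phantom) {
  reg <- .source_regions(phantom)
  if (any(reg$volume <= 0))
    stop("invalid geometry: source region with non-positive volume")
  A <- scenario$total_activity * 1e6  # Bq
  Vd <- reg$volume[reg$region == "dermis"]
  Vh <- reg$volume[reg$region == "hypodermis"]
  cd <- A / (Vd + scenario$ratio * Vh)
  ch <- scenario$ratio * cd
  reg$concentration <- c(cd, ch)
  reg$activity <- reg$concentration * reg$volume
  reg
}

#' Sample emission sites in the infiltrate
#'
#' Region chosen proportional to concentration x volume; position uniform
#' within the region's footprint column. Reproducible for a given seed.
#'
#' @param partition Output of [partition_activity()].
#' @param phantom A [skin_phantom()].
#' @param n Number of sites.
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `y`, `z` (mm) and `region`.
#' @export
sample_emission_site <- function(partition, phantom, n, seed = 1L) {
  if (all(partition$activity <= 0))
    stop("no source: all region activities are zero")
  p <- partition$activity / sum(partition$activity)
  u <- cpp_sample_inverse_cdf(c(0, 1), c(0, 1), 3L * as.integer(n),
                              as.integer(seed))
  u <- matrix(u, ncol = 3)
  reg <- ifelse(u[, 1] <= p[1], 1L, 2L)
  z <- partition$zlo[reg] + u[, 2] * (partition$zhi[reg] - partition$zlo[reg])
  x <- (u[, 3] - 0.5) * phantom$footprint[1]
  # y from a fourth stream
  uy <- cpp_sample_inverse_cdf(c(0, 1), c(0, 1), as.integer(n),
                               as.integer(seed) + 1L)
  data.frame(x = x, y = uy * phantom$footprint[2] - phantom$footprint[2] / 2,
             z = z, region = partition$region[reg])
}

# Geometry list handed to the C++ engine.
.geom_list <- function(phantom, wrap = FALSE, infinite = FALSE) {
  list(zb = phantom$z_boundaries,
       density = vapply(phantom$layers, function(l) l$material$density, 0),
       lat_x = phantom$lateral_extent[1], lat_y = phantom$lateral_extent[2],
       fp_x = phantom$footprint[1], fp_y = phantom$footprint[2],
       wrap = wrap, infinite = infinite)
}

# Per-layer masses (kg) of the tally regions (footprint column).
.layer_masses <- function(phantom) {
  area_cm2 <- prod(phantom$footprint) / 100
  th_cm <- phantom$thickness / 10
  dens <- vapply(phantom$layers, function(l) l$material$density, 0)
  masses_g <- area_cm2 * th_cm * dens
  setNames(masses_g / 1000, phantom$names)
}
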