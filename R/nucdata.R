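#' Beta-decay branch
#'
#' A single beta branch of a radionuclide: the spectrum endpoint (Q-value
#' available to the beta particle), the branching fraction, and whether the
#' emitted particle is a positron.
#'
#' @param endpoint_energy Spectrum endpoint energy in MeV (> 0).
#' @param branching_fraction Fraction of decays through this branch, in (0, 1].
#' @param is_positron Logical; `TRUE` for beta-plus branches.
#' @param daughter_Z Atomic number of the daughter nucleus, used in the
#'   Coulomb (Fermi-function) correction of the spectrum shape.
#' @param shape Spectrum shape: `"allowed"` (default) or
#'   `"forbidden_unique"` (first-forbidden unique shape factor
#'   \eqn{p^2 + q^2}, appropriate e.g. for yttrium-90).
#' @return An object of class `beta_branch`.
#' @examples
#' b <- beta_branch(0.6335, 0.9686, is_positron = TRUE, daughter_Z = 8)
#' beta_spectrum_pdf(b, c(0.1, 0.25, 0.6335))
#' @export
beta_branch <- function(endpoint_energy, branching_fraction,
                        is_positron = FALSE, daughter_Z = 1,
                        shape = c("allowed", "forbidden_unique")) {
  shape <- match.arg(shape)
  if (!is.numeric(endpoint_energy) || length(endpoint_energy) != 1 ||
      !is.finite(endpoint_energy) || endpoint_energy <= 0)
    stop("invalid beta branch: endpoint_energy must be a positive number")
  if (!is.numeric(branching_fraction) || branching_fraction <= 0 ||
      branching_fraction > 1)
    stop("invalid beta branch: branching_fraction must lie in (0, 1]")
  structure(
    list(endpoint_energy = endpoint_energy,
         branching_fraction = branching_fraction,
         is_positron = isTRUE(is_positron),
         daughter_Z = daughter_Z,
         shape = shape),
    class = "beta_branch")
}

#' Discrete emission line
#'
#' @param energy Line energy in MeV (> 0).
#' @param yield_per_decay Emissions per decay (>= 0).
#' @param kind `"photon"` or `"discrete_electron"` (conversion/Auger).
#' @return An object of class `emission_line`.
#' @export
emission_line <- function(energy, yield_per_decay,
                          kind = c("photon", "discrete_electron")) {
  kind <- match.arg(kind)
  if (energy <= 0) stop("emission line energy must be > 0")
  if (yield_per_decay < 0) stop("emission line yield must be >= 0")
  structure(list(energy = energy, yield_per_decay = yield_per_decay,
                 kind = kind),
            class = "emission_line")
}

#' Radionuclide
#'
#' Container for the decay data the dose model needs: physical half-life,
#' beta branches, discrete photon / conversion-electron lines, and whether
#' the nuclide is a positron emitter (implying two 0.511 MeV annihilation
#' photons per annihilation).
#'
#' @param name Nuclide identifier, e.g. `"F-18"`.
#' @param physical_half_life Physical half-life in minutes (> 0).
#' @param beta_branches List of [beta_branch()] objects (possibly empty).
#' @param lines List of [emission_line()] objects (possibly empty).
#' @param annihilation Logical; `TRUE` for positron emitters.
#' @return An object of class `radionuclide`.
#' @export
radionuclide <- function(name, physical_half_life, beta_branches = list(),
                         lines = list(), annihilation = FALSE) {
  if (!is.numeric(physical_half_life) || physical_half_life <= 0)
    stop("physical_half_life must be > 0")
  if (length(beta_branches) + length(lines) == 0)
    stop("radionuclide must have at least one emission")
  btot <- sum(vapply(beta_branches, function(b) b$branching_fraction, 0))
  if (btot > 1 + 1e-9)
    stop("total beta branching fraction exceeds 1")
  structure(
    list(name = name, physical_half_life = physical_half_life,
         beta_branches = beta_branches, lines = lines,
         annihilation = isTRUE(annihilation)),
    class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide %s>  T1/2(phys) = %.4g min\n",
              x$name, x$physical_half_life))
  for (b in x$beta_branches)
    cat(sprintf("  beta%s  endpoint %.4f MeV  branching %.4f (%s)\n",
                if (b$is_positron) "+" else "-", b$endpoint_energy,
                b$branching_fraction, b$shape))
  for (l in x$lines)
    cat(sprintf("  %s  %.4f MeV  yield %.4f\n", l$kind, l$energy,
                l$yield_per_decay))
  if (x$annihilation)
    cat("  annihilation: 2 x 0.511 MeV photons per beta+ decay\n")
  invisible(x)
}

# --- Fermi beta spectrum --------------------------------------------------

# Unnormalised allowed beta spectrum shape with the nonrelativistic
# Fermi-function Coulomb correction F = 2*pi*eta / (1 - exp(-2*pi*eta)),
# eta = +- Z*alpha/beta (positive for beta-minus, negative for beta-plus,
# Z of the daughter nucleus). Vectorised in `energy`.
.beta_shape <- function(energy, endpoint, Z, is_positron, shape) {
  w <- numeric(length(energy))
  ok <- energy > 0 & energy < endpoint
  E <- energy[ok]
  Etot <- E + .ME
  p <- sqrt(E * (E + 2 * .ME))
  beta <- p / Etot
  eta <- Z * .ALPHA / beta * if (is_positron) -1 else 1
  x <- 2 * pi * eta
  fermi <- ifelse(abs(x) < 1e-12, 1, x / (1 - exp(-x)))
  s <- fermi * p * Etot * (endpoint - E)^2
  if (shape == "forbidden_unique")
    s <- s * (p^2 + (endpoint - E)^2)
  w[ok] <- s
  w
}

# Energy grid and normalisation constant for a branch. The normalisation
# uses adaptive quadrature so the density integrates to 1 to ~1e-10.
.branch_grid <- function(branch, n = 2048) {
  E <- seq(0, branch$endpoint_energy, length.out = n)
  w <- .beta_shape(E, branch$endpoint_energy, branch$daughter_Z,
                   branch$is_positron, branch$shape)
  norm <- stats::integrate(
    function(e) .beta_shape(e, branch$endpoint_energy, branch$daughter_Z,
                            branch$is_positron, branch$shape),
    0, branch$endpoint_energy, rel.tol = 1e-10,
    subdivisions = 500L)$value
  list(E = E, w = w, norm = norm)
}

#' Fermi beta-spectrum probability density
#'
#' Allowed-shape (optionally first-forbidden unique) Fermi-theory beta
#' spectrum with the nonrelativistic Fermi-function Coulomb correction,
#' normalised to integrate to 1 over \[0, endpoint\]. Density is 0 at and
#' above the endpoint.
#'
#' @param branch A [beta_branch()].
#' @param energy Kinetic energy (MeV), vectorised; must be >= 0.
#' @return Probability density in 1/MeV at each `energy`.
#' @export
beta_spectrum_pdf <- function(branch, energy) {
  if (!inherits(branch, "beta_branch")) stop("branch must be a beta_branch")
  if (any(energy < 0)) stop("energy must be >= 0")
  g <- .branch_grid(branch)
  .beta_shape(energy, branch$endpoint_energy, branch$daughter_Z,
              branch$is_positron, branch$shape) / g$norm
}

#' Mean energy of a beta branch by numeric quadrature
#'
#' @param branch A [beta_branch()].
#' @param n Number of grid points for the trapezoid rule.
#' @return Mean beta energy in MeV.
#' @export
beta_mean_energy <- function(branch, n = 4096) {
  g <- .branch_grid(branch, n)
  h <- g$E[2] - g$E[1]
  Ew <- g$E * g$w
  sum((Ew[-1] + Ew[-n]) / 2) * h / g$norm
}

# Combined (branch-weighted) inverse-CDF sampling table over all beta
# branches of a nuclide. Returned as list(E, cdf) on a common grid.
.beta_sampling_table <- function(nuclide, n = 4096) {
  brs <- nuclide$beta_branches
  if (length(brs) == 0)
    stop(sprintf("unsupported nuclide: %s has no beta branch", nuclide$name))
  emax <- max(vapply(brs, function(b) b$endpoint_energy, 0))
  E <- seq(0, emax, length.out = n)
  w <- numeric(n)
  fr <- vapply(brs, function(b) b$branching_fraction, 0)
  fr <- fr / sum(fr)
  for (i in seq_along(brs)) {
    g <- .branch_grid(brs[[i]])
    wi <- .beta_shape(E, brs[[i]]$endpoint_energy, brs[[i]]$daughter_Z,
                      brs[[i]]$is_positron, brs[[i]]$shape) / g$norm
    w <- w + fr[i] * wi
  }
  h <- E[2] - E[1]
  cdf <- c(0, cumsum((w[-1] + w[-n]) / 2) * h)
  cdf <- cdf / cdf[n]
  list(E = E, cdf = cdf,
       is_positron = brs[[1]]$is_positron,
       branching = sum(vapply(brs, function(b) b$branching_fraction, 0)))
}

#' Sample beta emission energies for a nuclide
#'
#' Branch chosen by branching fraction; energy drawn from the branch's
#' Fermi spectrum by inverse-CDF lookup on a fine quadrature grid.
#' Fully reproducible for a given seed (counter-based generator shared with
#' the transport engine).
#'
#' @param nuclide A [radionuclide()] with at least one beta branch.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of kinetic energies (MeV).
#' @export
sample_beta_energy <- function(nuclide, n, seed = 1L) {
  tab <- .beta_sampling_table(nuclide)
  cpp_sample_inverse_cdf(tab$E, tab$cdf, as.integer(n), as.integer(seed))
}

# --- default library ------------------------------------------------------

#' Built-in radionuclide library
#'
#' Returns the four nuclides the skin-dose model covers: the PET positron
#' emitters fluorine-18 and gallium-68 and the therapy beta emitters
#' yttrium-90 and lutetium-177. Constants (half-lives, endpoints, branching
#' fractions, principal lines) follow the standard decay-data compilations
#' (NNDC/ENSDF as tabulated for MIRD use); see the package vignette.
#' Conversion-electron and Auger lines are included only where
#' yield x energy exceeds 1 keV per decay; weaker lines are below the dose
#' tally's statistical resolution.
#'
#' @return Named list of [radionuclide()] objects
#'   (`"F-18"`, `"Ga-68"`, `"Y-90"`, `"Lu-177"`).
#' @export
build_default_library <- function() {
  lib <- list(
    # 18F: T1/2 109.77 min; beta+ endpoint 0.6335 MeV, 96.86% (EC remainder,
    # no significant photon lines besides annihilation).
    "F-18" = radionuclide(
      "F-18", 109.77,
      beta_branches = list(
        beta_branch(0.6335, 0.9686, is_positron = TRUE, daughter_Z = 8)),
      annihilation = TRUE),
    # 68Ga: T1/2 67.71 min; beta+ 1.8991 MeV 87.72%, 0.8219 MeV 1.19%;
    # gamma 1.0770 MeV 3.22%.
    "Ga-68" = radionuclide(
      "Ga-68", 67.71,
      beta_branches = list(
        beta_branch(1.8991, 0.8772, is_positron = TRUE, daughter_Z = 30),
        beta_branch(0.8219, 0.0119, is_positron = TRUE, daughter_Z = 30)),
      lines = list(emission_line(1.0770, 0.0322, "photon")),
      annihilation = TRUE),
    # 90Y: T1/2 64.05 h; beta- endpoint 2.2801 MeV ~100%, first-forbidden
    # unique transition; pure beta emitter (no significant photon yield).
    "Y-90" = radionuclide(
      "Y-90", 64.05 * 60,
      beta_branches = list(
        beta_branch(2.2801, 0.9998, is_positron = FALSE, daughter_Z = 40,
                    shape = "forbidden_unique"))),
    # 177Lu: T1/2 6.647 d; beta- 0.4983 MeV 79.4%, 0.3854 MeV 9.0%,
    # 0.1766 MeV 11.6%; gammas 0.2084 MeV 10.4%, 0.1129 MeV 6.2%;
    # principal conversion-electron lines ~48 keV (K-113) and ~111 keV
    # (K-208) retained per the yield x energy > 1 keV rule.
    "Lu-177" = radionuclide(
      "Lu-177", 6.647 * 24 * 60,
      beta_branches = list(
        beta_branch(0.4983, 0.7940, is_positron = FALSE, daughter_Z = 72),
        beta_branch(0.3854, 0.0900, is_positron = FALSE, daughter_Z = 72),
        beta_branch(0.1766, 0.1160, is_positron = FALSE, daughter_Z = 72)),
      lines = list(
        emission_line(0.2084, 0.1038, "photon"),
        emission_line(0.1129, 0.0617, "photon"),
        emission_line(0.0478, 0.0520, "discrete_electron"),
        emission_line(0.1110, 0.0680, "discrete_electron"))))
  lib
}

#' Look up a nuclide by name
#'
#' @param name Nuclide name; tolerant of case and separator
#'   (`"F-18"`, `"f18"`, `"18F"` all match fluorine-18).
#' @param library Nuclide library, by default [build_default_library()].
#' @return A [radionuclide()].
#' @export
get_nuclide <- function(name, library = build_default_library()) {
  canon <- function(x) {
    x <- toupper(gsub("[^A-Za-z0-9]", "", x))
    # normalise "18F" -> "F18"
    m <- regmatches(x, regexec("^([0-9]+)([A-Z]+)$", x))[[1]]
    if (length(m) == 3) x <- paste0(m[3], m[2])
    x
  }
  key <- canon(name)
  hit <- which(vapply(names(library), canon, "") == key)
  if (length(hit) != 1)
    stop(sprintf("unknown nuclide '%s'", name))
  library[[hit]]
}

#' Export / import a nuclide library as JSON
#'
#' @param library Named list of [radionuclide()] objects.
#' @param path File path.
#' @return `read_nuclide_library()` returns the library;
#'   `write_nuclide_library()` returns `path` invisibly.
#' @export
write_nuclide_library <- function(library, path) {
  ser <- lapply(library, function(nuc) {
    list(name = nuc$name, physical_half_life = nuc$physical_half_life,
         annihilation = nuc$annihilation,
         beta_branches = lapply(nuc$beta_branches, unclass),
         lines = lapply(nuc$lines, unclass))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nuclide_library
#' @export
read_nuclide_library <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(r) {
    radionuclide(
      r$name, r$physical_half_life,
      beta_branches = lapply(r$beta_branches, function(b)
        beta_branch(b$endpoint_energy, b$branching_fraction,
                    b$is_positron, b$daughter_Z, b$shape)),
      lines = lapply(r$lines, function(l)
        emission_line(l$energy, l$yield_per_decay, l$kind)),
      annihilation = isTRUE(r$annihilation))
  })
  names(out) <- vapply(out, function(n) n$name, "")
  out
}

# Mean emitted charged-particle energy per decay (MeV): branch-weighted
# mean beta energy plus discrete-electron line contribution. Used by the
# radiation-equilibrium closed form.
mean_charged_energy_per_decay <- function(nuclide) {
  e <- 0
  for (b in nuclide$beta_branches)
    e <- e + b$branching_fraction * beta_mean_energy(b)
  for (l in nuclide$lines)
    if (l$kind == "discrete_electron")
      e <- e + l$yield_per_decay * l$energy
  e
}
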