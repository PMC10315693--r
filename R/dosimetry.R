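#' Cumulated decays under effective clearance
#'
#' Complete decay-plus-clearance time integral from injection to infinity
#' for single-exponential kinetics: `A0 * T_eff / ln 2` with `T_eff` in
#' seconds, i.e. the total number of decays occurring in the region.
#'
#' @param initial_activity Initial activity in Bq (> 0).
#' @param effective_half_life Effective half-life in minutes (> 0).
#' @return Number of decays (dimensionless).
#' @export
cumulated_decays <- function(initial_activity, effective_half_life) {
  if (!is.numeric(initial_activity) || initial_activity <= 0 ||
      !is.numeric(effective_half_life) || effective_half_life <= 0)
    stop("invalid kinetics: activity and half-life must be > 0")
  initial_activity * (effective_half_life * 60) / log(2)
}

# Emission descriptions per mode for a nuclide: a beta run (which also
# carries the annihilation photons), a photon-line run, and a
# discrete-electron run. Each carries its per-decay yield weight.
.emission_runs <- function(nuclide) {
  runs <- list()
  if (length(nuclide$beta_branches) > 0) {
    tab <- .beta_sampling_table(nuclide)
    runs$beta <- list(
      emission = list(kind = "beta", E = tab$E, cdf = tab$cdf,
                      is_positron = tab$is_positron),
      weight = tab$branching)
  }
  ph <- Filter(function(l) l$kind == "photon", nuclide$lines)
  if (length(ph) > 0) {
    yl <- vapply(ph, function(l) l$yield_per_decay, 0)
    runs$photon <- list(
      emission = list(kind = "photon_lines",
                      energies = vapply(ph, function(l) l$energy, 0),
                      cum_probs = cumsum(yl) / sum(yl)),
      weight = sum(yl))
  }
  el <- Filter(function(l) l$kind == "discrete_electron", nuclide$lines)
  if (length(el) > 0) {
    yl <- vapply(el, function(l) l$yield_per_decay, 0)
    runs$electron <- list(
      emission = list(kind = "electron_lines",
                      energies = vapply(el, function(l) l$energy, 0),
                      cum_probs = cumsum(yl) / sum(yl)),
      weight = sum(yl))
  }
  runs
}

#' Run the absorbed-dose simulation for a partition scenario
#'
#' For each emission mode of the nuclide (beta particles, photons,
#' discrete electrons) `n_histories` emissions are sampled from the
#' partitioned infiltrate source and transported through the phantom.
#' Per-layer energy depositions are normalised to per-decay values using
#' the mode yields, multiplied by the cumulated number of decays (complete
#' decay integral with the scenario's effective half-life) and divided by
#' the layer mass over the infiltrate footprint to give absorbed dose in
#' Gy. Annihilation photons from positron histories are tallied under the
#' photon mode.
#'
#' @param scenario A [partition_scenario()].
#' @param phantom A [skin_phantom()]; default [build_default_phantom()].
#' @param n_histories Histories per emission mode (>= 1e4; a warning below
#'   1e6, where per-layer uncertainties exceed ~1%).
#' @param seed Integer seed; mode sub-runs derive their own substreams.
#' @return An object of class `dose_report`: list with `per_layer` data
#'   frame (dose in Gy, dose per MBq infiltrated, relative SE, per-mode
#'   fractions), `mode_dose` matrix (Gy), and scenario metadata.
#' @export
run_dose_simulation <- function(scenario, phantom = build_default_phantom(),
                                n_histories = 1e6, seed = 1L) {
  if (n_histories < 1e4) stop("n_histories must be >= 1e4")
  if (n_histories < 1e6)
    warning("fewer than 1e6 histories per mode; layer uncertainties > ~1%")
  n_histories <- as.integer(n_histories)

  # source spatial distribution: concentration-weighted regions under the
  # footprint (ratio-determined; independent of the total activity)
  ref <- scenario
  ref$total_activity <- 1
  part <- partition_activity(ref, phantom)
  p <- part$activity / sum(part$activity)
  src <- list(zlo = part$zlo, zhi = part$zhi, cum_prob = cumsum(p),
              x_extent = phantom$footprint[1],
              y_extent = phantom$footprint[2])

  runs <- .emission_runs(scenario$nuclide)
  L <- length(phantom$names)
  eperdecay <- matrix(0, L, 3, dimnames = list(phantom$names,
                                               c("beta", "photon",
                                                 "discrete_electron")))
  vperdecay <- eperdecay
  escaped <- 0
  emitted <- 0
  for (k in seq_along(runs)) {
    run <- runs[[k]]
    res <- cpp_simulate(run$emission, src, .geom_list(phantom),
                        physics_tables(), n_histories,
                        as.integer(seed) + 7919L * (k - 1L))
    m <- res$sum[seq_len(L), , drop = FALSE] / res$n
    v <- res$sum2[seq_len(L), , drop = FALSE] / res$n - m^2
    eperdecay <- eperdecay + run$weight * m
    vperdecay <- vperdecay + run$weight^2 * v / res$n
    escaped <- escaped + run$weight * res$escaped / res$n
    emitted <- emitted + run$weight * res$emitted / res$n
  }

  # per-MBq normalisation: cumulated decays for 1 MBq, complete integral
  atilde_per_mbq <- cumulated_decays(1e6, scenario$effective_half_life)
  masses <- .layer_masses(phantom)
  dose_mode_per_mbq <- eperdecay * atilde_per_mbq * .MEV_J / masses
  se_mode_per_mbq <- sqrt(vperdecay) * atilde_per_mbq * .MEV_J / masses
  dpm <- rowSums(dose_mode_per_mbq)
  se_pm <- sqrt(rowSums(se_mode_per_mbq^2))
  A <- scenario$total_activity
  frac <- dose_mode_per_mbq / ifelse(dpm > 0, dpm, 1)

  per_layer <- data.frame(
    layer = phantom$names,
    mass_g = masses * 1000,
    dose_Gy = dpm * A,
    dose_per_MBq = dpm,
    se_rel = ifelse(dpm > 0, se_pm / dpm, 0),
    frac_beta = frac[, "beta"],
    frac_photon = frac[, "photon"],
    frac_discrete_electron = frac[, "discrete_electron"],
    row.names = NULL)

  structure(
    list(per_layer = per_layer,
         mode_dose = dose_mode_per_mbq * A,
         mode_dose_per_MBq = dose_mode_per_mbq,
         meta = list(nuclide = scenario$nuclide$name,
                     total_activity_MBq = A,
                     ratio = scenario$ratio,
                     effective_half_life_min = scenario$effective_half_life,
                     n_histories = n_histories, seed = as.integer(seed),
                     escaped_MeV_per_decay = escaped,
                     emitted_MeV_per_decay = emitted)),
    class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<dose_report> %s  %.4g MBq  ratio %g:1  Teff %g min  n=%g  seed=%d\n",
    m$nuclide, m$total_activity_MBq, m$ratio, m$effective_half_life_min,
    m$n_histories, m$seed))
  df <- x$per_layer
  df$dose <- sprintf("%.4g mGy", df$dose_Gy * 1e3)
  df$per_MBq <- sprintf("%.3g mGy/MBq", df$dose_per_MBq * 1e3)
  print(df[, c("layer", "dose", "per_MBq", "se_rel", "frac_beta",
               "frac_photon")], digits = 3)
  invisible(x)
}

#' Layer dose lookup
#'
#' @param report A `dose_report`.
#' @param layer Layer name, or `"dermis"` for the thickness-weighted
#'   (mass-weighted) average over papillary and reticular dermis.
#' @param per_MBq If `TRUE` return Gy/MBq instead of Gy.
#' @return Absorbed dose in Gy (or Gy/MBq).
#' @export
layer_dose <- function(report, layer, per_MBq = FALSE) {
  df <- report$per_layer
  col <- if (per_MBq) "dose_per_MBq" else "dose_Gy"
  if (layer == "dermis") {
    i <- df$layer %in% c("papillary_dermis", "reticular_dermis")
    return(sum(df[[col]][i] * df$mass_g[i]) / sum(df$mass_g[i]))
  }
  v <- df[[col]][df$layer == layer]
  if (length(v) != 1) stop(sprintf("unknown layer '%s'", layer))
  v
}

#' Linear extrapolation of a dose report to a new infiltrated activity
#'
#' All layer doses scale linearly with the infiltrated activity (fixed
#' geometry and kinetics); relative uncertainties are unchanged.
#'
#' @param report A `dose_report` with positive reference activity.
#' @param new_activity New total infiltrated activity in MBq (>= 0).
#' @return A `dose_report` at the new activity.
#' @export
extrapolate_dose <- function(report, new_activity) {
  if (!inherits(report, "dose_report")) stop("report must be a dose_report")
  if (!is.numeric(new_activity) || new_activity < 0)
    stop("invalid input: new_activity must be >= 0")
  if (report$meta$total_activity_MBq <= 0)
    stop("reference report must have positive activity")
  out <- report
  out$per_layer$dose_Gy <- report$per_layer$dose_per_MBq * new_activity
  out$mode_dose <- report$mode_dose_per_MBq * new_activity
  out$meta$total_activity_MBq <- new_activity
  out$meta$extrapolated_from_MBq <- report$meta$total_activity_MBq
  out
}

#' Per-layer emission-mode dose fractions
#'
#' @param report A `dose_report`.
#' @return Data frame of beta / photon / discrete-electron dose fractions
#'   per layer (fractions sum to 1 where the layer dose is non-zero).
#' @export
component_breakdown <- function(report) {
  report$per_layer[, c("layer", "frac_beta", "frac_photon",
                       "frac_discrete_electron")]
}

#' Compare nuclides / scenarios on a common phantom
#'
#' @param scenarios List of [partition_scenario()] (>= 2).
#' @param phantom A [skin_phantom()].
#' @param n_histories Histories per mode per scenario.
#' @param seed Integer seed.
#' @return List with `reports` (one `dose_report` per scenario) and
#'   `table`: per layer and scenario, dose (Gy), dose per MBq, and the
#'   ratio of each to the first scenario's values.
#' @export
compare_nuclides <- function(scenarios, phantom = build_default_phantom(),
                             n_histories = 1e6, seed = 1L) {
  if (length(scenarios) < 2) stop("need at least two scenarios")
  reports <- lapply(seq_along(scenarios), function(i)
    run_dose_simulation(scenarios[[i]], phantom, n_histories,
                        as.integer(seed) + 104729L * (i - 1L)))
  labs <- vapply(scenarios, function(s)
    sprintf("%s_%gMBq_%g:1", s$nuclide$name, s$total_activity, s$ratio), "")
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    df <- reports[[i]]$per_layer[, c("layer", "dose_Gy", "dose_per_MBq")]
    df$scenario <- labs[i]
    df$dose_ratio_vs_first <-
      df$dose_Gy / reports[[1]]$per_layer$dose_Gy
    df$per_MBq_ratio_vs_first <-
      df$dose_per_MBq / reports[[1]]$per_layer$dose_per_MBq
    df
  }))
  list(reports = setNames(reports, labs), table = tab)
}

#' Radiation-equilibrium check
#'
#' Simulates a uniform activity distribution in a periodic (effectively
#' infinite) homogeneous medium, where the absorbed dose per decay must
#' equal the mean emitted charged-particle energy per decay divided by the
#' region mass. Annihilation photons are not followed so the closed form
#' involves charged-particle energy only.
#'
#' @param nuclide A [radionuclide()] (or name) with a beta branch.
#' @param n_histories Number of histories.
#' @param seed Integer seed.
#' @param box_mm Edge length of the periodic box (mm).
#' @param density Medium density (g/cm^3).
#' @return List with `mc_dose_per_decay` (Gy), `closed_form` (Gy), `se`.
#' @export
equilibrium_check <- function(nuclide, n_histories = 1e5, seed = 1L,
                              box_mm = 20, density = 1.0) {
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  tab <- .beta_sampling_table(nuclide)
  geom <- list(zb = c(0, box_mm), density = density, lat_x = box_mm,
               lat_y = box_mm, fp_x = box_mm, fp_y = box_mm,
               wrap = TRUE, infinite = FALSE)
  src <- list(zlo = 0, zhi = box_mm, cum_prob = 1,
              x_extent = box_mm, y_extent = box_mm)
  em <- list(kind = "beta", E = tab$E, cdf = tab$cdf,
             is_positron = tab$is_positron)
  res <- cpp_simulate(em, src, geom, physics_tables(),
                      as.integer(n_histories), as.integer(seed),
                      follow_photons = FALSE)
  mass_kg <- (box_mm / 10)^3 * density / 1000
  m <- sum(res$sum[, 1]) / res$n          # MeV per beta emission
  v <- sum(res$sum2[, 1]) / res$n - m^2
  w <- tab$branching                      # emissions per decay
  mean_beta <- m * w
  # closed form: branch-weighted mean beta energy per decay
  cf <- sum(vapply(nuclide$beta_branches, function(b)
    b$branching_fraction * beta_mean_energy(b), 0))
  list(mc_dose_per_decay = mean_beta * .MEV_J / mass_kg,
       closed_form = cf * .MEV_J / mass_kg,
       se = w * sqrt(v / res$n) * .MEV_J / mass_kg)
}

#' Serialise a dose report
#'
#' @param report A `dose_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(meta = report$meta, per_layer = report$per_layer),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(report$per_layer, path, row.names = FALSE)
  }
  invisible(path)
}
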