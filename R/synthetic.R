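#' Cohort generator specification
#'
#' Parameters of the seeded synthetic PET cohort. Defaults emulate the
#' statistical structure of a large multicentre PET/CT cohort: ~1,000
#' patients, injected activities Normal(405, 78) MBq truncated positive,
#' about half the patients showing a small visible injection-site residual
#' (log-normal, median ~34 kBq), near-zero residuals otherwise, a low
#' contralateral background, and rare infiltration events of configurable
#' rate and magnitude. The residual distribution's log-normal form is a
#' synthetic choice (strictly positive, heavy right tail), not a claim
#' about any real cohort.
#'
#' @param n_patients Number of patients (>= 1).
#' @param injected_mean_MBq,injected_sd_MBq Injected activity moments.
#' @param residual_median_kBq Median visible residual at the injection
#'   site, kBq.
#' @param residual_sdlog Log-scale SD of the residual distribution.
#' @param visible_fraction Fraction of patients with a visible residual.
#' @param event_rate Infiltration event probability per patient.
#' @param event_fraction_injected Infiltrated fraction of the injected
#'   activity for event patients (e.g. 0.05 = 5%).
#' @param nuclide_mix Named probabilities over nuclide names.
#' @param uptake_range_min Uniform uptake-interval range, minutes.
#' @param seed Integer seed.
#' @return An object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_patients = 1000,
                            injected_mean_MBq = 405,
                            injected_sd_MBq = 78,
                            residual_median_kBq = 34,
                            residual_sdlog = 1.0,
                            visible_fraction = 0.46,
                            event_rate = 0,
                            event_fraction_injected = 0.05,
                            nuclide_mix = c("F-18" = 0.952,
                                            "Ga-68" = 0.048),
                            uptake_range_min = c(55, 75),
                            seed = 1L) {
  if (n_patients < 1) stop("invalid spec: n_patients must be >= 1")
  if (injected_sd_MBq < 0 || residual_sdlog < 0)
    stop("invalid spec: SDs must be >= 0")
  probs <- c(visible_fraction, event_rate)
  if (any(probs < 0 | probs > 1))
    stop("invalid spec: probabilities must lie in [0, 1]")
  if (abs(sum(nuclide_mix) - 1) > 1e-9)
    stop("invalid spec: nuclide_mix must sum to 1")
  structure(
    list(n_patients = as.integer(n_patients),
         injected_mean_MBq = injected_mean_MBq,
         injected_sd_MBq = injected_sd_MBq,
         residual_median_kBq = residual_median_kBq,
         residual_sdlog = residual_sdlog,
         visible_fraction = visible_fraction,
         event_rate = event_rate,
         event_fraction_injected = event_fraction_injected,
         nuclide_mix = nuclide_mix,
         uptake_range_min = uptake_range_min,
         seed = as.integer(seed)),
    class = "cohort_gen_spec")
}

#' Generate a synthetic cohort
#'
#' Seeded generator producing a list of [patient_record()]s with the
#' structure described in [cohort_gen_spec()]. VOI summaries are built so
#' that the recorded (imaging-time) net activity reflects the simulated
#' residual after physical decay over the patient's uptake interval.
#'
#' @param spec A [cohort_gen_spec()].
#' @return List of [patient_record()] of length `spec$n_patients`.
#' @export
generate_cohort <- function(spec = cohort_gen_spec()) {
  if (!inherits(spec, "cohort_gen_spec"))
    stop("generation error: spec must be a cohort_gen_spec")
  s <- spec
  withr_seed <- function(code) {  # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s$seed)
    code
  }
  withr_seed({
    n <- s$n_patients
    inj <- rnorm(n, s$injected_mean_MBq, s$injected_sd_MBq)
    while (any(inj <= 0))
      inj[inj <= 0] <- rnorm(sum(inj <= 0), s$injected_mean_MBq,
                             s$injected_sd_MBq)
    inj_bq <- inj * 1e6
    nucs <- sample(names(s$nuclide_mix), n, TRUE, s$nuclide_mix)
    uptake <- runif(n, s$uptake_range_min[1], s$uptake_range_min[2])
    visible <- runif(n) < s$visible_fraction
    # residual at injection time, Bq
    resid <- ifelse(visible,
                    rlnorm(n, log(s$residual_median_kBq * 1e3),
                           s$residual_sdlog),
                    rlnorm(n, log(2e3), 0.8))
    event <- runif(n) < s$event_rate
    resid[event] <- inj_bq[event] * s$event_fraction_injected
    routes <- sample(c("iv_catheter", "port", "picc"), n, TRUE,
                     c(0.93, 0.066, 0.004))
    sites <- sample(c("antecubital", "hand", "forearm", "wrist"), n, TRUE,
                    c(0.645, 0.135, 0.111, 0.034))
    half_life <- vapply(nucs, function(x) get_nuclide(x)$physical_half_life,
                        0)
    # activity present at imaging after physical decay
    resid_img <- resid * 2^(-uptake / half_life)
    site_vol <- runif(n, 3, 12)
    contra_vol <- site_vol * runif(n, 0.9, 1.1)
    bg_conc <- rlnorm(n, log(150), 0.5)           # Bq/cm^3 background
    site_conc <- bg_conc + resid_img / site_vol
    lapply(seq_len(n), function(i) patient_record(
      id = sprintf("P%04d", i), nuclide = nucs[i],
      injected_activity = inj_bq[i],
      injection_time = 0, imaging_time = uptake[i],
      injection_site_voi = voi_measurement(site_conc[i], site_vol[i],
                                           site_conc[i] * runif(1, 1.5, 4)),
      contralateral_voi = voi_measurement(bg_conc[i], contra_vol[i],
                                          bg_conc[i] * runif(1, 1.2, 2)),
      route = routes[i], site = sites[i],
      visual = if (event[i]) "clearly_visualized"
               else if (visible[i]) sample(c("clearly_visualized",
                                             "barely_visible"), 1)
               else "not_visible"))
  })
}

#' Ready-made infiltration dose scenarios
#'
#' Convenience fixtures pairing the default phantom with a populated
#' scenario: `"patientE"` (0.41 MBq F-18, 30 min effective half-life —
#' the measured minor-infiltration case), `"fullF18"` (470 MBq F-18,
#' hypothetical full-injection worst case), `"fullGa68"` (148 MBq Ga-68,
#' 25 min effective half-life), or a user-defined combination.
#'
#' @param fixture One of `"patientE"`, `"fullF18"`, `"fullGa68"`,
#'   `"custom"`.
#' @param activity Total infiltrated activity in MBq (for `"custom"`, or
#'   to override a fixture).
#' @param nuclide Nuclide name (for `"custom"`).
#' @param ratio Hypodermis-to-dermis concentration ratio.
#' @param effective_half_life Effective half-life in minutes (for
#'   `"custom"`; fixtures carry their own).
#' @return List with `scenario` ([partition_scenario()]) and `phantom`
#'   ([build_default_phantom()]).
#' @export
generate_infiltration_case <- function(fixture = c("patientE", "fullF18",
                                                   "fullGa68", "custom"),
                                       activity = NULL, nuclide = "F-18",
                                       ratio = 10,
                                       effective_half_life = 30) {
  fixture <- match.arg(fixture)
  pars <- switch(fixture,
    patientE = list(nuclide = "F-18", activity = 0.41, teff = 30),
    fullF18 = list(nuclide = "F-18", activity = 470, teff = 30),
    fullGa68 = list(nuclide = "Ga-68", activity = 148, teff = 25),
    custom = list(nuclide = nuclide, activity = activity,
                  teff = effective_half_life))
  if (!is.null(activity) && fixture != "custom") pars$activity <- activity
  if (is.null(pars$activity)) stop("custom fixture needs an activity")
  list(scenario = partition_scenario(pars$nuclide, pars$activity, ratio,
                                     pars$teff),
       phantom = build_default_phantom())
}
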