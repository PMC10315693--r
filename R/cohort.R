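#' VOI measurement
#'
#' Summary of a PET volume of interest: mean and maximum activity
#' concentration and the VOI volume.
#'
#' @param mean_concentration Mean concentration, Bq/cm^3 (>= 0).
#' @param volume VOI volume, cm^3 (> 0).
#' @param max_concentration Maximum concentration, Bq/cm^3
#'   (>= `mean_concentration`; defaults to the mean).
#' @return An object of class `voi_measurement`.
#' @export
voi_measurement <- function(mean_concentration, volume,
                            max_concentration = mean_concentration) {
  if (!is.numeric(volume) || volume <= 0) stop("VOI volume must be > 0")
  if (mean_concentration < 0 || max_concentration < mean_concentration)
    stop("need 0 <= mean_concentration <= max_concentration")
  structure(list(mean_concentration = mean_concentration,
                 max_concentration = max_concentration, volume = volume),
            class = "voi_measurement")
}

#' Patient record
#'
#' One row of the cohort table: injected activity, timing, and the
#' injection-site and contralateral VOI summaries.
#'
#' @param id Patient identifier.
#' @param nuclide Nuclide name (resolved through [get_nuclide()]).
#' @param injected_activity Net injected activity in Bq (> 0).
#' @param injection_time,imaging_time Times (POSIXct or minutes as
#'   numeric); imaging must not precede injection.
#' @param injection_site_voi,contralateral_voi [voi_measurement()]s.
#' @param route Injection route label (optional annotation).
#' @param site Injection site label (optional annotation).
#' @param visual Optional reader assessment (`"clearly_visualized"`,
#'   `"barely_visible"`, `"not_visible"`); annotation only, never used in
#'   the quantitative classification.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, nuclide, injected_activity, injection_time,
                           imaging_time, injection_site_voi,
                           contralateral_voi, route = NA_character_,
                           site = NA_character_, visual = NA_character_) {
  if (!is.numeric(injected_activity) || injected_activity <= 0)
    stop("injected_activity must be > 0")
  if (as.numeric(imaging_time) < as.numeric(injection_time))
    stop("invalid time: imaging precedes injection")
  structure(list(id = id, nuclide = nuclide,
                 injected_activity = injected_activity,
                 injection_time = injection_time,
                 imaging_time = imaging_time,
                 injection_site_voi = injection_site_voi,
                 contralateral_voi = contralateral_voi,
                 route = route, site = site, visual = visual),
            class = "patient_record")
}

#' Net injection-site activity
#'
#' Difference between the activity at the injection site (mean
#' concentration x VOI volume) and the activity in the contralateral VOI,
#' floored at zero (a negative difference is a background fluctuation, not
#' physical residual activity).
#'
#' @param record A [patient_record()].
#' @return Net activity at imaging time, Bq.
#' @export
net_injection_site_activity <- function(record) {
  s <- record$injection_site_voi
  c <- record$contralateral_voi
  if (is.null(s) || is.null(c))
    stop("incomplete record: both VOIs are required")
  max(0, s$mean_concentration * s$volume - c$mean_concentration * c$volume)
}

#' Decay-correct an activity back to injection time
#'
#' Uses the physical half-life only (biological clearance plays no role in
#' this bookkeeping step).
#'
#' @param activity Activity in Bq at imaging time.
#' @param elapsed Minutes between injection and imaging (>= 0).
#' @param nuclide A [radionuclide()] or nuclide name.
#' @return Activity in Bq at injection time.
#' @export
decay_correct <- function(activity, elapsed, nuclide) {
  if (any(elapsed < 0)) stop("invalid time: elapsed must be >= 0")
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  activity * 2^(elapsed / nuclide$physical_half_life)
}

#' Percent of injected activity
#'
#' @param net_activity Net activity in Bq (>= 0).
#' @param injected Injected activity in Bq (> 0).
#' @return Percentage, `100 * net / injected`.
#' @export
percent_injected <- function(net_activity, injected) {
  if (any(injected <= 0)) stop("invalid record: injected activity must be > 0")
  100 * net_activity / injected
}

#' Classify an injection site
#'
#' Strict-inequality thresholds: `negligible` up to 370 kBq decay-corrected
#' net activity; `above_370kBq` beyond that up to 1% of the injected
#' activity; `above_1pct` beyond 1% (the clinically meaningful bound).
#'
#' @param net_activity_at_injection Decay-corrected net activity, Bq.
#' @param injected Injected activity, Bq.
#' @param activity_threshold Analysis threshold in Bq (default 370 kBq).
#' @param percent_threshold Clinically meaningful bound in % (default 1).
#' @return Factor with levels `negligible`, `above_370kBq`, `above_1pct`.
#' @export
classify_injection_site <- function(net_activity_at_injection, injected,
                                    activity_threshold = 370e3,
                                    percent_threshold = 1) {
  pct <- percent_injected(net_activity_at_injection, injected)
  lv <- c("negligible", "above_370kBq", "above_1pct")
  out <- ifelse(pct > percent_threshold, "above_1pct",
                ifelse(net_activity_at_injection > activity_threshold,
                       "above_370kBq", "negligible"))
  factor(out, levels = lv)
}

#' Assess a patient record
#'
#' @param record A [patient_record()].
#' @return An `infiltration_assessment`: net activity at imaging and
#'   (decay-corrected) at injection, percent of injected activity, and
#'   category.
#' @export
assess_infiltration <- function(record) {
  net_img <- net_injection_site_activity(record)
  elapsed <- as.numeric(record$imaging_time) -
    as.numeric(record$injection_time)
  if (inherits(record$imaging_time, "POSIXct")) elapsed <- elapsed / 60
  net_inj <- decay_correct(net_img, elapsed, record$nuclide)
  structure(
    list(id = record$id,
         net_activity_at_imaging = net_img,
         net_activity_at_injection = net_inj,
         percent_injected = percent_injected(net_inj,
                                             record$injected_activity),
         category = classify_injection_site(net_inj,
                                            record$injected_activity)),
    class = "infiltration_assessment")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval from the exact binomial tail probabilities, via the beta
#' quantile representation. For zero successes the lower bound is 0 and
#' the upper bound solves the one-sided tail at alpha/2,
#' `1 - (alpha/2)^(1/n)`.
#'
#' @param successes Number of events (0 <= successes <= n).
#' @param n Sample size.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return An object of class `rate_interval` with fields `successes`,
#'   `n`, `confidence`, `estimate`, `lower`, `upper`.
#' @export
exact_binomial_ci <- function(successes, n, confidence = 0.95) {
  if (!is.numeric(successes) || !is.numeric(n) || n < 1 ||
      successes < 0 || successes > n || successes != round(successes))
    stop("invalid counts: need 0 <= successes <= n")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  a <- 1 - confidence
  lower <- if (successes == 0) 0 else qbeta(a / 2, successes,
                                            n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1,
                                            n - successes)
  structure(list(successes = successes, n = n, confidence = confidence,
                 estimate = successes / n, lower = lower, upper = upper),
            class = "rate_interval")
}

#' @export
print.rate_interval <- function(x, ...) {
  cat(sprintf(
    "%d/%d events; %.0f%% exact binomial CI for the rate: %.4f - %.4f\n",
    x$successes, x$n, 100 * x$confidence, x$lower, x$upper))
  invisible(x)
}

#' Summarise a cohort
#'
#' Assesses every record and aggregates: mean +/- SD injected activity,
#' category counts, route/site counts, a histogram of net activity, the
#' cases above the 370 kBq analysis threshold, and the exact binomial
#' interval for the above-1% infiltration rate.
#'
#' @param records List of [patient_record()] (>= 1), or a cohort data
#'   frame as produced by [cohort_to_df()] / [read_cohort_csv()].
#' @param confidence Confidence level for the rate interval.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, confidence = 0.95) {
  if (is.data.frame(records)) records <- df_to_cohort(records)
  if (length(records) == 0) stop("empty cohort")
  ass <- lapply(records, assess_infiltration)
  inj <- vapply(records, function(r) r$injected_activity, 0)
  net <- vapply(ass, function(a) a$net_activity_at_injection, 0)
  pct <- vapply(ass, function(a) a$percent_injected, 0)
  cat_ <- factor(vapply(ass, function(a) as.character(a$category), ""),
                 levels = c("negligible", "above_370kBq", "above_1pct"))
  n <- length(records)
  successes <- sum(cat_ == "above_1pct")
  above_thr <- which(cat_ != "negligible")
  breaks <- c(0, 37e3, 74e3, 185e3, 370e3, 740e3, 1.85e6, 3.7e6, Inf)
  hist_counts <- table(cut(net, breaks, right = TRUE,
                           include.lowest = TRUE))
  route <- vapply(records, function(r) as.character(r$route), "")
  site <- vapply(records, function(r) as.character(r$site), "")
  structure(
    list(n = n,
         injected_mean_MBq = mean(inj) / 1e6,
         injected_sd_MBq = if (n > 1) sd(inj) / 1e6 else NA_real_,
         category_counts = table(cat_),
         route_counts = table(route[!is.na(route)]),
         site_counts = table(site[!is.na(site)]),
         net_activity_Bq = net,
         percent_injected = pct,
         net_activity_hist = hist_counts,
         cases_above_threshold = data.frame(
           id = vapply(records[above_thr], function(r) as.character(r$id),
                       ""),
           net_activity_Bq = net[above_thr],
           percent_injected = pct[above_thr]),
         rate_interval = exact_binomial_ci(successes, n, confidence)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d patients\n", x$n))
  if (is.na(x$injected_sd_MBq))
    cat(sprintf("  injected activity: %.0f MBq (SD undefined, n = 1)\n",
                x$injected_mean_MBq))
  else
    cat(sprintf("  injected activity: %.0f +/- %.0f MBq\n",
                x$injected_mean_MBq, x$injected_sd_MBq))
  cat("  categories: ")
  print(x$category_counts)
  print(x$rate_interval)
  invisible(x)
}

# --- cohort table I/O -----------------------------------------------------

#' Convert between a cohort record list and a flat data frame
#'
#' The column dictionary: `id`, `nuclide`, `injected_activity_bq`,
#' `injection_time_min`, `imaging_time_min`, `site_mean_bq_cm3`,
#' `site_max_bq_cm3`, `site_volume_cm3`, `contra_mean_bq_cm3`,
#' `contra_max_bq_cm3`, `contra_volume_cm3`, `route`, `site`, `visual`.
#'
#' @param records List of [patient_record()].
#' @return `cohort_to_df()` a data frame; `df_to_cohort()` a record list.
#' @export
cohort_to_df <- function(records) {
  out <- do.call(rbind, lapply(records, function(r) data.frame(
    id = as.character(r$id), nuclide = unname(r$nuclide),
    injected_activity_bq = r$injected_activity,
    injection_time_min = as.numeric(r$injection_time),
    imaging_time_min = as.numeric(r$imaging_time),
    site_mean_bq_cm3 = r$injection_site_voi$mean_concentration,
    site_max_bq_cm3 = r$injection_site_voi$max_concentration,
    site_volume_cm3 = r$injection_site_voi$volume,
    contra_mean_bq_cm3 = r$contralateral_voi$mean_concentration,
    contra_max_bq_cm3 = r$contralateral_voi$max_concentration,
    contra_volume_cm3 = r$contralateral_voi$volume,
    route = r$route, site = r$site, visual = r$visual)))
  rownames(out) <- NULL
  out
}

#' @rdname cohort_to_df
#' @param df Cohort data frame with the documented columns.
#' @export
df_to_cohort <- function(df) {
  lapply(seq_len(nrow(df)), function(i) patient_record(
    id = df$id[i], nuclide = df$nuclide[i],
    injected_activity = df$injected_activity_bq[i],
    injection_time = df$injection_time_min[i],
    imaging_time = df$imaging_time_min[i],
    injection_site_voi = voi_measurement(df$site_mean_bq_cm3[i],
                                         df$site_volume_cm3[i],
                                         df$site_max_bq_cm3[i]),
    contralateral_voi = voi_measurement(df$contra_mean_bq_cm3[i],
                                        df$contra_volume_cm3[i],
                                        df$contra_max_bq_cm3[i]),
    route = df$route[i], site = df$site[i], visual = df$visual[i]))
}

#' Read / write a cohort CSV
#'
#' @param path File path.
#' @param records List of [patient_record()].
#' @return `read_cohort_csv()` a list of records; `write_cohort_csv()`
#'   `path` invisibly.
#' @export
read_cohort_csv <- function(path) df_to_cohort(read.csv(path))

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(cohort_to_df(records), path, row.names = FALSE)
  invisible(path)
}
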