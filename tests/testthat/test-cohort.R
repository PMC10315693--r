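rec_with <- function(site_conc, site_vol, contra_conc, contra_vol,
                     injected = 400e6, uptake = 60, nuclide = "F-18") {
  patient_record("P1", nuclide, injected, 0, uptake,
                 voi_measurement(site_conc, site_vol),
                 voi_measurement(contra_conc, contra_vol))
}

test_that("net injection-site activity is the floored VOI difference", {
  expect_equal(net_injection_site_activity(
    rec_with(10e3, 5, 1e3, 5)), 45e3)
  # contralateral >= site floors at zero
  expect_equal(net_injection_site_activity(
    rec_with(1e3, 5, 10e3, 5)), 0)
  expect_equal(net_injection_site_activity(
    rec_with(2e3, 4, 2e3, 4)), 0)
})

test_that("decay correction uses the physical half-life and inverts", {
  expect_equal(decay_correct(5e3, 0, "F-18"), 5e3)
  t12 <- get_nuclide("F-18")$physical_half_life
  expect_equal(decay_correct(100e3, t12, "F-18"), 200e3)
  expect_equal(decay_correct(50e3, 2 * t12, "F-18"), 200e3)
  # correcting then un-correcting returns the original value
  for (el in c(13.7, 61.2, 140)) {
    a <- decay_correct(77e3, el, "Ga-68")
    expect_equal(a * 2^(-el / get_nuclide("Ga-68")$physical_half_life),
                 77e3, tolerance = 1e-12)
  }
  expect_error(decay_correct(1e3, -5, "F-18"), "invalid time")
})

test_that("percent of injected activity reproduces the worked examples", {
  # 370 kBq of 407 MBq is ~0.1% after rounding to one decimal
  expect_equal(round(percent_injected(370e3, 407e6), 1), 0.1)
  # 34 kBq of 407 MBq is ~0.008% at one significant figure
  expect_equal(signif(percent_injected(34e3, 407e6), 1), 0.008)
  expect_identical(percent_injected(0, 407e6), 0)
  expect_error(percent_injected(1e3, 0), "invalid record")
})

test_that("classification applies strict thresholds and is monotone", {
  inj <- 400e6
  expect_identical(as.character(classify_injection_site(369e3, inj)),
                   "negligible")
  expect_identical(as.character(classify_injection_site(370e3, inj)),
                   "negligible")  # strictly 'more than' 370 kBq
  # 1.65 MBq of 400 MBq is 0.41% < 1%
  expect_identical(as.character(classify_injection_site(1.65e6, inj)),
                   "above_370kBq")
  expect_identical(as.character(classify_injection_site(5e6, inj)),
                   "above_1pct")
  # increasing net activity never lowers the category
  cats <- as.integer(classify_injection_site(
    seq(0, 10e6, length.out = 400), inj))
  expect_true(all(diff(cats) >= 0))
})

test_that("exact binomial interval matches tail-sum bisection oracle", {
  # oracle: bisection on the exact binomial tail sums
  tail_upper <- function(x, n, a) {  # smallest p with P(X <= x) <= a/2
    f <- function(p) pbinom(x, n, p) - a / 2
    uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  tail_lower <- function(x, n, a) {  # largest p with P(X >= x) <= a/2
    f <- function(p) 1 - pbinom(x - 1, n, p) - a / 2
    uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  cases <- list(c(5, 10), c(1, 30), c(7, 12), c(0, 50), c(10, 10))
  for (cs in cases) {
    x <- cs[1]; n <- cs[2]
    ci <- exact_binomial_ci(x, n, 0.95)
    if (x > 0)
      expect_equal(ci$lower, tail_lower(x, n, 0.05), tolerance = 1e-8)
    else expect_identical(ci$lower, 0)
    if (x < n)
      expect_equal(ci$upper, tail_upper(x, n, 0.05), tolerance = 1e-8)
    else expect_identical(ci$upper, 1)
  }
  # zero-success closed form 1 - (alpha/2)^(1/n)
  ci <- exact_binomial_ci(0, 1000, 0.95)
  expect_equal(ci$upper, 1 - 0.025^(1 / 1000), tolerance = 1e-12)
  expect_error(exact_binomial_ci(-1, 10), "invalid counts")
  expect_error(exact_binomial_ci(11, 10), "invalid counts")
  expect_error(exact_binomial_ci(1, 10, 1.2), "confidence")
})

test_that("exact interval achieves nominal coverage for rare events", {
  set.seed(77)
  p <- 0.002
  n <- 1000
  reps <- 2000
  xs <- rbinom(reps, n, p)
  covered <- vapply(xs, function(x) {
    ci <- exact_binomial_ci(x, n, 0.95)
    ci$lower <= p && p <= ci$upper
  }, TRUE)
  # exact intervals are conservative: coverage >= 95% up to MC error
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("cohort summary composes assessments and the rate interval", {
  recs <- generate_cohort(cohort_gen_spec(n_patients = 120, seed = 5))
  s <- summarize_cohort(recs)
  expect_identical(s$n, 120L)
  expect_identical(s$rate_interval$successes,
                   sum(unname(s$category_counts["above_1pct"])))
  ci <- exact_binomial_ci(s$rate_interval$successes, 120, 0.95)
  expect_equal(s$rate_interval$upper, ci$upper)
  # single record: SD reported as absent
  s1 <- summarize_cohort(recs[1])
  expect_true(is.na(s1$injected_sd_MBq))
  expect_error(summarize_cohort(list()), "empty")
})

test_that("cohort tables round-trip through CSV", {
  recs <- generate_cohort(cohort_gen_spec(n_patients = 25, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(recs, path)
  back <- read_cohort_csv(path)
  expect_equal(cohort_to_df(back), cohort_to_df(recs), tolerance = 1e-12)
  a1 <- assess_infiltration(recs[[10]])
  a2 <- assess_infiltration(back[[10]])
  expect_equal(a1$net_activity_at_injection, a2$net_activity_at_injection,
               tolerance = 1e-9)
})
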