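test_that("cumulated decays follow the closed decay-plus-clearance integral", {
  # unit construction: 1 Bq over T_eff = ln(2) seconds -> exactly 1 decay
  expect_equal(cumulated_decays(1, log(2) / 60), 1, tolerance = 1e-12)
  # closed form vs numeric integration of A0 * 2^(-t/T)
  oracle <- integrate(function(t) 0.41e6 * 2^(-t / (30 * 60)), 0, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(cumulated_decays(0.41e6, 30), oracle, tolerance = 1e-8)
  # linearity in the initial activity
  expect_equal(cumulated_decays(470e6, 30),
               470 / 0.41 * cumulated_decays(0.41e6, 30),
               tolerance = 1e-12)
  expect_error(cumulated_decays(0, 30), "invalid kinetics")
  expect_error(cumulated_decays(1, -1), "invalid kinetics")
})

test_that("dose reports are seed-deterministic and linear in activity", {
  sc1 <- partition_scenario("F-18", 0.41, 10, 30)
  sc2 <- partition_scenario("F-18", 0.82, 10, 30)
  r1 <- suppressWarnings(run_dose_simulation(sc1, n_histories = 1e4,
                                             seed = 2))
  r1b <- suppressWarnings(run_dose_simulation(sc1, n_histories = 1e4,
                                              seed = 2))
  r2 <- suppressWarnings(run_dose_simulation(sc2, n_histories = 1e4,
                                             seed = 2))
  expect_identical(r1$per_layer, r1b$per_layer)  # bit-identical
  expect_equal(r2$per_layer$dose_Gy, 2 * r1$per_layer$dose_Gy,
               tolerance = 1e-12)
  expect_equal(r2$per_layer$dose_per_MBq, r1$per_layer$dose_per_MBq,
               tolerance = 1e-12)
})

test_that("zero-activity scenario yields a zero-dose report", {
  sc <- partition_scenario("F-18", 0, 10, 30)
  r <- suppressWarnings(run_dose_simulation(sc, n_histories = 1e4,
                                            seed = 1))
  expect_true(all(r$per_layer$dose_Gy == 0))
  expect_true(all(r$per_layer$dose_per_MBq > 0))  # per-MBq still defined
})

test_that("mode fractions sum to one and breakdown exposes them", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  r <- suppressWarnings(run_dose_simulation(sc, n_histories = 2e4,
                                            seed = 4))
  cb <- component_breakdown(r)
  sums <- rowSums(cb[, -1])
  nz <- r$per_layer$dose_Gy > 0
  expect_equal(unname(sums[nz]), rep(1, sum(nz)), tolerance = 1e-6)
})

test_that("extrapolation scales doses linearly and keeps uncertainty", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  r <- suppressWarnings(run_dose_simulation(sc, n_histories = 1e4,
                                            seed = 6))
  same <- extrapolate_dose(r, 0.41)
  expect_equal(same$per_layer$dose_Gy, r$per_layer$dose_Gy,
               tolerance = 1e-12)
  up <- extrapolate_dose(r, 470)
  expect_equal(up$per_layer$dose_Gy,
               r$per_layer$dose_Gy * 470 / 0.41, tolerance = 1e-12)
  expect_equal(up$per_layer$se_rel, r$per_layer$se_rel)
  expect_identical(up$meta$total_activity_MBq, 470)
  expect_error(extrapolate_dose(r, -1), "invalid input")
})

test_that("uniform source in a periodic medium reaches radiation equilibrium", {
  eq <- equilibrium_check("Y-90", n_histories = 2e4, seed = 3)
  expect_lt(abs(eq$mc_dose_per_decay - eq$closed_form), 3 * eq$se)
  eq2 <- equilibrium_check("F-18", n_histories = 2e4, seed = 3)
  expect_lt(abs(eq2$mc_dose_per_decay - eq2$closed_form), 3 * eq2$se)
})

test_that("reported uncertainties match the spread across seeds", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  doses <- c()
  ses <- c()
  for (s in 1:10) {
    r <- suppressWarnings(run_dose_simulation(sc, n_histories = 2e4,
                                              seed = 100 + s))
    i <- r$per_layer$layer == "hypodermis"
    doses <- c(doses, r$per_layer$dose_Gy[i])
    ses <- c(ses, r$per_layer$se_rel[i] * r$per_layer$dose_Gy[i])
  }
  ratio <- sd(doses) / mean(ses)
  expect_lt(ratio, 1.5)
  expect_gt(ratio, 1 / 1.5)
})

test_that("per-layer uncertainty shrinks as 1/sqrt(N)", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  ses <- vapply(c(1e4, 1e5), function(n) {
    r <- suppressWarnings(run_dose_simulation(sc, n_histories = n,
                                              seed = 5))
    r$per_layer$se_rel[r$per_layer$layer == "hypodermis"]
  }, 0)
  expect_equal(ses[1] / ses[2], sqrt(10), tolerance = 0.25)
})

test_that("dose report serialises to JSON and CSV", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  r <- suppressWarnings(run_dose_simulation(sc, n_histories = 1e4,
                                            seed = 8))
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_dose_report(r, jf)
  write_dose_report(r, cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$per_layer$dose_Gy, r$per_layer$dose_Gy)
  expect_equal(read.csv(cf)$dose_per_MBq, r$per_layer$dose_per_MBq)
})
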