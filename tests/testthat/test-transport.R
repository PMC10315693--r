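test_that("stopping power decreases over 0.1-1 MeV and scales with density", {
  e <- seq(0.1, 1, by = 0.05)
  s <- stopping_power(water, e)
  expect_true(all(diff(s) < 0))
  adipose <- tissue_material("adipose", 0.95, "adipose")
  expect_equal(stopping_power(adipose, e), s * 0.95, tolerance = 1e-12)
  expect_warning(stopping_power(water, 5), "clamped")
})

test_that("CSDA range matches independent quadrature of the embedded table", {
  # independent oracle: trapezoid integral of 1/S over the table itself
  oracle <- trapz(function(e) 1 / (stopping_power(water, e) * 10),
                  0.01, 1, n = 20001)  # g/cm2
  expect_equal(csda_range(1), oracle, tolerance = 0.01)
  # in mm for unit density: g/cm2 * 10
  expect_equal(csda_range(1, water), csda_range(1) * 10, tolerance = 1e-9)
})

test_that("every history conserves energy exactly", {
  set.seed(11)
  for (i in 1:60) {
    kind <- sample(c("electron", "positron", "photon"), 1)
    st <- particle_state(kind,
                         position = c(runif(1, -15, 15), runif(1, -8, 8),
                                      runif(1, 0.05, 8)),
                         direction = rnorm(3),
                         energy = runif(1, 0.02, 2))
    r <- transport_particle(st, default_phantom, seed = i)
    emitted <- st$energy + if (kind == "positron") 2 * 0.51099895 else 0
    expect_lt(abs(sum(r$events$energy_deposited) + r$escaped - emitted),
              1e-9)
    expect_true(all(r$events$energy_deposited >= 0))
  }
})

test_that("zero-energy and invalid particles are handled", {
  st <- particle_state("electron", c(0, 0, 1), c(0, 0, 1), 0)
  r <- transport_particle(st, default_phantom)
  expect_identical(nrow(r$events), 0L)
  expect_error(particle_state("electron", c(0, 0, NaN), c(0, 0, 1), 1),
               "corrupted")
  expect_error(particle_state("electron", energy = -1), "corrupted")
  expect_error(
    transport_particle(particle_state("photon", c(0, 0, -5), c(0, 0, 1),
                                      0.5), default_phantom),
    "outside")
})

test_that("photon slab attenuation matches the closed form", {
  # 0.511 MeV photons fired straight down an 8 mm water slab: the
  # interacting fraction must equal 1 - exp(-mu * 8 mm)
  slab <- skin_phantom(
    list(skin_layer("deep_tissue", 8, water)),
    lateral_extent = c(4000, 4000), footprint = c(4000, 4000))
  mu_mm <- photon_attenuation(0.511)$mu_total * 1.0 / 10
  expected <- 1 - exp(-mu_mm * 8)
  n <- 2e4
  interacted <- 0L
  for (i in seq_len(n)) {
    r <- transport_particle(
      particle_state("photon", c(0, 0, 1e-9), c(0, 0, 1), 0.511),
      slab, seed = i)
    if (nrow(r$events) > 0) interacted <- interacted + 1L
  }
  frac <- interacted / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("mean penetration depth increases with mean beta energy", {
  # ordering by spectrum mean energy: Lu-177 (0.13 MeV) < F-18 (0.25)
  # < Ga-68 (0.84) < Y-90 (0.97 MeV)
  r <- vapply(c("Lu-177", "F-18", "Ga-68", "Y-90"), function(nm)
    mean_range(nm, n_histories = 2e4, seed = 9)$mean, 0)
  expect_true(all(diff(r) > 0))
})

test_that("range estimates are seed-deterministic", {
  a <- mean_range("F-18", n_histories = 2000, seed = 5)
  b <- mean_range("F-18", n_histories = 2000, seed = 5)
  c <- mean_range("F-18", n_histories = 2000, seed = 6)
  expect_identical(a$mean, b$mean)
  expect_false(identical(a$mean, c$mean))
  expect_error(mean_range("F-18", n_histories = 10), ">= 1000")
})
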