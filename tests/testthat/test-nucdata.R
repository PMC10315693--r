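test_that("beta spectrum density is normalised, vanishes at endpoint", {
  for (nm in names(nuclib)) {
    for (b in nuclib[[nm]]$beta_branches) {
      integral <- integrate(function(e) beta_spectrum_pdf(b, e),
                            0, b$endpoint_energy, rel.tol = 1e-9,
                            subdivisions = 500L)$value
      expect_equal(integral, 1, tolerance = 1e-6)
      expect_identical(beta_spectrum_pdf(b, b$endpoint_energy), 0)
      expect_identical(beta_spectrum_pdf(b, b$endpoint_energy * 2), 0)
    }
  }
  expect_error(beta_branch(-1, 0.5), "endpoint")
  expect_error(beta_branch(1, 0), "branching")
  expect_error(beta_spectrum_pdf(beta_branch(0.6, 1), -0.1), ">= 0")
})

test_that("mean branch energies match quadrature and known magnitudes", {
  # 18F: quadrature oracle frozen from trapezoid integration of the pdf
  f18 <- nuclib[["F-18"]]$beta_branches[[1]]
  m_f18 <- trapz(function(e) e * beta_spectrum_pdf(f18, e),
                 0, f18$endpoint_energy, n = 8001)
  expect_equal(beta_mean_energy(f18), m_f18, tolerance = 1e-4)
  expect_equal(m_f18, 0.2504, tolerance = 2e-3)
  # 90Y average beta energy is close to 1 MeV
  y90 <- nuclib[["Y-90"]]$beta_branches[[1]]
  expect_equal(beta_mean_energy(y90), 0.97, tolerance = 0.08)
})

test_that("beta energy sampling reproduces the spectrum", {
  for (nm in c("F-18", "Lu-177")) {
    nuc <- nuclib[[nm]]
    es <- sample_beta_energy(nuc, 1e5, seed = 42)
    emax <- max(vapply(nuc$beta_branches,
                       function(b) b$endpoint_energy, 0))
    expect_true(all(es < emax))
    expect_true(all(es >= 0))
    # mean within 3 SE of the branch-weighted quadrature mean
    fr <- vapply(nuc$beta_branches, function(b) b$branching_fraction, 0)
    qmean <- sum(fr * vapply(nuc$beta_branches, beta_mean_energy, 0)) /
      sum(fr)
    se <- sd(es) / sqrt(length(es))
    expect_lt(abs(mean(es) - qmean), 3 * se)
    # KS distance of the empirical CDF against the quadrature CDF
    tab <- skindose:::.beta_sampling_table(nuc)
    ks <- max(abs(ecdf(es)(tab$E) - tab$cdf))
    expect_lt(ks, 0.01)
  }
  # fixed seed reproduces the identical sequence
  expect_identical(sample_beta_energy(nuclib[["F-18"]], 1000, seed = 7),
                   sample_beta_energy(nuclib[["F-18"]], 1000, seed = 7))
  expect_error(sample_beta_energy(
    radionuclide("x", 10, lines = list(emission_line(0.1, 0.5))), 10),
    "unsupported|no beta")
})

test_that("mean sampled energy increases with endpoint across nuclides", {
  means <- vapply(c("Lu-177", "F-18", "Ga-68", "Y-90"), function(nm)
    mean(sample_beta_energy(nuclib[[nm]], 2e4, seed = 3)), 0)
  expect_true(all(diff(means) > 0))
})

test_that("default library carries the documented decay data", {
  expect_setequal(names(nuclib), c("F-18", "Ga-68", "Y-90", "Lu-177"))
  expect_equal(nuclib[["F-18"]]$physical_half_life, 110, tolerance = 0.01)
  # 90Y is a pure beta emitter
  expect_length(Filter(function(l) l$kind == "photon",
                       nuclib[["Y-90"]]$lines), 0)
  expect_false(nuclib[["Y-90"]]$annihilation)
  # 68Ga has both a beta+ branch and a gamma line
  expect_true(nuclib[["Ga-68"]]$annihilation)
  expect_gt(length(nuclib[["Ga-68"]]$beta_branches), 0)
  expect_gt(length(Filter(function(l) l$kind == "photon",
                          nuclib[["Ga-68"]]$lines)), 0)
  # total beta branching never exceeds 1
  for (nuc in nuclib)
    expect_lte(sum(vapply(nuc$beta_branches,
                          function(b) b$branching_fraction, 0)), 1)
  # name normalisation
  expect_identical(get_nuclide("18F")$name, "F-18")
  expect_identical(get_nuclide("ga68")$name, "Ga-68")
  expect_error(get_nuclide("Tc-99m"), "unknown")
})

test_that("nuclide library survives a JSON round trip", {
  path <- tempfile(fileext = ".json")
  write_nuclide_library(nuclib, path)
  back <- read_nuclide_library(path)
  expect_setequal(names(back), names(nuclib))
  expect_equal(back[["Lu-177"]]$beta_branches[[1]]$endpoint_energy,
               nuclib[["Lu-177"]]$beta_branches[[1]]$endpoint_energy)
  expect_equal(back[["Ga-68"]]$lines[[1]]$yield_per_decay,
               nuclib[["Ga-68"]]$lines[[1]]$yield_per_decay)
  expect_identical(back[["Y-90"]]$beta_branches[[1]]$shape,
                   "forbidden_unique")
})
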