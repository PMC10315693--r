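test_that("default phantom reproduces the documented geometry", {
  ph <- default_phantom
  th <- setNames(ph$thickness, ph$names)
  expect_equal(unname(th["papillary_dermis"] + th["reticular_dermis"]), 1.2)
  expect_equal(unname(th["hypodermis"]), 6.8)
  expect_equal(unname(th["epidermis"]), 0.06)
  # geometry closure: boundaries accumulate the thicknesses
  expect_equal(max(ph$z_boundaries), sum(ph$thickness))
  # infiltrate source volume 3.6 x 2.1 x 0.8 cm
  reg <- skindose:::.source_regions(ph)
  expect_equal(sum(reg$volume), 6.048, tolerance = 1e-12)
  expect_warning(build_default_phantom(0.08), "band")
  expect_error(build_default_phantom(-0.01), "invalid geometry")
  expect_error(skin_phantom(list(skin_layer("epidermis", 1, water)),
                            c(10, 10), c(20, 20)), "footprint")
})

test_that("activity partition solves the two linear constraints exactly", {
  for (ratio in c(10, 5, 2, 1)) {
    sc <- partition_scenario("F-18", 0.41, ratio, 30)
    part <- partition_activity(sc, default_phantom)
    ch <- part$concentration[part$region == "hypodermis"]
    cd <- part$concentration[part$region == "dermis"]
    expect_equal(ch / cd, ratio, tolerance = 1e-12)
    expect_equal(sum(part$activity), 0.41e6, tolerance = 1e-9)
  }
  # independent 2x2 linear solve for the 10:1 default-phantom case
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  part <- partition_activity(sc, default_phantom)
  Vd <- part$volume[part$region == "dermis"]
  Vh <- part$volume[part$region == "hypodermis"]
  ab <- solve(matrix(c(10, -1, Vd, Vh), 2, 2, byrow = TRUE),
              c(0, 0.41e6))  # 10*cd - ch = 0 ; Vd*cd + Vh*ch = A
  expect_equal(part$concentration[part$region == "dermis"], ab[1],
               tolerance = 1e-12)
  expect_equal(part$concentration[part$region == "hypodermis"], ab[2],
               tolerance = 1e-12)
})

test_that("scenario validation enforces kinetics and ratio", {
  expect_error(partition_scenario("F-18", 0.41, 0, 30), "ratio")
  expect_error(partition_scenario("F-18", -1, 10, 30), ">= 0")
  expect_error(partition_scenario("F-18", 0.41, 10, 200),
               "cannot exceed")  # longer than the 18F physical half-life
  expect_error(partition_scenario("F-18", 0.41, 10, -5), "invalid kinetics")
})

test_that("emission sites follow the activity partition", {
  sc <- partition_scenario("F-18", 0.41, 10, 30)
  part <- partition_activity(sc, default_phantom)
  sites <- sample_emission_site(part, default_phantom, 2e4, seed = 21)
  # all sites inside the footprint and inside the dermis+hypodermis span
  expect_true(all(abs(sites$x) <= 18 & abs(sites$y) <= 10.5))
  expect_true(all(sites$z >= 0.06 & sites$z < 8.06))
  # hypodermis fraction within 3 SE of A_h / (A_h + A_d)
  p_exp <- part$activity[part$region == "hypodermis"] / sum(part$activity)
  p_obs <- mean(sites$region == "hypodermis")
  se <- sqrt(p_exp * (1 - p_exp) / nrow(sites))
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # reproducible
  expect_identical(sites,
                   sample_emission_site(part, default_phantom, 2e4,
                                        seed = 21))
  part0 <- part
  part0$activity <- c(0, 0)
  expect_error(sample_emission_site(part0, default_phantom, 10),
               "no source")
})
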