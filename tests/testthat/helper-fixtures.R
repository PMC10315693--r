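# Shared fixtures: built once per test run.

nuclib <- build_default_library()
default_phantom <- build_default_phantom()

# water at unit density, the reference medium for range checks
water <- tissue_material("soft_tissue", 1.0)

# quick patient-E style scenario
patientE_scenario <- function(ratio = 10) {
  partition_scenario("F-18", 0.41, ratio, 30)
}

# independent trapezoid quadrature of a function on [a, b]
trapz <- function(f, a, b, n = 4001) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}
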