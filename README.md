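# skindose

Microscale skin dosimetry and cohort quantitation of radiopharmaceutical
injection-site infiltration.

When part of a PET tracer injection leaks into the tissue around the vein,
the activity pools in the subcutaneous fat under a stack of skin layers
with very different radiosensitivities. `skindose` answers the two
questions that matter for that event:

1. **Tissue level** — what absorbed dose does an infiltrate deliver to
   the epidermis, dermis and subcutaneous fat? A coupled
   electron/positron–photon Monte Carlo engine (Rcpp core) transports
   Fermi-spectrum beta particles, annihilation photons, gamma lines and
   conversion electrons through a layered skin phantom (epidermis,
   papillary/reticular dermis, hypodermis, deep tissue), with the
   infiltrated activity partitioned between hypodermis and dermis at a
   configurable concentration ratio and cleared with an effective
   half-life. Doses are tallied per layer and per emission mode, so the
   model resolves the *dermal beta-shield*: the ~1.2 mm dermis absorbs
   most beta energy from subcutaneous sources and protects the epidermis
   for short-range emitters such as F-18, but not for the higher-energy
   positrons of Ga-68.
2. **Cohort level** — how often do meaningful infiltrations happen?
   Net injection-site activity is quantified from PET volume-of-interest
   summaries (mean concentration × volume, contralateral-subtracted,
   decay-corrected), classified against the 370 kBq and 1%-of-injected
   thresholds, and the infiltration rate gets an exact Clopper–Pearson
   binomial confidence interval: for 0 events in *n* patients the 95%
   upper bound is `1 − 0.025^(1/n)` — 0.0037 at n = 1000.

The core dose quantity per layer is
`D = Ã · Σ_modes y_mode · Ē_layer,mode / m_layer`, with cumulated decays
`Ã = A₀ · T_eff / ln 2` (complete decay-plus-clearance integral), `y` the
emissions per decay, `Ē` the mean tallied energy per emission and `m` the
layer mass under the 36 × 21 mm infiltrate footprint. Doses per MBq are
activity-independent, so hypothetical full-injection infiltrations are
linear extrapolations.

Intended users: medical physicists and nuclear-medicine researchers who
need infiltration dose estimates that respect skin microanatomy, and
anyone auditing infiltration-frequency claims quantitatively.

## Worked example

The measured minor-infiltration case — 0.41 MBq of F-18 pooled under a
36 × 21 mm footprint, 10:1 hypodermis:dermis concentration ratio, 30 min
effective clearance half-life:

```r
library(skindose)
case <- generate_infiltration_case("patientE", ratio = 10)
rep  <- run_dose_simulation(case$scenario, case$phantom,
                            n_histories = 1e5, seed = 1)
print(rep)
#> <dose_report> F-18  0.41 MBq  ratio 10:1  Teff 30 min  n=100000  seed=1
#>              layer       dose       per_MBq  se_rel frac_beta frac_photon
#> 1        epidermis  0.574 mGy   1.4 mGy/MBq 0.06229     0.456      0.5439
#> 2 papillary_dermis 0.5991 mGy  1.46 mGy/MBq 0.07307     0.498      0.5021
#> 3 reticular_dermis  1.806 mGy   4.4 mGy/MBq 0.01531     0.741      0.2593
#> 4       hypodermis  8.516 mGy  20.8 mGy/MBq 0.00186     0.923      0.0769
#> 5      deep_tissue 0.2124 mGy 0.518 mGy/MBq 0.01086     0.240      0.7602
```

Reading it: the hypodermis — where the activity pools — receives ~8.5 mGy,
dominated (92%) by beta particles. The epidermis receives ~0.6 mGy, and
more than half of even that little is photon dose: the dermis has
shielded the epidermis from the subcutaneous beta flux. Scaling to a
hypothetical full-injection 470 MBq infiltration is linear:

```r
layer_dose(extrapolate_dose(rep, 470), "epidermis")   # ~0.66 Gy
```

The rate side composes the same way:

```r
print(exact_binomial_ci(0, 1000, 0.95))
#> 0/1000 events; 95% exact binomial CI for the rate: 0.0000 - 0.0037

mean_range("F-18", n_histories = 1e5, seed = 1)$mean  # 0.52 mm in tissue
```

A seeded synthetic cohort with realistic statistical structure
(n = 1000, injected activity 405 ± 78 MBq, ~half the patients with a
small visible residual) exercises the whole pipeline without any data
download — see `generate_cohort()` and `summarize_cohort()`. YAML-driven
runs (dose simulation, cohort quantitation, rate estimation, synthetic
generation, figures) go through `sd_run()`; a thin command-line wrapper
is installed at `system.file("cli", "skindose.R", package = "skindose")`.

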