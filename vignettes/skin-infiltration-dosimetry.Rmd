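---
title: "Microscale skin dosimetry of radiopharmaceutical infiltration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscale skin dosimetry of radiopharmaceutical infiltration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindose)
```

## The problem

When a PET radiopharmaceutical injection partially leaks into the
perivascular tissue (an *infiltration*), the activity pools in the skin
instead of circulating. Two questions follow. First, at cohort level: how
often does this happen, and how much activity is actually involved, when
it is measured quantitatively from the PET images rather than judged
visually? Second, at tissue level: what absorbed dose does an infiltrate
deliver to the radiosensitive epidermis, given that skin is not a uniform
slab but a stack of layers — a thin proliferative epidermis (50–70 µm),
a dense fibrous dermis (~1.2 mm) that admits very little fluid, and a
deformable subcutaneous fat layer (hypodermis) where infiltrated fluid
actually pools?

`skindose` implements both pillars: a microscale Monte Carlo absorbed-dose
model for a layered skin phantom with an activity partition between
hypodermis and dermis, and a cohort pipeline that converts PET
volume-of-interest (VOI) summaries into net injection-site activities,
classifies them, and puts an exact binomial confidence interval on the
infiltration rate.

## Radionuclide data and beta spectra

The built-in library (`build_default_library()`) carries F-18, Ga-68,
Y-90 and Lu-177 with half-lives, beta endpoints, branching fractions and
principal photon / conversion-electron lines taken from the standard
decay-data compilations (NNDC/ENSDF as tabulated for MIRD use). Different
compilations can disagree in the third significant figure; results here
are reported to two. Conversion-electron and Auger lines are kept only
when yield × energy exceeds 1 keV per decay — weaker lines are below the
statistical resolution of the dose tallies. User-defined nuclides can be
supplied as JSON (`read_nuclide_library()`).

Beta spectra use the allowed Fermi shape
$N(E) \propto F(Z,E)\, p\, E_{tot}\, (Q-E)^2$
with the nonrelativistic Fermi-function Coulomb correction
$F = 2\pi\eta / (1-e^{-2\pi\eta})$, $\eta = \pm Z\alpha/\beta$ (daughter
$Z$; negative sign for positrons). Y-90's transition is first-forbidden
unique, so the standard shape factor $p^2 + q^2$ is applied (available to
any branch via `shape = "forbidden_unique"`); with it the Y-90 mean beta
energy evaluates to ≈0.97 MeV. Sampling is by inverse-CDF lookup on a
4096-point quadrature grid; the empirical CDF of $10^5$ draws stays
within Kolmogorov–Smirnov distance 0.01 of the quadrature CDF.

## Transport model

Charged particles use class-I condensed history:

* **Energy loss.** Collisional stopping powers for liquid water are
  embedded as a versioned CSV (`inst/extdata/stopping_power_water.csv`,
  ESTAR values, 10 keV–3 MeV) and log-log interpolated; other tissues
  scale by density. Radiative loss is omitted — the soft-tissue radiative
  fraction is below 1% at these energies. No delta rays are produced
  (targets are layer-integrated doses at two significant figures).
* **Stepping.** Step length is capped at 5% of the residual CSDA range
  and at the distance to the next layer boundary; the continuous loss of
  each step is deposited in the layer containing the step midpoint.
* **Multiple scattering.** Each step applies a Highland-model Gaussian
  deflection, $\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}
  \sqrt{x/X_0}\,[1 + 0.038 \ln(x/X_0)]$ with $X_0 = 36.08$ g/cm² for
  water. The logarithmic bracket is evaluated per step — the step being
  the unit of independent angular sampling — and clamped at 0.25. Two
  published conventions exist (per-step versus whole-path evaluation of
  the bracket); the per-step form was adopted because it reproduces
  published positron-range benchmarks in water (mean 3D displacement
  ≈0.55–0.65 mm for F-18, ≈0.23 mm for Lu-177) more closely.
* **Termination.** Histories end below 10 keV (residual range < 3 µm,
  beneath the epidermal resolution), with the remaining energy deposited
  locally. Positrons annihilate at track end into two back-to-back
  0.511 MeV photons, which are tallied under the *photon* emission mode.

Photons are transported analogically with photoelectric absorption and
incoherent (Klein–Nishina) scattering; coherent scattering is ignored.
The attenuation table (`inst/extdata/photon_attenuation_water.csv`) holds
the Klein–Nishina incoherent coefficient (free-electron approximation,
Z/A = 0.55509) and a photoelectric $E^{-3}$ power law anchored at the
standard 10 keV water value. These approximations are adequate because
photons contribute a minor fraction of the layer doses here; the
0.511 MeV total coefficient agrees with standard water tables to ~1%.
Photoelectric events deposit locally (the photoelectron range is
negligible at photoelectric-dominated energies); Compton electrons are
handed to the electron transport under the same source mode.

Every history conserves energy exactly: deposited + escaped equals
emitted kinetic energy (plus 1.022 MeV annihilation energy per positron),
to below $10^{-9}$ MeV. A counter-based RNG (splitmix64) derives one
substream per history from the run seed, so results are bit-reproducible
for a given seed under any execution order.

### What "mean range" means here

`mean_range()` reports the mean **straight-line distance from emission
point to track end** (3D penetration depth) over the sampled spectrum.
This is deliberately *not* the CSDA path length (which is longer — for
the F-18 spectrum the mean CSDA path in water is ≈0.70 mm versus a
penetration depth of ≈0.52 mm), and not a dose-point-kernel percentile
such as $X_{50}$. Literature "mean range" figures mix these definitions;
the package reports one consistent estimator and documents the
distinction. For Y-90 in particular, clinically quoted "mean tissue
penetration" values near 2.4 mm are substantially shorter than the mean
3D displacement of the full Y-90 spectrum under any consistent transport
model (≈3.3 mm here, with a mean CSDA path of ≈4.3 mm).

## The skin phantom and activity partition

`build_default_phantom()` builds the default geometry: epidermis 60 µm
(midpoint of the anatomical 50–70 µm band, tunable), papillary dermis
15 µm, reticular dermis 1.185 mm (dermis totals 1.2 mm), hypodermis
6.8 mm, and a 20 mm deep-tissue backing; air above the surface. The
infiltrate footprint is 36 × 21 mm, spanning the full dermis plus
hypodermis; the phantom extends 80 × 60 mm laterally so that escape
through the sides is negligible for the source region. Materials are
water-equivalent at 1.09 g/cm³ (epidermis/dermis), adipose at 0.95 g/cm³
(hypodermis) and water-equivalent at 1.04 g/cm³ (deep tissue). The five
tally compartments are read as epidermis, papillary dermis, reticular
dermis, hypodermis and deep tissue — one reading of an ambiguous
"five compartments" layout; doses are additionally reported as a
mass-weighted dermal average (`layer_dose(report, "dermis")`).

The infiltrated activity is split by `partition_activity()` between
hypodermis and dermis at a fixed concentration ratio $c_h/c_d = r$
subject to $c_d V_d + c_h V_h = A$; papillary and reticular dermis share
one concentration (tallied separately), and the epidermis holds no
activity — tumescent-injection evidence shows infiltrate pooling in fat
with at most minimal dermal intrusion, and none epidermal. The solve is
exact (residuals < $10^{-12}$ relative). Ratios of 10:1, 5:1 and 2:1
cover the plausible equilibrium range, 10:1 being closest to measured
piglet data. Geometry and activity distribution are static over the
integration period.

Emission sites are sampled region-proportional to concentration × volume
and uniformly within each region's footprint column. Dose tallies score
energy deposited inside the footprint column of each layer; layer mass is
footprint area × thickness × density. Deposition inside the phantom but
outside the column is tracked separately ("out of footprint"), so the
reported dose is the mean dose over the infiltrate-covered tissue, not
diluted over the whole slab.

## Kinetics and dose normalisation

Clearance is single-exponential with an **effective half-life** (physical
decay + biological washout): 30 min for F-18 infiltrates, 25 min for
Ga-68. The dose integral runs from injection to infinity (cumulated
decays $\tilde A = A_0 T_{eff}/\ln 2$) — the worst-case framing, rather
than an injection-to-imaging window. Per-layer dose is

$$D_\ell = \frac{\tilde A}{m_\ell} \sum_{\text{modes}}
  y_{\text{mode}} \, \bar E_{\ell,\text{mode}}$$

with $y$ the emissions per decay and $\bar E$ the mean energy deposited
in layer $\ell$ per emission. Doses are reported both absolute (Gy) and
per unit infiltrated activity (Gy/MBq); the latter is independent of
$A_0$, so `extrapolate_dose()` to a hypothetical full-injection
infiltration (e.g. 470 MBq) is pure linear scaling at fixed geometry —
a modelling assumption, since a real full-injection infiltrate would
occupy a larger volume. Statistical uncertainties come from the
per-history tally variance and are honest: across independent seeds the
empirical spread of layer doses matches the reported SE within a factor
of ~1.5.

Two printed bounds in the source material disagree for the extrapolated
470 MBq epidermis dose ("below 1 Gy" in one place, "generally below
2 Gy" in another, while linear scaling of the printed 1.5 mGy minimum
gives ≈1.7 Gy). The package simply reports its own simulated value
(≈0.7 Gy at 10:1) and checks it against the 2 Gy bound.

## Cohort quantitation and inference

Net injection-site activity is (mean concentration × VOI volume) at the
injection site minus the same product contralaterally, floored at zero
(negative differences are background fluctuations). Decay correction back
to injection time uses the physical half-life only. Classification uses
strict inequalities — `negligible` ≤ 370 kBq < `above_370kBq` ≤ 1% of
injected < `above_1pct` — because the thresholds are phrased as "more
than"; ties at the boundary stay in the lower category. Reader
visibility labels are carried as annotations only: the package's point is
that visual criteria are unreliable, so they never enter the
classification.

The infiltration-rate interval is Clopper–Pearson (exact binomial tail
probabilities, computed via beta quantiles). For zero events in $n$
patients the upper bound is $1 - (\alpha/2)^{1/n}$; at $n = 1000$,
95% confidence, this is 0.0037. Exact intervals are conservative by
construction, which the coverage test verifies by simulation.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* of a large
multicentre PET cohort: ~1,000 patients, injected activity
Normal(405, 78) MBq truncated positive, roughly half of patients with a
small visible injection-site residual, rare configurable infiltration
events, uptake intervals Uniform(55, 75) min (typical PET practice; it
only affects the size of the decay correction), and route/site labels in
realistic proportions. The residual-activity distribution is log-normal
with median 34 kBq for the visible fraction — chosen because residuals
are strictly positive with a heavy right tail; no distributional form is
claimed for any real cohort, and the parameters are spec-level knobs.

What passing tests on synthetic cohorts do show: the VOI arithmetic,
decay correction, classification and interval machinery are correct, and
the generator's moments are recovered. What they do not show: anything
about real PET cohorts — descriptive counts of any real cohort (e.g.
how many patients fall below 74 kBq) are properties of its patients and
are only emulated qualitatively here.

## Numerical choices and problem sizes

* Electron/photon cutoff 10 keV; below-table photon energies deposit
  locally.
* Step cap 5% of residual CSDA range; boundary crossings nudged by
  1 µm $\times 10^{-3}$ to avoid re-intersection.
* Inverse-CDF grids: 2048 points per branch for pdf normalisation, 4096
  for sampling; trapezoid quadrature throughout.
* Degenerate inputs: zero-energy particles produce empty event lists;
  zero-activity scenarios produce zero-dose reports (per-MBq values stay
  defined); all-zero source concentrations are an error.
* Default problem sizes: range estimates use $10^5$ histories
  (SE ≈ 0.3% of the mean), dose runs $10^6$ histories per emission mode
  (per-layer SE below ~1% in source-adjacent layers); the test suite
  uses $10^4$–$2\times10^4$ histories where only invariants, not
  absolute accuracy, are at stake.
* Radiation-equilibrium validation runs in a periodic (wrapped) box with
  a uniform source, where dose per decay must equal mean emitted
  charged-particle energy over mass.

## Known limitations

* Water-equivalent physics everywhere (density scaling only): adipose
  and dermis differ from water in composition by a few percent in
  stopping power; this is inside the two-significant-figure target.
* No variance reduction and no delta-ray / bremsstrahlung transport;
  not a general-purpose MC code.
* The Highland Gaussian has no single-scattering tail, so backscatter
  is underrepresented; layer doses are insensitive to this, range
  estimates carry it as part of the ±(few)% model spread.
* Static infiltrate: no spreading, diffusion, or patient-specific CT
  meshes. The same default phantom stands in for all geometries,
  including comparisons that originally used a second patient's
  geometry whose dimensions are not available.
* Photon physics uses a two-process model (photoelectric + incoherent);
  fine for 0.1–1.1 MeV dose fractions here, not for imaging physics.
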