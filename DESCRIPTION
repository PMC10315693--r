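Package: skindose
Title: Microscale Skin Dosimetry and Cohort Quantitation of
    Radiopharmaceutical Infiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing radiopharmaceutical injection-site
    infiltration. Provides a coupled electron/positron-photon Monte Carlo
    transport engine for layered skin (epidermis, papillary and reticular
    dermis, hypodermis, deep tissue) with Fermi-theory beta-spectrum
    sampling, per-layer and per-emission-mode absorbed dose tallies,
    activity-partition scenarios between hypodermis and dermis, clearance
    kinetics, and linear extrapolation to hypothetical full-injection
    infiltrations. Also implements a quantitative cohort pipeline that
    derives net injection-site activity from PET volume-of-interest
    summaries, decay-corrects and classifies it, and computes exact
    (Clopper-Pearson) binomial confidence intervals for the infiltration
    rate, together with seeded synthetic-cohort generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
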