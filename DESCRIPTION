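Package: hippostress
Title: Longitudinal Hippocampal Subfield, Connectivity and Cortisol Analysis
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal mental-training intervention studies
    linking hippocampal subfield volume and seed-based functional
    connectivity to diurnal and hair cortisol. Implements diurnal salivary
    cortisol summary indices (awakening response, diurnal slope, area under
    the curve with respect to ground), motion scrubbing and seed-connectivity
    network scoring on parcel time series, module-labelled change-score
    mixed models with effect sizes and multiplicity correction, behavioral
    partial least squares with permutation and bootstrap inference, and a
    synthetic cohort generator with known ground truth for end-to-end
    validation. A command-line pipeline orchestrates all stages
    reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
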