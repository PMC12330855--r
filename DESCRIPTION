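Package: vasculomap
Title: White-Matter Vasculature Mapping from Ferumoxytol-Enhanced R2* MRI
Version: 0.1.0
Authors@R: person("Vasculomap", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline linking white-matter vasculature
    (ferumoxytol-induced Delta-R2*) to fiber microstructure and cortical
    geometry. Provides multi-echo R2* relaxometry and Delta-R2* mapping,
    equivolumetric cortical layering with a superficial white-matter offset
    surface, ribbon-constrained volume-to-surface sampling, surface
    gradients, a cos^2-theta B0 orientation-bias model (estimation and
    correction), multi-scale Hessian-based Frangi vesselness filtering,
    along-tract profiling with outlier cleaning, exponential depth models
    compared by AICc/BIC, forward stepwise nonlinear prediction of vascular
    volume with leave-one-bundle-out cross-validation, and parcel-level
    bootstrap statistics. A synthetic digital-phantom generator supplies
    every input with known ground truth so the whole chain is testable
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
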