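Package: stressnet
Title: Quantitative Systems Model of Multi-Axis Stress and Nutritional Intervention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ordinary-differential-equation network model of interacting
    stress axes (NF-kB driven inflammation, NRF2-KEAP1 redox balance, the
    HPA cortisol axis and renin-angiotensin blood-pressure control), with a
    severity-parameterised stress induction, a multi-ingredient botanical
    and micronutrient intervention engine, clinical biomarker read-outs
    (ROS production percentage, TNF-alpha, systolic blood pressure and a
    cortisol-derived perceived-stress score), an in-silico virtual
    population with demographic and kinetic heterogeneity, and a staged
    calibration framework. Includes report generators for steady-state,
    population and stress-phenotype analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
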