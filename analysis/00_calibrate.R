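#!/usr/bin/env Rscript
# Regenerates the packaged calibrated model: solves the design table into
# kinetic constants (healthy / stressed / combined states as exact fixed
# points), fits the ingredient potencies to the printed single-ingredient
# efficacies, renormalises the node products to the combined-arm
# multipliers, and rewrites inst/extdata/*.json. Run from the repository
# root; takes about a minute.

suppressMessages(library(stressnet))

params <- build_reference_model()
form <- build_default_formulation(params, verbose = TRUE)

write_model_json(params, "inst/extdata/params_default.json")
write_formulation_json(form, "inst/extdata/formulation_default.json")

# verification: the three reference states through the shipped artefacts
refs <- reference_states(params, form)
cat(sprintf("\nstressed:  ROS %.2f%%  cortisol %.1f ng/mL  TNF %.3g pg/mL\n",
            refs$panel_stressed$ros_percent, refs$panel_stressed$cortisol,
            refs$panel_stressed$tnfa))
cat(sprintf("combined:  ROS %.2f%%  cortisol %.2f ng/mL  TNF %.3g pg/mL\n",
            refs$panel_combined$ros_percent, refs$panel_combined$cortisol,
            refs$panel_combined$tnfa))
cat("model and formulation written to inst/extdata/\n")
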