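#!/usr/bin/env Rscript
# Stress-phenotype analysis: classifies every simulated individual on the
# four stress axes (oxidative, inflammatory, physical, mental) before and
# after the combined intervention and reports the five-category
# distribution plus per-axis residual stress. Writes results/phenotypes.csv.

suppressMessages(library(stressnet))

args <- commandArgs(trailingOnly = TRUE)
i <- match("--n", args)
n <- if (!is.na(i)) as.integer(args[i + 1]) else 1000L

cfg <- run_config(n = n, seed = 1, arms = c("stressed", "combined"),
                  out_dir = "results")
ph <- run_phenotypes(cfg)

fmt <- function(d) paste(sprintf("%s %.1f%%", names(d), 100 * d),
                         collapse = ", ")
cat("Pre-intervention phenotypes: ", fmt(ph$pre), "\n")
cat("Post-intervention phenotypes:", fmt(ph$post), "\n")
cat("Residual stress per axis (post):",
    paste(sprintf("%s %.2f%%", names(ph$residual), ph$residual),
          collapse = ", "), "\n")
cat("\nTable written to results/phenotypes.csv\n")
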