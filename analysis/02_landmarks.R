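#!/usr/bin/env Rscript
# Applies the standardized cross-hair protocol (8 fixed + 56 semi-landmarks)
# to every outline and exports the configurations as a TPS file.

library(orbitmorph)
pop <- readRDS("results/population.rds")
lms <- landmark_outlines(pop)
write_tps(lms, "results/landmarks.tps")
lms_theory <- landmark_outlines(theoretical_set())
write_tps(lms_theory, "results/landmarks_theoretical.tps")
message("landmarked ", length(lms), " specimens and ", length(lms_theory),
        " theoretical shapes (64 points each)")
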