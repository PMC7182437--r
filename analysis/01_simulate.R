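#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the calibrated synthetic knee cohort used throughout the
# analysis: 20 femur+tibia pairs, five latent alignment parameters
# (frontal rotation, axial rotation, tibial slope, femoral and tibial
# joint-line tilts), 0.2 mm vertex noise, mixed left/right sides. The
# frontal rotation is drawn from two groups whose centres are separated
# by twice the 3-degree physiological HKA half-width, so the cohort
# contains a strong, known instability signal. Writes one PLY per bone
# plus cohort.csv / landmarks.csv under results/cohort/.

suppressPackageStartupMessages(library(kneessm))

seed <- 1
dir <- "results/cohort"

template <- build_template(n_phi = 40)
cohort <- generate_benchmark_cohort(seed = seed, n = 20, noise_sd = 0.2,
                                    template = template)
write_cohort(cohort, dir)

tab <- angle_table(cohort, use_true = TRUE)
cat(sprintf("wrote %d samples (seed %d) to %s\n", length(cohort), seed, dir))
cat(sprintf("sides: %d right, %d left\n",
            sum(tab$side == "right"), sum(tab$side == "left")))
cat("unstable counts per angle (of", nrow(tab), "samples):\n")
for (v in c("HKA", "FVV", "IER", "TVV", "TS"))
  cat(sprintf("  %-4s %d\n", v, sum(tab[[paste0("unstable_", v)]])))
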