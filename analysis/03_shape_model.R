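#!/usr/bin/env Rscript
# Step 3 — statistical shape model.
#
# Fits the joint femur+tibia PCA shape space on the correspondence set,
# reports how many modes carry 95% of the cumulative explained variance,
# projects every sample to its mode weights, and quantifies the
# truncation cost as per-sample reconstruction errors. Writes
# results/ssm.json, results/explained_variance.csv, results/weights.csv
# and results/reconstruction_errors.csv.

suppressPackageStartupMessages(library(kneessm))

corr <- read_correspondences("results/correspondences")
model <- fit_ssm(corr)
print(model)

k95 <- n_modes_for(model$ev, 0.95)
cat(sprintf("%d of %d modes reach 95%% cumulative EV\n", k95,
            length(model$sd)))

write_ssm(model, "results/ssm.json")
write.csv(data.frame(mode = seq_along(model$ev), sd_mm = model$sd,
                     ev = model$ev, cumulative_ev = cumsum(model$ev)),
          "results/explained_variance.csv", row.names = FALSE)

weights <- t(apply(corr$shapes, 1, function(s) project(model, s, k95)))
rownames(weights) <- rownames(corr$shapes)
colnames(weights) <- paste0("mov", seq_len(k95))
write.csv(data.frame(id = rownames(weights), weights),
          "results/weights.csv", row.names = FALSE)

rec <- reconstruction_errors(model, corr, k95)
cat(sprintf("reconstruction at %d modes: RMS %.3f +/- %.3f mm, max %.3f +/- %.3f mm\n",
            k95, rec$summary[["rms_mean"]], rec$summary[["rms_sd"]],
            rec$summary[["hausdorff_mean"]], rec$summary[["hausdorff_sd"]]))
write.csv(rec$per_sample, "results/reconstruction_errors.csv",
          row.names = FALSE)
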