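#!/usr/bin/env Rscript
# Step 5 — instability classification and mode-angle association.
#
# Runs the statistical battery on the retained mode weights: LDA, QDA and
# logistic-regression classification of each angle's stability label with
# leave-one-out validation (accuracy / sensitivity / specificity), greedy
# 3- and 4-mode QDA subsets, rank-sum comparisons of stable vs unstable
# weight distributions for logistic-significant modes, and Spearman
# correlations of every mode with the corrected angle deviations
# |X - Xbar|. Writes the report JSON and flat CSV tables under results/.

suppressPackageStartupMessages(library(kneessm))

w <- read.csv("results/weights.csv", stringsAsFactors = FALSE)
weights <- as.matrix(w[, -1])
rownames(weights) <- w$id
angles <- read.csv("results/angles.csv", stringsAsFactors = FALSE)

report <- run_analysis(weights, angles)
write_report(report, "results/report.json")
tabs <- report_tables(report)
for (nm in names(tabs))
  if (!is.null(tabs[[nm]]))
    write.csv(tabs[[nm]], file.path("results", paste0(nm, ".csv")),
              row.names = FALSE)

cat("LOO classification (all retained modes):\n")
print(tabs$classification, row.names = FALSE)
if (!is.null(tabs$subsets)) {
  cat("\nbest low-dimensional QDA subsets:\n")
  print(tabs$subsets, row.names = FALSE)
}
sig <- tabs$spearman[tabs$spearman$p < 0.05, ]
sig <- sig[order(sig$p), ]
cat("\nsignificant mode-angle Spearman correlations (p < 0.05):\n")
print(head(sig, 10), row.names = FALSE)
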