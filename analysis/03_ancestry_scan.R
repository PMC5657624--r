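#!/usr/bin/env Rscript

# Step 3: case-only excess-ancestry scan.
#
# For every locus, the excess European ancestry among cases is the mean
# deviation of local ancestry from each case's genome-wide ancestry,
# Delta_Pi_l = (1/N) sum_i (q_il - M_i), standardized by the pooled SD over
# all markers into Z_l. The right tail tests excess European ancestry (the
# disease is far more prevalent in European Americans), the left tail
# excess African ancestry; both are reported everywhere.

library(admixscan)

Q <- read_ancestry_tsv("results/cohort/ancestry.tsv")
scan <- z_scan(Q)

print(scan)
cat(sprintf("pooled SD of excess ancestry: %.5f\n", attr(scan, "pooled_sd")))
top <- as.data.frame(scan)[order(-scan$z)[1:5],
                           c("marker_id", "chrom", "pos_bp",
                             "delta_pi", "z", "neglog10_p_right")]
cat("top European-excess loci (null cohort -- expected unremarkable):\n")
print(top, row.names = FALSE, digits = 3)

write_scan_tsv(scan, "results/scan.tsv")
plot_scan(scan, tail = "eur", file = "results/scan_eur.png")
plot_scan(scan, tail = "afr", file = "results/scan_afr.png")
cat("scan written to results/scan.tsv (plots: results/scan_{eur,afr}.png)\n")
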