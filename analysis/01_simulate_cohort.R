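#!/usr/bin/env Rscript

# Step 1: generate the emulated study cohort.
#
# The real study genotyped FFPE-derived DNA from a small series of
# African-American Barrett's esophagus / esophageal adenocarcinoma cases and
# inferred local European/African ancestry per SNP. Neither genotypes nor
# ancestry calls are public, so the workflow runs on a simulated stand-in
# with the same statistical structure: 28 cases, 22 autosomes, single-pulse
# admixture (mean European fraction 0.27, 7 generations), Markov ancestry
# tracts, Balding-Nichols CEU/YRI-like panel frequencies, and FFPE-style
# heterogeneous missingness. No risk locus: this is the null cohort used to
# calibrate the scan machinery in steps 2-4.

library(admixscan)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- make_null_fixture(seed = 20170L, genotypes = TRUE)

write_ancestry_tsv(cohort$ancestry, file.path(out, "ancestry.tsv"))
write_genotypes_vcf(cohort$genotypes, file.path(out, "genotypes.vcf"))
write_panel_tsv(cohort$panel, file.path(out, "panel_freqs.tsv"))
jsonlite::write_json(cohort$config[setdiff(names(cohort$config), "risk_locus")],
                     file.path(out, "sim_config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

M <- global_ancestry(cohort$ancestry)
cat(sprintf("cohort: %d cases x %d markers\n",
            nrow(cohort$ancestry$q), ncol(cohort$ancestry$q)))
cat(sprintf("mean European ancestry %.3f (SD %.3f); genotype missingness %.1f%%\n",
            mean(M), sd(M), 100 * mean(is.na(cohort$genotypes$calls))))
cat("written to", out, "\n")
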