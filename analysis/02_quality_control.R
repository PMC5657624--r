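#!/usr/bin/env Rscript

# Step 2: genotype quality control.
#
# Applies the cascade used for the FFPE-degraded study genotypes: sample
# call rate > 0.95, heterozygosity within 3 SD of the cohort mean, SNP call
# rate > 0.964, removal of SNPs that are monomorphic or missing from the
# reference panel, and flagging of SNPs whose observed allele frequency
# departs from the admixture-weighted panel mixture 0.8*freqYRI +
# 0.2*freqCEU by more than 0.3. Frequency-discordant SNPs are flagged but
# kept (the scan can be run with and without them).

library(admixscan)

geno <- read_genotypes("results/cohort/genotypes.vcf")
panel <- read_panel_tsv("results/cohort/panel_freqs.tsv")

qc <- qc_pipeline(geno, panel, apply_concordance = FALSE)

print(qc$stage_counts, row.names = FALSE)
n_flag <- sum(qc$report$stage == "freq_concordance")
cat(sprintf("%d sample(s) and %d SNP flag(s)/removal(s) in total; %d frequency-discordant SNP(s) flagged\n",
            sum(qc$report$type == "sample"), sum(qc$report$type == "snp"),
            n_flag))

write.table(qc$report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(qc$stage_counts, "results/qc_stage_counts.json",
                     pretty = TRUE)
cat("report written to results/qc_report.tsv\n")
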