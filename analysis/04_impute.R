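#!/usr/bin/env Rscript
# Stage 4 — reference-panel imputation of the 10-cell biopsy arm.
#
# Imputes the QC-surviving biopsy genotypes against the phased self-cohort
# panel with the diploid Li-Stephens HMM, and scores the result against
# the known truth: call-rate change, post-imputation concordance, rescue
# rate, and the correction rate under both denominators.

library(embryogs)

truth <- read_vcf("results/fixture/truth.vcf")
biopsy <- read_vcf("results/fixture/biopsy_cells10.vcf")
panel <- read_vcf("results/fixture/panel.vcf", as = "panel")
snps_kept <- readLines("results/02_snps_kept.txt")

biopsy_q <- subset_geno(biopsy, snps = match(snps_kept, biopsy$map$snp_id))
truth_pairs <- subset_geno(truth,
                           samples = grep("^pair", rownames(truth$calls)),
                           snps = match(snps_kept, truth$map$snp_id))
truth_aligned <- geno_matrix(truth_pairs$calls, truth_pairs$map,
                             samples = rownames(biopsy_q$calls))

message("Imputing ", nrow(biopsy_q$calls), " embryos over ",
        ncol(biopsy_q$calls), " SNPs ...")
imputed <- impute_matrix(biopsy_q, panel, hmm_params())
rep <- evaluate_imputation(biopsy_q, imputed, truth_aligned)
print(rep)
write.table(rep$per_sample, "results/04_imputation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(imputed, "results/04_biopsy_cells10_imputed.vcf")
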