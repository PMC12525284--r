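#!/usr/bin/env Rscript
# Stage 2 — PLINK-style QC of the combined chip matrix.
#
# Reads the fixture written by 01_simulate.R, stacks reference animals,
# lambs and the 10-cell biopsy arm into one chip matrix, and applies the
# marker/sample filters (--mind 0.1, --geno 0.1, --maf 0.05, --hwe 1e-5),
# with the Hardy-Weinberg test restricted to the reference cohort. The
# surviving marker list feeds the later stages.

library(embryogs)

truth <- read_vcf("results/fixture/truth.vcf")
lambs <- read_vcf("results/fixture/lambs.vcf")
biopsy <- read_vcf("results/fixture/biopsy_cells10.vcf")
ref_ids <- grep("^ref", rownames(truth$calls), value = TRUE)
ref <- subset_geno(truth, samples = ref_ids)

chip <- geno_matrix(rbind(ref$calls, lambs$calls, biopsy$calls), truth$map)
res <- apply_qc(chip, qc_thresholds(), hwe_samples = ref_ids)
print(res$report)

write.table(res$report$steps, "results/02_qc_steps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(res$gm$map$snp_id, "results/02_snps_kept.txt")
message("Kept ", ncol(res$gm$calls), " of ", ncol(chip$calls), " SNPs and ",
        nrow(res$gm$calls), " of ", nrow(chip$calls), " samples.")
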