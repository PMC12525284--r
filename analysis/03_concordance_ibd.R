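#!/usr/bin/env Rscript
# Stage 3 — embryo/lamb genotype concordance and identity-by-descent.
#
# For every biopsy arm, computes the per-pair consistency rate between the
# embryo biopsy calls and the matched lamb blood calls, and the PLINK-style
# method-of-moments pi_hat using reference-cohort allele frequencies. The
# pooled consistency-on-pi_hat regression is the genotype-vs-genealogy
# cross-check of sample identity.

library(embryogs)

truth <- read_vcf("results/fixture/truth.vcf")
lambs <- read_vcf("results/fixture/lambs.vcf")
ref <- subset_geno(truth, samples = grep("^ref", rownames(truth$calls)))
freqs <- allele_frequencies(ref)

arm_files <- sort(list.files("results/fixture", "^biopsy_cells",
                             full.names = TRUE))
rows <- list()
for (f in arm_files) {
  biopsy <- read_vcf(f)
  n_cells <- as.integer(sub(".*cells(\\d+)\\.vcf$", "\\1", f))
  comb <- geno_matrix(rbind(biopsy$calls, lambs$calls), truth$map)
  for (i in seq_len(nrow(biopsy$calls))) {
    e_id <- rownames(biopsy$calls)[i]
    l_id <- sub("embryo", "lamb", e_id)
    cc <- pair_concordance(biopsy$calls[e_id, ], lambs$calls[l_id, ], e_id, l_id)
    ib <- moment_ibd(comb, e_id, l_id, freqs)
    rows[[length(rows) + 1L]] <- data.frame(
      embryo = e_id, n_cells = n_cells,
      consistency = cc$consistency_rate, pi_hat = ib$pi_hat)
  }
}
pairs_tab <- do.call(rbind, rows)
fit <- linear_fit(pairs_tab$pi_hat, pairs_tab$consistency)
write.table(pairs_tab, "results/03_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "Across %d pair-arm observations: consistency %.2f-%.2f%% , pi_hat %.2f-%.2f",
  nrow(pairs_tab), 100 * min(pairs_tab$consistency),
  100 * max(pairs_tab$consistency), min(pairs_tab$pi_hat),
  max(pairs_tab$pi_hat)))
print(fit)
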