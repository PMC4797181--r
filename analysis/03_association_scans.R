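#!/usr/bin/env Rscript
# Sex-stratified additive logistic association of every QC-passed SNP with
# the six pigmentation / sun-sensitivity traits and melanoma status:
# 7 outcomes x 2 sexes = 14 scans. Trait significance is reported at
# P < 0.01 (0.05 Bonferroni-split over six traits); P < 0.05 marks
# enrichment eligibility. Writes results/assoc/.

library(snpsexdiff)

ind <- "results/study"; out <- "results/assoc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- read_variants(file.path(ind, "variants.tsv"))
gm <- read_genotypes("results/qc/genotypes_qc.tsv", "tsv", variants)
samples <- read_phenotypes(file.path(ind, "phenotypes.tsv"))

outcomes <- c("eye", "hair", "skin", "naevi", "lentigines", "sunburn",
              "melanoma")
for (oc in outcomes) {
  for (st in c("F", "M")) {
    res <- assoc_scan(gm, samples, oc, st)
    write_results(res, file.path(out, sprintf("assoc_%s_%s.tsv", oc, st)))
    n_sig <- sum(res$sig_report, na.rm = TRUE)
    message(sprintf("%-11s %s: %3d SNPs at P < 0.01 (n per fit <= %d)",
                    oc, st, n_sig, max(res$n_used)))
  }
}
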