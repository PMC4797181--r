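#!/usr/bin/env Rscript
# Genotype QC for the simulated study: call-rate filter (>= 0.9), orientation
# to the sample minor allele, exact HWE screen with Bonferroni threshold
# alpha/m, per-sex MAF summary with the female-male frequency correlation,
# and a between-sex allele-count spot check. Writes results/qc/.

library(snpsexdiff)

ind <- "results/study"; out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- read_variants(file.path(ind, "variants.tsv"))
gm <- read_genotypes(file.path(ind, "genotypes.tsv"), "tsv", variants)
samples <- read_phenotypes(file.path(ind, "phenotypes.tsv"))

cr <- call_rate_filter(gm, 0.9)
message(sprintf("call-rate filter: %d of %d variants removed (%.1f%%)",
                cr$report$n_removed, ncol(gm$dosage),
                100 * cr$report$removal_fraction))

gm <- orient_minor_allele(cr$genotypes, samples)
scr <- hwe_screen(gm, samples, alpha = 0.05)
pooled <- scr$results[scr$results$stratum == "all", ]
message(sprintf("HWE threshold 0.05/%d = %.4g; %d variant(s) out of HWE",
                nrow(gm$variants), scr$threshold,
                sum(pooled$out_of_hwe, na.rm = TRUE)))

maf <- maf_by_sex(gm, samples)
message(sprintf("female vs male MAF R^2 = %.4f", maf$r_squared))

p_sex <- allele_count_sex_test(gm, samples, gm$variants$rsid[1])
message(sprintf("between-sex allele-count test, first SNP: P = %.3f", p_sex))

write_results(scr$results, file.path(out, "hwe.tsv"))
write_results(maf$summary, file.path(out, "maf.tsv"))
write_genotypes(gm, file.path(out, "genotypes_qc.tsv"))
maf_scatter(maf, path = file.path(out, "maf_scatter.png"))
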