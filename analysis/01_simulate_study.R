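#!/usr/bin/env Rscript
# Simulate a sex-stratified melanoma case-control study with the published
# layout (599 females: 316 cases / 283 controls; 458 males: 234 / 224;
# 363 SNPs, the last six X-linked), planting a handful of sex-specific
# effects so the downstream stages have signal to find:
#   - a male-only melanoma risk allele (OR 1.9), echoing the X-linked
#     male-specific melanoma signals reported for this panel
#   - a female-only protective melanoma allele (OR 0.55)
#   - opposite-direction eye-colour effects (OR 0.7 in F, 1.5 in M)
#   - an equal-effect skin-colour allele (OR 1.4 both sexes; should NOT be
#     flagged by the heterogeneity test)
# Writes the study TSVs plus the truth table under results/study/.

library(snpsexdiff)

out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

effects <- data.frame(
  snp     = c(360L,       20L,        45L,       80L),
  outcome = c("melanoma", "melanoma", "eye",     "skin"),
  beta_f  = c(0,          log(0.55),  log(0.7),  log(1.4)),
  beta_m  = c(log(1.9),   0,          log(1.5),  log(1.4))
)

cfg <- sim_config(effects = effects, seed = 20260102)
study <- generate_study(cfg)

write_genotypes(study$genotypes, file.path(out, "genotypes.tsv"))
write.table(study$genotypes$variants, file.path(out, "variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$samples, file.path(out, "phenotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_results(study$truth, file.path(out, "truth.tsv"))

message(sprintf("simulated %d samples x %d SNPs -> %s",
                length(study$genotypes$samples), nrow(study$genotypes$variants),
                out))
message(sprintf("planted %d true effects (see truth.tsv)", nrow(study$truth)))
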