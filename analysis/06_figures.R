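#!/usr/bin/env Rscript
# Figures: volcano plots of significance vs fold change per sex, Manhattan
# plots of the sex-differentiated P values, the female/male MAF scatter, and
# the enrichment bar chart. Writes results/figures/.

library(snpsexdiff)

out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- read_variants("results/study/variants.tsv")

for (oc in c("eye", "melanoma")) {
  for (st in c("F", "M")) {
    res <- read.delim(sprintf("results/assoc/assoc_%s_%s.tsv", oc, st))
    volcano(res, threshold = 0.01,
            path = file.path(out, sprintf("volcano_%s_%s.png", oc, st)))
  }
  sd <- read.delim(sprintf("results/sexdiff/sexdiff_%s.tsv", oc))
  manhattan_sexdiff(sd, variants, threshold = 0.01,
                    path = file.path(out, sprintf("manhattan_%s.png", oc)))
}

maf_tab <- read.delim("results/qc/maf.tsv")
maf <- list(summary = tibble::as_tibble(maf_tab),
            r_squared = cor(maf_tab$maf_f, maf_tab$maf_m)^2)
maf_scatter(maf, path = file.path(out, "maf_scatter.png"))

enr <- read.delim("results/enrichment/enrichment_simulated.tsv")
enrichment_bars(enr[enr$trait != "pooled", ],
                path = file.path(out, "enrichment_bars.png"))
message("figures written to ", out)
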