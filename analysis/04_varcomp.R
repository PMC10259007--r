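#!/usr/bin/env Rscript
# Stage 4: variance components and genetic correlations.
#
# Univariate genomic animal model for TLE with and without the dam
# effect (AIC comparison), then a bivariate TLE x BW1 fit for the
# genetic correlation; all by AI-REML.

library(troutherm)

out <- "results"
ch <- read_phenotypes(file.path(out, "challenge_pheno.tsv"))
rel <- readRDS(file.path(out, "relmat.rds"))
G <- rel$G

fit_dam <- reml_fit(ch, "tle", G)
fit_nodam <- reml_fit(ch, "tle", G, dam_traits = character(0))
cmp <- aic_compare(fit_dam, fit_nodam)

print(fit_dam)
message(sprintf("AIC with dam %.1f vs without %.1f -> %s model kept",
                fit_dam$AIC, fit_nodam$AIC,
                if (cmp$selected == 1) "dam" else "no-dam"))
write_reml_report(fit_dam, file.path(out, "reml_tle_dam.tsv"))
write_reml_report(fit_nodam, file.path(out, "reml_tle_nodam.tsv"))

biv <- reml_fit(ch, c("tle", "bw1"), G, dam_traits = "tle")
message(sprintf("genetic correlation TLE x BW1: %.2f (SE %.2f)",
                biv$rg, biv$rg_se))
write_reml_report(biv, file.path(out, "reml_tle_bw1.tsv"))
saveRDS(fit_dam, file.path(out, "null_fit.rds"))
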