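#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population.
#
# Emulates the study design: 10 full-factorial mating blocks (99 sires x
# 76 dams), one phenotyped offspring cohort, genotypes with blocky LD,
# a challenge trait with h2 = 0.29, a 6% dam share, a hidden major QTL,
# and a harvest cohort with 24 planted weight-sum inconsistencies.

library(troutherm)

seed <- 20260920 %% 1e6
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- make_pedigree(n_offspring = 1600, seed = seed)
map <- make_snp_map(n_snps = 2000, n_chr = 10, seed = seed + 1)
geno <- gene_drop(ped, map, missing_rate = 0.01, seed = seed + 2)

# hidden causal variant at a common locus, 50% of genetic variance
frq <- colMeans(geno, na.rm = TRUE) / 2
cand <- which(pmin(frq, 1 - frq) >= 0.35)
qsnp <- map$snp[cand[ceiling(length(cand) / 2)]]
pq <- frq[match(qsnp, map$snp)]
a <- sqrt(0.5 * 0.29 / (2 * pq * (1 - pq)))
truth <- truth_record(var_u = 0.5 * 0.29, var_dam = 0.06, var_e = 0.65,
                      qtl = data.frame(snp = qsnp, a = a, d = 0))

offspring <- ped$id[ped$generation > 0]
set.seed(seed + 3)
b1 <- sort(sample(offspring, 800)) # challenge batch
b2 <- setdiff(offspring, b1)       # harvest batch

challenge <- simulate_challenge(ped, geno, truth, ids = b1, seed = seed + 4)
harvest <- simulate_harvest(ped, geno, truth, n_violations = 24, ids = b2,
                            seed = seed + 5)

write_pedigree(ped, file.path(out, "pedigree.tsv"))
write_snp_map(map, file.path(out, "snp_map.tsv"))
# the genotyping array does not carry the causal variant itself: the
# analysis panel excludes it, so the GWAS must find it through linked SNPs
panel <- setdiff(colnames(geno), qsnp)
write_vcf(geno[, panel], map[match(panel, map$snp), ],
          file.path(out, "genotypes.vcf"))
write_vcf(geno, map, file.path(out, "genotypes_full_synthetic.vcf"))
write_phenotypes(challenge$pheno, file.path(out, "challenge_raw.tsv"))
write_phenotypes(harvest$pheno, file.path(out, "harvest_raw.tsv"))
write_truth(truth, file.path(out, "truth_components.tsv"),
            file.path(out, "truth_qtl.tsv"))

message(sprintf("simulated %d animals (%d challenge, %d harvest), %d SNPs",
                nrow(ped), length(b1), length(b2), nrow(map)))
message(sprintf("hidden causal variant: %s (freq %.2f, a = %.3f)",
                qsnp, pq, a))
message(sprintf("planted weight-sum violations: %d",
                length(harvest$violations)))
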