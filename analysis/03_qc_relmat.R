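#!/usr/bin/env Rscript
# Stage 3: genotype QC and relationship matrices.
#
# Individual call-rate filter (>= 0.90), then SNP filters (call rate
# > 0.97, MAF > 0.05, HWE p > 1e-5); pedigree A by the tabular method and
# VanRaden G blended as 0.95 G + 0.05 A for invertibility.

library(troutherm)

dat <- "results/data"
out <- "results"

v <- read_vcf(file.path(dat, "genotypes.vcf"))
ped <- read_pedigree(file.path(dat, "pedigree.tsv"))

qi <- qc_individuals(v$genotypes, min_call = 0.90)
qs <- qc_snps(qi$genotypes, min_call = 0.97, min_maf = 0.05,
              min_hwe_p = 1e-5)
print(qi$report)
print(qs$report)
write_qc_report(qs$report, file.path(out, "qc_snps.tsv"))

A <- a_matrix(ped)
G <- g_matrix(qs$genotypes, blend_weight = 0.95, a_matrix = A)
write_relmat(G, file.path(out, "g_matrix.tsv"))
saveRDS(list(A = A, G = G, geno = qs$genotypes),
        file.path(out, "relmat.rds")) # scratch cache for later stages
message(sprintf("retained %d individuals x %d SNPs; mean diag(G) = %.3f",
                nrow(qs$genotypes), ncol(qs$genotypes), mean(diag(G))))
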