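#!/usr/bin/env Rscript
# Stage 6: genotype contrasts at peak SNPs and isogenic-line concordance.
#
# TLE corrected for day and dam effects is contrasted across the three
# genotype classes of each peak SNP (homozygote difference in % of the
# phenotypic SD, Tukey HSD, dominance t-test). Two synthetic fully
# homozygous lines derived from two founders stand in for a sensitive
# and a resistant isogenic line.

library(troutherm)

out <- "results"
ch <- read_phenotypes(file.path(out, "challenge_pheno.tsv"))
rel <- readRDS(file.path(out, "relmat.rds"))
fit <- readRDS(file.path(out, "gwas_fit.rds"))
nf <- readRDS(file.path(out, "null_fit.rds"))
map <- read_snp_map("results/data/snp_map.tsv")
ped <- read_pedigree("results/data/pedigree.tsv")
q <- read.delim(file.path(out, "qtl_regions.tsv"))

if (nrow(q)) {
  contrasts <- lapply(q$peak_snp, function(s)
    peak_contrast(ch, nf, rel$geno, s))
  write_contrast_report(contrasts, file.path(out, "peak_contrasts.tsv"))
  for (x in contrasts) print(x)
} else {
  message("no QTL regions to contrast")
}

# synthetic isogenic pair from two founders; which founders rank as
# sensitive/resistant is set by their breeding-value proxy (mean GEBV of
# their offspring)
v <- read_vcf("results/data/genotypes_full_synthetic.vcf")
founders <- ped$id[ped$generation == 0]
off_by <- function(par) {
  kids <- ped$id[!is.na(ped$sire) & (ped$sire == par | ped$dam == par)]
  mean(fit$gebv[intersect(kids, names(fit$gebv))], na.rm = TRUE)
}
set.seed(7)
pair <- sample(founders[grepl("^S", founders)], 2)
ebv <- vapply(pair, off_by, numeric(1))
sens_id <- pair[which.min(ebv)]
res_id <- pair[which.max(ebv)]
lines <- synthesize_isogenic_pair(v$genotypes, sens_id, res_id, map, seed = 8)
rep <- isogenic_concordance(
  fit,
  data.frame(snp = lines$snp, allele = lines$allele_a),
  data.frame(snp = lines$snp, allele = lines$allele_b),
  map, logbf_threshold = 6)
write.table(as.data.frame(rep), file.path(out, "isogenic_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("isogenic report: %d differing SNPs above threshold, %d concordant",
                nrow(rep), sum(rep$concordant)))
print(as.data.frame(rep), row.names = FALSE)
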