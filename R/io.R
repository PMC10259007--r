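# Plain-text interchange: pedigree TSV ("0" = unknown parent), GT-only
# VCFv4.2 with a SNP-map sidecar, phenotype tables and the truth record.

#' Write / read a pedigree TSV
#'
#' Columns `id`, `sire`, `dam`, `generation`; unknown parents are written
#' as `"0"`.
#'
#' @param pedigree pedigree `data.frame`.
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree[, c("id", "sire", "dam", "generation")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  .write_tsv(out, path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- .read_tsv(path, colClasses = "character")
  ped$generation <- as.integer(ped$generation)
  ped$sire[ped$sire == "0"] <- NA_character_
  ped$dam[ped$dam == "0"] <- NA_character_
  ped
}

#' Write genotypes as a GT-only VCFv4.2 file
#'
#' The genotype code is the count of the reference allele, so code 2 is
#' written `0/0`, 1 as `0/1`, 0 as `1/1` and missing as `./.`.
#'
#' @param genotypes individuals x SNPs matrix coded 0/1/2 with `NA`
#'   missing.
#' @param snp_map SNP map with `snp`, `chr`, `pos`, `ref`, `alt`.
#' @param path output path (`.vcf`).
#' @export
write_vcf <- function(genotypes, snp_map, path) {
  snp_map <- snp_map[match(colnames(genotypes), snp_map$snp), ]
  gt_code <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=troutherm",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)), collapse = "\t")),
             con)
  gt <- matrix("./.", ncol(genotypes), nrow(genotypes))
  for (code in 0:2) {
    gt[t(genotypes) == code] <- gt_code[[as.character(code)]]
  }
  lines <- paste(snp_map$chr, snp_map$pos, snp_map$snp, snp_map$ref,
                 snp_map$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix and SNP map
#'
#' @param path VCF path.
#' @return list with `genotypes` (individuals x SNPs, reference-allele
#'   counts) and `snp_map`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  alt_count[clean == "0/0"] <- 0L
  alt_count[clean %in% c("0/1", "1/0")] <- 1L
  alt_count[clean == "1/1"] <- 2L
  geno <- t(2L - alt_count) # reference-allele count
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  map <- data.frame(snp = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  colnames(geno) <- map$snp
  list(genotypes = geno, snp_map = map)
}

#' Write / read a SNP map TSV
#'
#' @param snp_map SNP map `data.frame`.
#' @param path file path.
#' @export
write_snp_map <- function(snp_map, path) .write_tsv(snp_map, path)

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  m <- .read_tsv(path)
  m$chr <- as.character(m$chr)
  m
}

#' Write / read a phenotype table TSV
#'
#' @param table phenotype `data.frame`.
#' @param path file path.
#' @export
write_phenotypes <- function(table, path) .write_tsv(table, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) .read_tsv(path)

#' Write / read a truth record as a TSV pair (variance components + QTL)
#'
#' @param truth a [truth_record()].
#' @param components_path,qtl_path file paths.
#' @export
write_truth <- function(truth, components_path, qtl_path) {
  comp <- data.frame(component = c("var_u", "var_dam", "var_e"),
                     value = c(truth$var_u, truth$var_dam, truth$var_e))
  .write_tsv(comp, components_path)
  qtl <- truth$qtl %||% data.frame(snp = character(0), a = numeric(0),
                                   d = numeric(0))
  .write_tsv(qtl, qtl_path)
  invisible(NULL)
}

#' @rdname write_truth
#' @export
read_truth <- function(components_path, qtl_path) {
  comp <- .read_tsv(components_path)
  v <- setNames(comp$value, comp$component)
  qtl <- .read_tsv(qtl_path)
  if (!nrow(qtl)) qtl <- NULL
  truth_record(var_u = v[["var_u"]], var_dam = v[["var_dam"]],
               var_e = v[["var_e"]], qtl = qtl)
}
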