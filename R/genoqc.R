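# Genotype quality control: individual call-rate filter, SNP filters on
# call rate, minor allele frequency and Hardy-Weinberg equilibrium.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square with 1 df of the observed genotype counts against the
#' p^2 : 2pq : q^2 proportions expected from the observed allele frequency.
#' No continuity correction is applied (the per-SNP sample sizes of array
#' QC make it immaterial). Monomorphic SNPs return `NA`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorised).
#' @return `data.frame` with columns `chisq` and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stopf("need at least one genotyped individual per SNP")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  mono <- p == 0 | q == 0
  eAA <- n * p^2; eAa <- n * 2 * p * q; eaa <- n * q^2
  chisq <- (n_AA - eAA)^2 / eAA + (n_Aa - eAa)^2 / eAa + (n_aa - eaa)^2 / eaa
  chisq[mono] <- NA_real_
  pval <- pchisq(chisq, df = 1, lower.tail = FALSE)
  data.frame(chisq = chisq, p = pval)
}

#' Individual-level genotype QC
#'
#' Removes individuals whose genotype call rate is strictly below
#' `min_call` (an individual at exactly the threshold is retained).
#'
#' @param genotypes individuals x SNPs matrix coded 0/1/2 with `NA` missing.
#' @param min_call minimum call rate.
#' @return list with `genotypes` (retained rows) and `report` (class
#'   `qc_report`): per-individual call rates and removed ids.
#' @export
qc_individuals <- function(genotypes, min_call = 0.90) {
  if (!nrow(genotypes) || !ncol(genotypes)) stopf("empty genotype matrix")
  call_rate <- rowMeans(!is.na(genotypes))
  keep <- call_rate >= min_call - 1e-9 # exactly at threshold: retained
  report <- structure(list(
    stage = "individuals",
    n_input = nrow(genotypes),
    n_removed = sum(!keep),
    removed = rownames(genotypes)[!keep],
    call_rate = call_rate,
    rules = c(call_rate = sum(!keep))), class = "qc_report")
  list(genotypes = genotypes[keep, , drop = FALSE], report = report)
}

#' SNP-level genotype QC
#'
#' Retains SNPs with call rate strictly above `min_call`, minor allele
#' frequency strictly above `min_maf`, and Hardy-Weinberg p-value strictly
#' above `min_hwe_p` (thresholds follow the "higher than" convention of
#' array QC, so a SNP exactly at a threshold is removed). MAF and the HWE
#' test use non-missing calls only. Each removed SNP is attributed to the
#' first rule it fails, in the order call rate, MAF, HWE.
#'
#' @param genotypes individuals x SNPs matrix (individual QC already
#'   applied).
#' @param min_call,min_maf,min_hwe_p thresholds.
#' @return list with `genotypes` (retained columns) and `report` (class
#'   `qc_report`) holding per-SNP call rate, MAF, HWE chi-square and p,
#'   removed ids and per-rule counts.
#' @export
qc_snps <- function(genotypes, min_call = 0.97, min_maf = 0.05,
                    min_hwe_p = 1e-5) {
  if (!nrow(genotypes) || !ncol(genotypes)) stopf("empty genotype matrix")
  call_rate <- colMeans(!is.na(genotypes))
  n_AA <- colSums(genotypes == 2, na.rm = TRUE)
  n_Aa <- colSums(genotypes == 1, na.rm = TRUE)
  n_aa <- colSums(genotypes == 0, na.rm = TRUE)
  freq <- (2 * n_AA + n_Aa) / (2 * pmax(n_AA + n_Aa + n_aa, 1))
  maf <- pmin(freq, 1 - freq)
  hwe <- hwe_test(n_AA, n_Aa, n_aa)

  # strict "higher than" thresholds, with a tiny epsilon so a SNP sitting
  # exactly on a threshold is removed despite floating-point rounding
  eps <- 1e-9
  fail_call <- call_rate <= min_call + eps
  fail_maf <- maf <= min_maf + eps
  fail_hwe <- !is.na(hwe$p) & hwe$p <= min_hwe_p * (1 + eps)
  first_rule <- rep(NA_character_, ncol(genotypes))
  first_rule[fail_hwe] <- "hwe"
  first_rule[fail_maf] <- "maf"
  first_rule[fail_call] <- "call_rate"
  keep <- is.na(first_rule)

  report <- structure(list(
    stage = "snps",
    n_input = ncol(genotypes),
    n_removed = sum(!keep),
    removed = colnames(genotypes)[!keep],
    snp_stats = data.frame(snp = colnames(genotypes), call_rate = call_rate,
                           maf = maf, hwe_chisq = hwe$chisq, hwe_p = hwe$p,
                           removed_by = first_rule, stringsAsFactors = FALSE),
    rules = c(call_rate = sum(first_rule == "call_rate", na.rm = TRUE),
              maf = sum(first_rule == "maf", na.rm = TRUE),
              hwe = sum(first_rule == "hwe", na.rm = TRUE))),
    class = "qc_report")
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Genotype QC (%s): %d of %d removed\n", x$stage, x$n_removed, x$n_input))
  for (r in names(x$rules)) cat(sprintf("  %-10s %d\n", r, x$rules[[r]]))
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  if (!is.null(report$snp_stats)) {
    .write_tsv(report$snp_stats, path)
  } else {
    .write_tsv(data.frame(id = names(report$call_rate),
                          call_rate = report$call_rate,
                          removed = names(report$call_rate) %in% report$removed),
               path)
  }
}
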