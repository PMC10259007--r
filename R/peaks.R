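# Genotype contrasts at peak SNPs (homozygote difference, Tukey HSD,
# dominance test) and isogenic-line concordance with GWAS favourable
# alleles.

#' Genotype contrast at a peak SNP
#'
#' Phenotypes are corrected for the day and dam effects of a previously
#' fitted null animal model (day BLUEs and dam BLUPs subtracted; the SNP is
#' not co-fitted). The difference between the two homozygote class means is
#' expressed as a percentage of the phenotypic SD, with the favourable
#' homozygote named; significance across the three genotype classes comes
#' from a Tukey HSD after one-way ANOVA. The dominance effect d is the
#' heterozygote mean minus the midpoint of the homozygote means, tested by
#' default a z-test whose standard error accounts for the sampling
#' variance of both the heterozygote mean and the estimated midpoint
#' (`dominance_test = "adjusted"`), which holds the nominal size on
#' additive loci; `dominance_test = "midpoint-t"` gives the naive
#' one-sample t-test of the heterozygotes' values against the observed
#' midpoint treated as a known constant (anti-conservative, provided for
#' comparability with tabulated per-SNP dominance p-values).
#'
#' @param phenotypes `data.frame` with `id`, the trait and the day/dam
#'   columns used in the null fit.
#' @param null_fit univariate `reml_fit` of the trait without the SNP.
#' @param genotypes genotype matrix (0/1/2) containing the SNP.
#' @param snp SNP identifier (column of `genotypes`).
#' @param trait,day_col,dam_col column names.
#' @param sd_pheno phenotypic SD used to scale the difference; defaults to
#'   the SD of the trait column (1 for within-group standardised TLE).
#' @param dominance_test `"adjusted"` (default) or `"midpoint-t"`, see
#'   Details.
#' @return object of class `peak_contrast`: genotype-class means and
#'   counts, `maf`, `diff` (hom2 - hom0 on the trait scale),
#'   `diff_pct_sd` (absolute, % of phenotypic SD), `favourable_homozygote`
#'   (`"ref"` or `"alt"`), `tukey_p` (hom0 vs hom2), `dominance`,
#'   `dominance_p`, `complete` (all three classes observed).
#' @export
peak_contrast <- function(phenotypes, null_fit, genotypes, snp,
                          trait = "tle", day_col = "group", dam_col = "dam",
                          sd_pheno = NULL,
                          dominance_test = c("adjusted", "midpoint-t")) {
  dominance_test <- match.arg(dominance_test)
  ids <- intersect(phenotypes$id, rownames(genotypes))
  ph <- phenotypes[match(ids, phenotypes$id), ]
  y <- ph[[trait]]
  sd_pheno <- sd_pheno %||% sd(y)

  day_eff <- null_fit$fixef[[trait]]
  adj <- y - unname(day_eff[as.character(ph[[day_col]])])
  if (!is.null(null_fit$dam_blup)) {
    db <- null_fit$dam_blup[as.character(ph[[dam_col]])]
    db[is.na(db)] <- 0
    adj <- adj - unname(db)
  }

  z <- genotypes[ids, snp]
  ok <- !is.na(z) & is.finite(adj)
  z <- z[ok]; adj <- adj[ok]
  counts <- vapply(0:2, function(g) sum(z == g), integer(1))
  names(counts) <- c("hom0", "het", "hom2")
  complete <- all(counts >= 1)
  freq <- mean(z) / 2
  maf <- min(freq, 1 - freq)

  means <- vapply(0:2, function(g) if (counts[g + 1]) mean(adj[z == g]) else NA_real_,
                  numeric(1))
  names(means) <- names(counts)

  diff <- means["hom2"] - means["hom0"]
  tukey_p <- dominance <- dominance_p <- NA_real_
  if (complete) {
    gf <- factor(z, levels = 0:2)
    tk <- TukeyHSD(aov(adj ~ gf))$gf
    tukey_p <- tk["2-0", "p adj"]
    midpoint <- (means["hom0"] + means["hom2"]) / 2
    dominance <- means["het"] - midpoint
    vars <- vapply(0:2, function(g)
      if (counts[g + 1] > 1) var(adj[z == g]) else NA_real_, numeric(1))
    if (all(counts >= 2) && all(vars > 0)) {
      if (dominance_test == "adjusted") {
        se_d <- sqrt(vars[2] / counts["het"] +
                       (vars[1] / counts["hom0"] + vars[3] / counts["hom2"]) / 4)
        dominance_p <- 2 * stats::pnorm(-abs(dominance / se_d))
      } else {
        dominance_p <- t.test(adj[z == 1], mu = midpoint)$p.value
      }
    }
  }

  structure(list(snp = snp, n = counts, means = means, maf = maf,
                 diff = unname(diff),
                 diff_pct_sd = abs(unname(diff)) / sd_pheno * 100,
                 favourable_homozygote = if (is.na(diff)) NA_character_
                   else if (diff >= 0) "ref" else "alt",
                 tukey_p = unname(tukey_p),
                 dominance = unname(dominance),
                 dominance_p = unname(dominance_p),
                 sd_pheno = sd_pheno,
                 complete = complete),
            class = "peak_contrast")
}

#' @export
print.peak_contrast <- function(x, ...) {
  cat(sprintf("Contrast at %s (MAF %.2f)%s\n", x$snp, x$maf,
              if (x$complete) "" else " [INCOMPLETE: missing genotype class]"))
  print(round(rbind(n = x$n, mean = x$means), 3))
  if (x$complete) {
    cat(sprintf("homozygote difference: %.3f (%.0f%% of phenotypic SD, favourable %s), Tukey p = %.3g\n",
                x$diff, x$diff_pct_sd, x$favourable_homozygote, x$tukey_p))
    cat(sprintf("dominance d = %.3f, p = %.3g\n", x$dominance, x$dominance_p))
  }
  invisible(x)
}

#' Concordance of isogenic-line alleles with GWAS favourable alleles
#'
#' For every SNP above the logBF threshold at which the two fully
#' homozygous lines carry different alleles, reports the line alleles, the
#' favourable allele estimated by the GWAS (the reference allele when the
#' posterior mean effect is positive, the alternate otherwise), and
#' whether the resistant line carries it.
#'
#' @param gwas_result `gwas_result` (fit with a map).
#' @param line_sensitive,line_resistant `data.frame`s with columns `snp`
#'   and `allele` (one base per SNP) for the sensitive and resistant
#'   lines.
#' @param snp_map SNP map supplying `ref` and `alt` alleles.
#' @param logbf_threshold minimum logBF for a SNP to be examined.
#' @return `data.frame` (class `isogenic_report`): `snp`, `chr`, `pos`,
#'   `allele_sensitive`, `allele_resistant`, `logbf`, `effect`,
#'   `favourable_allele`, `concordant`. Only SNPs where the lines differ
#'   appear.
#' @export
isogenic_concordance <- function(gwas_result, line_sensitive, line_resistant,
                                 snp_map, logbf_threshold = 6) {
  for (ln in list(line_sensitive, line_resistant)) {
    if (anyDuplicated(ln$snp)) stopf("SNP-id collision in line genotypes")
  }
  snps <- gwas_result$snps
  top <- snps[snps$logbf > logbf_threshold, , drop = FALSE]
  mi_s <- match(top$snp, line_sensitive$snp)
  mi_r <- match(top$snp, line_resistant$snp)
  keep <- !is.na(mi_s) & !is.na(mi_r)
  top <- top[keep, , drop = FALSE]
  al_s <- line_sensitive$allele[mi_s[keep]]
  al_r <- line_resistant$allele[mi_r[keep]]
  differ <- al_s != al_r
  top <- top[differ, , drop = FALSE]
  al_s <- al_s[differ]; al_r <- al_r[differ]
  mm <- match(top$snp, snp_map$snp)
  fav <- ifelse(top$effect > 0, snp_map$ref[mm], snp_map$alt[mm])
  out <- data.frame(snp = top$snp,
                    chr = top$chr %||% snp_map$chr[mm],
                    pos = top$pos %||% snp_map$pos[mm],
                    allele_sensitive = al_s,
                    allele_resistant = al_r,
                    logbf = top$logbf,
                    effect = top$effect,
                    favourable_allele = fav,
                    concordant = al_r == fav,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("isogenic_report", class(out))
  out
}

#' Write a peak-contrast table (one row per contrast) to TSV
#'
#' @param contrasts list of `peak_contrast` objects.
#' @param path output path.
#' @export
write_contrast_report <- function(contrasts, path) {
  df <- do.call(rbind, lapply(contrasts, function(x) {
    data.frame(snp = x$snp, maf = x$maf,
               n_hom0 = x$n["hom0"], n_het = x$n["het"], n_hom2 = x$n["hom2"],
               mean_hom0 = x$means["hom0"], mean_het = x$means["het"],
               mean_hom2 = x$means["hom2"],
               diff_pct_sd = x$diff_pct_sd,
               favourable = x$favourable_homozygote,
               tukey_p = x$tukey_p,
               dominance = x$dominance, dominance_p = x$dominance_p,
               complete = x$complete, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  .write_tsv(df, path)
}
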