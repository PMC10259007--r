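toy_result <- function(pos_kb, logbf, chr = "1") {
  fake_gwas_result(data.frame(
    snp = sprintf("T%03d", seq_along(pos_kb)),
    chr = chr, pos = pos_kb * 1000,
    freq = 0.3, p_incl = 0.5, effect = 0.1, logbf = logbf,
    stringsAsFactors = FALSE))
}

test_that("credibility intervals chain supporting SNPs", {
  res <- toy_result(c(100, 150, 200, 320, 600), c(2, 4, 9, 3.5, 3.5))
  q <- call_qtl(res)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_snp, "T003")
  expect_equal(q$start, 150000) # chained left over T002
  expect_equal(q$end, 320000) # T004 chained; T005 is 280 kb beyond: not
  expect_equal(q$n_snps, 3)
})

test_that("singleton peaks are discarded as artifacts", {
  # nearest support is 250 kb away: outside the 200-kb window
  res <- toy_result(c(100, 350), c(7, 3.5))
  q <- call_qtl(res)
  expect_equal(nrow(q), 0)
  art <- attr(q, "artifacts")
  expect_equal(art$snp, "T001")

  # same map with support at 150 kb: called
  res2 <- toy_result(c(100, 250), c(7, 3.5))
  expect_equal(nrow(call_qtl(res2)), 1)
})

test_that("no peaks means no regions", {
  res <- toy_result(c(100, 200, 300), c(5.9, 3, 2))
  q <- call_qtl(res)
  expect_equal(nrow(q), 0)
  expect_null(attr(q, "artifacts"))
})

test_that("overlapping intervals merge under the higher peak", {
  res <- toy_result(c(100, 200, 300, 400, 500), c(3.5, 8, 3.5, 7, 3.5))
  q <- call_qtl(res)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_snp, "T002")
  expect_equal(c(q$start, q$end), c(100000, 500000))
  expect_equal(q$n_snps, 5)
})

test_that("calling is invariant to row order and regions respect the map", {
  res <- toy_result(c(100, 150, 200, 320, 600, 900), c(2, 4, 9, 3.5, 3.5, 6.5))
  q1 <- call_qtl(res)
  res2 <- res
  set.seed(1)
  res2$snps <- res2$snps[sample(nrow(res2$snps)), ]
  q2 <- call_qtl(res2)
  expect_equal(as.data.frame(q1), as.data.frame(q2))
  # every region's SNP count equals the mapped SNPs inside its interval
  for (i in seq_len(nrow(q1))) {
    inside <- res$snps$pos >= q1$start[i] & res$snps$pos <= q1$end[i]
    expect_equal(q1$n_snps[i], sum(inside))
  }
})

test_that("the fixed-window alternative bounds intervals at one window", {
  res <- toy_result(c(100, 290, 480, 600), c(9, 3.5, 3.5, 2))
  chain <- call_qtl(res, method = "chain")
  fixed <- call_qtl(res, method = "fixed")
  expect_equal(chain$end, 480000) # 290 chains to 480
  expect_equal(fixed$end, 290000) # only SNPs within 200 kb of the peak
})

test_that("variance explained follows the 2p(1-p)a^2 closed form", {
  set.seed(41)
  n <- 4000
  z <- rbinom(n, 2, 0.42)
  geno <- matrix(z, n, 1, dimnames = list(paste0("i", 1:n), "T001"))
  p_obs <- mean(z) / 2
  gebv <- rnorm(n)
  gebv <- gebv / sd(gebv) * sqrt(0.29) # empirical GEBV variance 0.29
  res <- fake_gwas_result(data.frame(snp = "T001", chr = "1", pos = 100000,
                                     freq = p_obs, p_incl = 1, effect = 0.10,
                                     logbf = 10, stringsAsFactors = FALSE),
                          gebv = setNames(gebv, rownames(geno)))
  reg <- data.frame(name = "Q1", chr = "1", peak_snp = "T001",
                    peak_pos = 100000, peak_logbf = 10,
                    start = 100000, end = 100000, n_snps = 1)
  v <- variance_explained(reg, res, geno)
  vg <- var(gebv)
  expect_equal(v$pct_var_peak, 2 * p_obs * (1 - p_obs) * 0.01 / vg * 100,
               tolerance = 1e-10)
  # frozen arithmetic at the nominal values: 2 * .42 * .58 * .01 / .29 = 1.68%
  expect_equal(2 * 0.42 * 0.58 * 0.10^2 / 0.29 * 100, 1.68, tolerance = 0.01)
  # single causal SNP, no LD: region share matches the peak share
  expect_equal(v$pct_var_region, v$pct_var_peak, tolerance = 0.05)
})

test_that("region variance uses the LD-aware regional genomic value", {
  set.seed(42)
  n <- 2000
  z1 <- rbinom(n, 2, 0.5)
  z2 <- z1 # perfect LD duplicate
  geno <- cbind(T001 = z1, T002 = z2)
  rownames(geno) <- paste0("i", 1:n)
  gebv <- (z1 - mean(z1)) * 0.2 # all genetic variance from this locus
  res <- fake_gwas_result(data.frame(snp = c("T001", "T002"), chr = "1",
                                     pos = c(1e5, 1.5e5), freq = 0.5,
                                     p_incl = 0.5, effect = c(0.1, 0.1),
                                     logbf = c(8, 4), stringsAsFactors = FALSE),
                          gebv = setNames(gebv, rownames(geno)))
  reg <- data.frame(name = "Q1", chr = "1", peak_snp = "T001",
                    peak_pos = 1e5, peak_logbf = 8,
                    start = 1e5, end = 1.5e5, n_snps = 2)
  v <- variance_explained(reg, res, geno)
  # two perfectly correlated SNPs: summed value is 0.2 z, variance = gebv var
  expect_equal(v$pct_var_region, 100, tolerance = 1e-8)
  expect_error(variance_explained(reg, fake_gwas_result(res$snps,
                                                        gebv = rep(0, 5)),
                                  geno), "zero total genetic variance")
})

test_that("gene annotation counts >= 1 bp overlaps and flags mismatches", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t120000\t140000\t.\t+\t.\tID=g1;Name=geneA",
    "1\ttest\tgene\t200000\t210000\t.\t-\t.\tID=g2;Name=geneB",
    "1\ttest\tgene\t50000\t100000\t.\t+\t.\tID=g3;Name=geneC",
    "2\ttest\tgene\t100000\t200000\t.\t+\t.\tID=g4;Name=geneD"), gff)
  reg <- data.frame(name = "Q1", chr = "1", peak_snp = "T001",
                    peak_pos = 150000, peak_logbf = 8,
                    start = 100000, end = 200000, n_snps = 3)
  out <- annotate_regions(reg, gff)
  # geneA inside, geneB touches the boundary bp, geneC ends exactly at start
  expect_equal(out$n_genes, 3)
  expect_setequal(strsplit(out$genes, ",")[[1]], c("geneA", "geneB", "geneC"))

  empty <- annotate_regions(reg, GenomicRanges::GRanges())
  expect_equal(empty$n_genes, 0)

  reg2 <- reg; reg2$chr <- "chrZ"
  expect_warning(annotate_regions(reg2, gff), "chrZ")
})

test_that("unmapped results are rejected", {
  res <- fake_gwas_result(data.frame(snp = "a", p_incl = 1, effect = 1,
                                     logbf = 9))
  expect_error(call_qtl(res), "map")
})
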