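make_contrast_data <- function(n = 1000, maf = 0.42, a = 0.345, d = 0,
                               sd_e = 1, seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 2, maf)
  y <- a * z + d * (z == 1) + rnorm(n, 0, sd_e)
  ids <- paste0("i", seq_len(n))
  list(pheno = data.frame(id = ids, tle = y, group = "G1", dam = "D1",
                          stringsAsFactors = FALSE),
       geno = matrix(z, n, 1, dimnames = list(ids, "Q1")))
}

test_that("equal class means give a null contrast", {
  ids <- paste0("i", 1:9)
  z <- rep(0:2, each = 3)
  y <- rep(c(-1, 0, 1), times = 3) # identical means in all classes
  ph <- data.frame(id = ids, tle = y, group = "G1", dam = "D1")
  geno <- matrix(z, 9, 1, dimnames = list(ids, "Q1"))
  ct <- peak_contrast(ph, flat_null_fit(), geno, "Q1")
  expect_equal(ct$diff, 0)
  expect_equal(ct$dominance, 0)
  expect_gt(ct$tukey_p, 0.99)
  expect_true(ct$complete)
})

test_that("an additive contrast recovers the homozygote difference", {
  # effect half the homozygote gap: 2a = 0.69 of the unit phenotypic SD
  dat <- make_contrast_data(n = 1000, maf = 0.42, a = 0.345, seed = 2)
  ct <- peak_contrast(dat$pheno, flat_null_fit(), dat$geno, "Q1",
                      sd_pheno = 1)
  expect_lt(abs(ct$diff_pct_sd - 69), 12)
  expect_gt(ct$dominance_p, 0.05) # purely additive: no dominance
  expect_equal(ct$favourable_homozygote, "ref")
  expect_lt(ct$tukey_p, 1e-6)
})

test_that("planted dominance is recovered across replicates", {
  dhat <- vapply(1:20, function(r) {
    dat <- make_contrast_data(n = 1000, maf = 0.46, a = 0.18, d = 0.09,
                              seed = 100 + r)
    peak_contrast(dat$pheno, flat_null_fit(), dat$geno, "Q1",
                  sd_pheno = 1)$dominance
  }, numeric(1))
  expect_lt(abs(mean(dhat) - 0.09), 0.05)
})

test_that("the dominance test holds its nominal size on additive loci", {
  pvals <- vapply(1:100, function(r) {
    dat <- make_contrast_data(n = 400, maf = 0.35, a = 0.3, d = 0,
                              seed = 500 + r)
    peak_contrast(dat$pheno, flat_null_fit(), dat$geno, "Q1")$dominance_p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # binomial check around 5% over 100 loci
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 0.02)
})

test_that("allele relabelling flips the call consistently", {
  dat <- make_contrast_data(n = 800, maf = 0.4, a = 0.4, seed = 3)
  ct1 <- peak_contrast(dat$pheno, flat_null_fit(), dat$geno, "Q1")
  flipped <- dat$geno
  flipped[, 1] <- 2L - flipped[, 1]
  ct2 <- peak_contrast(dat$pheno, flat_null_fit(), flipped, "Q1")
  expect_equal(ct1$diff_pct_sd, ct2$diff_pct_sd, tolerance = 1e-10)
  expect_equal(ct1$maf, ct2$maf)
  expect_setequal(c(ct1$favourable_homozygote, ct2$favourable_homozygote),
                  c("ref", "alt"))
})

test_that("a missing genotype class flags the contrast incomplete", {
  ids <- paste0("i", 1:10)
  z <- c(rep(0, 5), rep(1, 5)) # no hom2 class
  ph <- data.frame(id = ids, tle = rnorm(10), group = "G1", dam = "D1")
  geno <- matrix(z, 10, 1, dimnames = list(ids, "Q1"))
  ct <- peak_contrast(ph, flat_null_fit(), geno, "Q1")
  expect_false(ct$complete)
  expect_true(is.na(ct$tukey_p))
})

test_that("day and dam corrections are subtracted before contrasting", {
  set.seed(4)
  n <- 600
  ids <- paste0("i", seq_len(n))
  z <- rbinom(n, 2, 0.4)
  grp <- sample(c("G1", "G2"), n, TRUE)
  dams <- sample(c("D1", "D2", "D3"), n, TRUE)
  day_eff <- c(G1 = 0, G2 = 2)
  dam_eff <- c(D1 = -0.5, D2 = 0, D3 = 0.5)
  y <- 0.3 * z + day_eff[grp] + dam_eff[dams] + rnorm(n, 0, 0.5)
  ph <- data.frame(id = ids, tle = y, group = grp, dam = dams)
  nf <- structure(list(fixef = list(tle = day_eff),
                       dam_blup = dam_eff), class = "reml_fit")
  geno <- matrix(z, n, 1, dimnames = list(ids, "Q1"))
  ct_adj <- peak_contrast(ph, nf, geno, "Q1", sd_pheno = 1)
  ct_raw <- peak_contrast(ph, flat_null_fit(c("G1", "G2")), geno, "Q1",
                          sd_pheno = 1)
  # adjustment sharpens the contrast toward the true 0.6 gap
  expect_lt(abs(ct_adj$diff - 0.6), abs(ct_raw$diff - 0.6) + 0.05)
  expect_lt(abs(ct_adj$diff - 0.6), 0.15)
})

test_that("isogenic concordance reports exactly the differing top SNPs", {
  snps <- data.frame(snp = paste0("S", 1:6), chr = "1",
                     pos = seq(1e5, 6e5, by = 1e5), freq = 0.4,
                     p_incl = 0.5,
                     effect = c(0.2, -0.3, 0.1, 0.4, -0.2, 0.05),
                     logbf = c(8, 7, 2, 9, 6.5, 1),
                     stringsAsFactors = FALSE)
  res <- fake_gwas_result(snps)
  map <- data.frame(snp = snps$snp, chr = "1", pos = snps$pos,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  # lines differ at S1, S2, S5 (all logBF > 6) and at S3 (below threshold)
  sens <- data.frame(snp = map$snp, allele = c("G", "A", "A", "A", "A", "A"))
  resi <- data.frame(snp = map$snp, allele = c("A", "G", "G", "A", "G", "A"))
  rep <- isogenic_concordance(res, sens, resi, map)
  expect_equal(nrow(rep), 3)
  expect_setequal(rep$snp, c("S1", "S2", "S5"))
  # favourable allele is ref (A) iff effect > 0
  expect_equal(rep$favourable_allele[rep$snp == "S1"], "A")
  expect_equal(rep$favourable_allele[rep$snp == "S2"], "G")
  expect_true(rep$concordant[rep$snp == "S1"]) # resistant carries A
  expect_true(rep$concordant[rep$snp == "S2"]) # resistant carries G
  expect_equal(rep$concordant[rep$snp == "S5"],
               rep$favourable_allele[rep$snp == "S5"] == "G")

  # identical lines: empty report
  rep2 <- isogenic_concordance(res, sens, sens, map)
  expect_equal(nrow(rep2), 0)

  dup <- rbind(sens, sens[1, ])
  expect_error(isogenic_concordance(res, dup, resi, map), "collision")
})

test_that("synthetic isogenic pairs are homozygous line genomes", {
  st <- small_study()
  founders <- st$ped$id[st$ped$generation == 0]
  pair <- synthesize_isogenic_pair(st$geno, founders[1], founders[2], st$map,
                                   seed = 5)
  expect_equal(nrow(pair), nrow(st$map))
  expect_true(all(pair$allele_a %in% c(st$map$ref, st$map$alt)))
  # a homozygous founder locus keeps its allele
  hom2 <- which(st$geno[founders[1], st$map$snp] == 2)
  expect_true(all(pair$allele_a[hom2] == st$map$ref[hom2]))
})
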