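test_that("factorial pedigree has the required block structure", {
  ped <- make_pedigree(n_blocks = 2, sires_per_block = 2, dams_per_block = 2,
                       offspring_per_pair = 1, seed = 1)
  off <- ped[ped$generation == 1, ]
  expect_equal(nrow(off), 8) # 2 blocks x 2x2 pairs x 1 offspring
  founders <- ped[ped$generation == 0, ]
  blk <- setNames(founders$block, founders$id)
  expect_true(all(blk[off$sire] == blk[off$dam]))
  expect_true(all(is.na(founders$sire) & is.na(founders$dam)))

  # default design: 99 sires, 76 dams over 10 blocks
  ped2 <- make_pedigree(seed = 2)
  expect_equal(sum(grepl("^S", ped2$id)), 99)
  expect_equal(sum(grepl("^D", ped2$id)), 76)

  # mean full-sib family size equals offspring / mated pairs
  ped3 <- make_pedigree(n_blocks = 3, sires_per_block = 3, dams_per_block = 2,
                        offspring_per_pair = 4, seed = 3)
  off3 <- ped3[ped3$generation == 1, ]
  fam <- table(paste(off3$sire, off3$dam))
  expect_equal(mean(fam), nrow(off3) / (3 * 3 * 2))

  expect_error(make_pedigree(n_blocks = 0), "n_blocks")
  expect_error(make_pedigree(sires_per_block = 0), ">= 1")
})

test_that("pedigree generation is deterministic under a fixed seed", {
  a <- make_pedigree(n_offspring = 50, seed = 7)
  b <- make_pedigree(n_offspring = 50, seed = 7)
  expect_identical(a, b)
  g1 <- gene_drop(a, make_snp_map(100, 2, seed = 8), seed = 9)
  g2 <- gene_drop(a, make_snp_map(100, 2, seed = 8), seed = 9)
  expect_identical(g1, g2)
})

test_that("gene dropping is Mendelian-consistent and respects fixed alleles", {
  ped <- make_pedigree(n_blocks = 2, sires_per_block = 3, dams_per_block = 3,
                       offspring_per_pair = 3, seed = 11)
  map <- make_snp_map(200, 4, seed = 12)
  g <- gene_drop(ped, map, seed = 13)

  # fixed founder alleles propagate unchanged
  gfix <- gene_drop(ped, map, founder_freq = 1, seed = 14)
  expect_true(all(gfix == 2L))
  gfix0 <- gene_drop(ped, map, founder_freq = 0, seed = 15)
  expect_true(all(gfix0 == 0L))

  # no offspring genotype incompatible with its parents
  off <- ped[ped$generation == 1, ]
  for (k in seq_len(nrow(off))) {
    zs <- g[off$sire[k], ]; zd <- g[off$dam[k], ]; zo <- g[off$id[k], ]
    lo <- (zs == 2) + (zd == 2) # forced reference gametes
    hi <- 2 - ((zs == 0) + (zd == 0)) # forced alternate gametes
    expect_true(all(zo >= lo & zo <= hi))
  }
})

test_that("het x het matings segregate 1:2:1 within binomial error", {
  ped <- make_pedigree(n_blocks = 1, sires_per_block = 1, dams_per_block = 1,
                       offspring_per_pair = 10000, seed = 21)
  map <- make_snp_map(30, 3, seed = 22)
  g <- gene_drop(ped, map, founder_freq = 0.5, seed = 23)
  het <- which(g["S001", ] == 1 & g["D001", ] == 1)
  expect_gt(length(het), 0)
  off <- g[ped$id[ped$generation == 1], het, drop = FALSE]
  n <- nrow(off)
  for (j in seq_len(ncol(off))) {
    counts <- c(sum(off[, j] == 0), sum(off[, j] == 1), sum(off[, j] == 2))
    expected <- n * c(0.25, 0.5, 0.25)
    se <- sqrt(n * c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75))
    expect_true(all(abs(counts - expected) < 4 * se))
  }
})

test_that("gene dropping conserves allele frequency in expectation", {
  ped <- make_pedigree(n_blocks = 4, sires_per_block = 5, dams_per_block = 4,
                       offspring_per_pair = 3, seed = 31)
  map <- make_snp_map(150, 3, seed = 32)
  founders <- ped$id[ped$generation == 0]
  offspring <- ped$id[ped$generation == 1]
  diffs <- replicate(20, {
    g <- gene_drop(ped, map)
    colMeans(g[offspring, ]) / 2 - colMeans(g[founders, ]) / 2
  })
  # mean drift over replicates should be within 3 SE of zero per SNP
  se <- apply(diffs, 1, sd) / sqrt(ncol(diffs))
  expect_gt(mean(abs(rowMeans(diffs)) < 3 * pmax(se, 1e-8)), 0.95)
})

test_that("founder genotypes sit at Hardy-Weinberg proportions", {
  ped <- make_pedigree(n_blocks = 10, sires_per_block = 30, dams_per_block = 30,
                       offspring_per_pair = 1, seed = 41)
  map <- make_snp_map(400, 4, seed = 42)
  g <- gene_drop(ped, map, seed = 43)
  gf <- g[ped$generation == 0, ]
  counts <- cbind(colSums(gf == 2), colSums(gf == 1), colSums(gf == 0))
  hw <- hwe_test(counts[, 1], counts[, 2], counts[, 3])
  # about 5% of SNPs should fail at alpha = 0.05 under the null
  expect_lt(mean(hw$p < 0.05, na.rm = TRUE), 0.12)
})

test_that("missingness rate and input validation behave", {
  ped <- make_pedigree(n_blocks = 1, sires_per_block = 2, dams_per_block = 2,
                       offspring_per_pair = 20, seed = 51)
  map <- make_snp_map(300, 2, seed = 52)
  g <- gene_drop(ped, map, missing_rate = 0.1, seed = 53)
  expect_gt(mean(is.na(g)), 0.07)
  expect_lt(mean(is.na(g)), 0.13)
  expect_error(gene_drop(ped, map, founder_freq = 1.2), "frequencies")
  expect_error(gene_drop(ped, map, missing_rate = 1), "missing_rate")
})

test_that("heating curves follow the two-phase profile", {
  hc <- heating_curve("G1", t0 = 17.3)
  # +3.1 C/h for 1.5 h then +0.9 C/h: at 6 h the rise is 8.7 C
  expect_equal(temp_at(hc, 360), 17.3 + 1.5 * 3.1 + 4.5 * 0.9, tolerance = 1e-10)
  expect_equal(temp_at(hc, 0), 17.3)
  tt <- temp_at(hc, seq(0, 600, by = 10))
  expect_true(all(diff(tt) >= 0))
  finite <- heating_curve("G1", t0 = 17, segments = data.frame(
    duration_h = c(1, 1), rate_c_per_h = c(2, 1)))
  expect_error(temp_at(finite, 121), "ends before")
  expect_error(heating_curve("G1", segments = data.frame(
    duration_h = 1, rate_c_per_h = -1)), "rates")
})

test_that("zero-variance challenge yields identical times within a group", {
  ped <- make_pedigree(n_blocks = 1, sires_per_block = 2, dams_per_block = 2,
                       offspring_per_pair = 10, seed = 61)
  map <- make_snp_map(100, 2, seed = 62)
  g <- gene_drop(ped, map, seed = 63)
  tr <- truth_record(var_u = 0, var_dam = 0, var_e = 0)
  sim <- simulate_challenge(ped, g, tr,
                            heating_curves = default_heating_curves("G1"),
                            seed = 64)
  expect_lt(diff(range(sim$pheno$rtle)), 1e-8)
})

test_that("challenge variance decomposition recovers the configured fractions", {
  ped <- make_pedigree(n_offspring = 500, seed = 71)
  map <- make_snp_map(1500, 10, seed = 72)
  g <- gene_drop(ped, map, seed = 73)
  tr <- truth_record(var_u = 0.30, var_dam = 0.06, var_e = 0.64)
  fr <- t(replicate(50, {
    sim <- simulate_challenge(ped, g, tr)
    cmp <- sim$components
    tot <- var(cmp$u + cmp$qtl + cmp$dam_eff + cmp$resid)
    c(h2 = var(cmp$u) / tot, dam = var(cmp$dam_eff) / tot)
  }))
  for (k in c("h2", "dam")) {
    se <- sd(fr[, k]) / sqrt(nrow(fr))
    target <- c(h2 = 0.30, dam = 0.06)[[k]]
    # replicate-mean fraction within 2 SE (plus a small allowance for the
    # finite-sample covariance between components)
    expect_lt(abs(mean(fr[, k]) - target), 2 * se + 0.02)
  }
})

test_that("planted QTL contribute 2p(1-p)a^2 of genetic variance", {
  ped <- make_pedigree(n_offspring = 600, seed = 81)
  map <- make_snp_map(800, 5, seed = 82)
  g <- gene_drop(ped, map, seed = 83)
  frq <- colMeans(g) / 2
  i <- which.min(abs(frq - 0.4))
  a <- 0.5
  tr <- truth_record(var_u = 0.2, var_dam = 0, var_e = 0.5,
                     qtl = data.frame(snp = map$snp[i], a = a, d = 0))
  qvar <- replicate(30, {
    sim <- simulate_challenge(ped, g, tr)
    var(sim$components$qtl)
  })
  p <- mean(g[ped$id[ped$generation == 1], i]) / 2
  expect_equal(mean(qvar), 2 * p * (1 - p) * a^2, tolerance = 0.15)
})

test_that("harvest simulator plants exactly the requested inconsistencies", {
  ped <- make_pedigree(n_offspring = 400, seed = 91)
  map <- make_snp_map(600, 5, seed = 92)
  g <- gene_drop(ped, map, seed = 93)
  hs <- simulate_harvest(ped, g, truth_record(), n_violations = 24, seed = 94)
  flt <- derive_and_filter_harvest(hs$pheno)
  expect_equal(length(flt$removed), 24)
  expect_setequal(flt$removed, hs$violations)
  keep <- flt$table
  expect_true(all(abs(keep$bw2 - (keep$hgcw + keep$headw + keep$viscw)) <= 10))
})

test_that("harvest genetic correlations track an identity target", {
  ped <- make_pedigree(n_offspring = 300, seed = 95)
  map <- make_snp_map(600, 5, seed = 96)
  g <- gene_drop(ped, map, seed = 97)
  hv <- default_harvest_truth()
  hv$rg <- diag(4); dimnames(hv$rg) <- dimnames(hv$rp)
  hv$rp <- diag(4); dimnames(hv$rp) <- dimnames(hv$rg)
  tr <- truth_record(harvest = hv)
  cors <- replicate(25, {
    hs <- simulate_harvest(ped, g, tr, n_violations = 0)
    u <- as.matrix(hs$components[, -1])
    c(cor(u[, 1], u[, 2]), cor(u[, 1], u[, 3]), cor(u[, 2], u[, 4]))
  })
  expect_true(all(abs(rowMeans(cors)) < 3 * apply(cors, 1, sd) / sqrt(25) + 0.05))
})

test_that("impossible covariance targets are rejected with a diagnostic", {
  ped <- make_pedigree(n_blocks = 1, sires_per_block = 2, dams_per_block = 2,
                       offspring_per_pair = 5, seed = 98)
  map <- make_snp_map(100, 2, seed = 99)
  g <- gene_drop(ped, map, seed = 100)
  hv <- default_harvest_truth()
  hv$rg[1, 2] <- hv$rg[2, 1] <- 0.99
  hv$rg[1, 3] <- hv$rg[3, 1] <- 0.99
  hv$rg[2, 3] <- hv$rg[3, 2] <- -0.99 # jointly infeasible
  expect_error(simulate_harvest(ped, g, truth_record(harvest = hv),
                                n_violations = 0),
               "positive semi-definite")
  expect_error(truth_record(var_u = -0.1), ">= 0")
})
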