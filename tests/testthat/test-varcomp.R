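test_that("univariate REML recovers components and converges cleanly", {
  st <- small_study()
  G <- small_G()$G
  fit <- reml_fit(st$pheno, "tle", G)
  expect_true(fit$converged)
  expect_false(any(fit$boundary))
  # log-likelihood never decreases across accepted iterations
  expect_true(all(diff(fit$trajectory$logL) > -1e-8))
  # estimates within 3 SE of the generating values
  expect_lt(abs(fit$h2 - 0.29), 3 * fit$h2_se + 0.05)
  expect_lt(abs(fit$dam_ratio - 0.06), 3 * fit$dam_ratio_se + 0.02)
  expect_equal(sum(fit$varcomp), fit$sigma_p2)
  # phenotypic variance close to the variance of day-adjusted data
  expect_equal(fit$sigma_p2, var(st$pheno$tle), tolerance = 0.15)
})

test_that("pedigree and genomic fits coincide when A = I = G", {
  set.seed(21)
  n <- 150
  ids <- paste0("i", 1:n)
  ph <- data.frame(id = ids, tle = rnorm(n),
                   group = sample(c("G1", "G2"), n, TRUE),
                   dam = sample(paste0("D", 1:10), n, TRUE))
  I_ped <- diag(n); dimnames(I_ped) <- list(ids, ids)
  I_gen <- diag(n); dimnames(I_gen) <- list(ids, ids)
  f1 <- reml_fit(ph, "tle", I_ped)
  f2 <- reml_fit(ph, "tle", I_gen)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-10)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-10)
})

test_that("zero additive variance is flagged at the boundary", {
  st <- small_study()
  G <- small_G()$G
  ph <- st$pheno
  set.seed(22)
  ph$noise <- rnorm(nrow(ph)) # no genetic signal at all
  fit <- reml_fit(ph, "noise", G, dam_traits = character(0))
  expect_lt(fit$varcomp[["var_u"]] / fit$sigma_p2, 0.1)
})

test_that("AIC comparison prefers parsimony on ties and real dam effects", {
  fa <- structure(list(AIC = 100, n_param = 3, n_obs = 50L), class = "reml_fit")
  fb <- structure(list(AIC = 100, n_param = 2, n_obs = 50L), class = "reml_fit")
  expect_equal(aic_compare(fa, fb)$selected, 2L) # tie -> simpler model
  # equal likelihood with one extra parameter is exactly Delta AIC = 2
  la <- -47
  fa2 <- structure(list(AIC = -2 * la + 2 * 3, n_param = 3, n_obs = 50L),
                   class = "reml_fit")
  fb2 <- structure(list(AIC = -2 * la + 2 * 2, n_param = 2, n_obs = 50L),
                   class = "reml_fit")
  expect_equal(aic_compare(fa2, fb2)$delta_aic, 2)
  expect_equal(aic_compare(fa2, fb2)$selected, 2L)
  fc <- structure(list(AIC = 90, n_param = 3, n_obs = 40L), class = "reml_fit")
  expect_error(aic_compare(fa, fc), "same data")
})

test_that("the dam model wins the AIC race when a dam effect exists", {
  ped <- make_pedigree(n_offspring = 600, seed = 31)
  map <- make_snp_map(1500, 10, seed = 32)
  g <- gene_drop(ped, map, seed = 33)
  pick <- function(truth, seed) {
    sim <- simulate_challenge(ped, g, truth, seed = seed)
    ph <- standardize_rtle(sim$pheno)
    G <- g_matrix(g[ph$id, ], blend_weight = 0.95, a_matrix = a_matrix(ped))
    f1 <- reml_fit(ph, "tle", G)
    f2 <- reml_fit(ph, "tle", G, dam_traits = character(0))
    aic_compare(f1, f2)$selected == 1L
  }
  with_dam <- vapply(1:10, function(r)
    pick(truth_record(var_u = 0.29, var_dam = 0.06, var_e = 0.65), 100 + r),
    logical(1))
  without_dam <- vapply(1:10, function(r)
    pick(truth_record(var_u = 0.29, var_dam = 0, var_e = 0.71), 200 + r),
    logical(1))
  expect_gte(mean(with_dam), 0.7)
  expect_lte(mean(without_dam), 0.5)
})

test_that("bivariate fits drop the residual covariance for disjoint traits", {
  st <- small_study()
  G <- small_G()$G
  ph <- st$pheno
  n <- nrow(ph)
  half <- seq_len(n) <= n / 2
  ph$t1 <- ifelse(half, ph$tle, NA)
  ph$t2 <- ifelse(!half, ph$bw1, NA)
  fit <- reml_fit(ph, c("t1", "t2"), G, dam_traits = character(0))
  expect_false("cov_e" %in% names(fit$varcomp)) # disjoint: fixed at zero
  expect_true(abs(fit$rg) <= 1)

  # shared animals: residual covariance is estimated
  fit2 <- reml_fit(ph, c("tle", "bw1"), G, dam_traits = "tle")
  expect_true("cov_e" %in% names(fit2$varcomp))
  expect_true(is.finite(fit2$rg_se))
})

test_that("REML reports mismatched relationship matrices", {
  st <- small_study()
  G <- small_G()$G
  ph <- st$pheno
  ph$id[1] <- "ghost"
  expect_error(reml_fit(ph, "tle", G), "missing from the relationship matrix")
})
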