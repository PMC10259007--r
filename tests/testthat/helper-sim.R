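# Shared synthetic fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a moderate challenge study reused by several files
small_study <- function() {
  fixture("small_study", function() {
    ped <- make_pedigree(n_offspring = 400, seed = 901)
    map <- make_snp_map(n_snps = 1200, n_chr = 10, seed = 902)
    geno <- gene_drop(ped, map, seed = 903)
    sim <- simulate_challenge(ped, geno, truth_record(), seed = 904)
    ph <- standardize_rtle(sim$pheno)
    list(ped = ped, map = map, geno = geno, sim = sim, pheno = ph)
  })
}

small_G <- function() {
  fixture("small_G", function() {
    st <- small_study()
    A <- a_matrix(st$ped)
    G <- g_matrix(st$geno[st$pheno$id, ], blend_weight = 0.95, a_matrix = A)
    list(A = A, G = G)
  })
}

# minimal fitted-null stand-in for peak contrasts on pre-adjusted data
flat_null_fit <- function(groups = "G1", trait = "tle") {
  structure(list(fixef = setNames(list(setNames(rep(0, length(groups)), groups)),
                                  trait),
                 dam_blup = NULL),
            class = "reml_fit")
}

# fabricate a gwas_result for the deterministic QTL-calling tests
fake_gwas_result <- function(snps, gebv = NULL) {
  structure(list(snps = snps,
                 gebv = gebv %||% setNames(rnorm(10), paste0("i", 1:10)),
                 pi_mean = 0.001, n_saved = 1000),
            class = "gwas_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
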