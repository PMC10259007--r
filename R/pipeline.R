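# End-to-end pipeline: simulate -> standardise -> QC -> relationship
# matrices -> REML -> GWAS -> QTL calling -> peak contrasts -> isogenic
# concordance, with every stage writing plain TSVs so any stage can be
# re-run standalone.

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' stage toggles, simulation sizes, QC thresholds, MCMC settings, QTL
#' thresholds and the master seed. Any element can be overridden through
#' `...` (or by editing the YAML written with [write_pipeline_config()]).
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param ... named overrides of the defaults.
#' @return configuration list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    stages = list(simulate = TRUE, standardize = TRUE, qc = TRUE,
                  relmat = TRUE, reml = TRUE, gwas = TRUE, callqtl = TRUE,
                  contrast = TRUE, isocheck = TRUE),
    sim = list(n_offspring = 800, n_snps = 2000, n_chr = 10,
               n_groups = 7, missing_rate = 0.01,
               var_u = 0.29, var_dam = 0.06, var_e = 0.65,
               qtl = list(n = 1, pct_genetic = 50, hidden = TRUE,
                          min_maf = 0.35),
               n_harvest = 0, n_violations = 24),
    qc = list(ind_min_call = 0.90, snp_min_call = 0.97, min_maf = 0.05,
              min_hwe_p = 1e-5),
    relmat = list(blend_weight = 0.95),
    reml = list(maxit = 100, tol = 1e-8),
    gwas = list(n_cycles = 20000, burn_in = 2000, thin = 10,
                alpha = NULL, beta = NULL, h2_prior = 0.3),
    qtl = list(peak_threshold = 6, support_threshold = 3, window_bp = 200000),
    isocheck = list(logbf_threshold = 6),
    annotation = NULL)
  modifyList(cfg, list(...))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config configuration list.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  modifyList(pipeline_config(), yaml::read_yaml(path))
}

.cfg_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in order and writes each stage's outputs as
#' TSV under `out_dir`, plus a `summary.txt` report holding descriptive
#' statistics, variance components, the QTL table, peak contrasts and the
#' isogenic concordance table. Identical config and seed give bit-identical
#' outputs; every output directory records the seed and a config hash.
#'
#' @param config configuration list from [pipeline_config()] or a YAML
#'   path.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages (written to standard error).
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "pipeline_out",
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  seed <- config$seed
  res <- list(config = config)

  writeLines(c(sprintf("seed: %s", seed),
               sprintf("config_md5: %s", .cfg_hash(config))),
             file.path(out_dir, "run_info.txt"))

  stage <- function(name, code) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    say("stage %s", name)
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s (prior outputs preserved in %s)",
            name, conditionMessage(e), out_dir))
  }

  # --- simulate ------------------------------------------------------------
  res$sim <- stage("simulate", {
    sc <- config$sim
    ped <- make_pedigree(n_offspring = sc$n_offspring, seed = seed)
    map <- make_snp_map(n_snps = sc$n_snps, n_chr = sc$n_chr, seed = seed + 1)
    geno <- gene_drop(ped, map, missing_rate = sc$missing_rate, seed = seed + 2)
    qtl <- NULL
    if (sc$qtl$n > 0) {
      # causal variants are planted at common, well-tagged loci (the
      # emulated QTL have intermediate MAF); when hidden, the causal SNP
      # itself is excluded from the analysis panel so it is detected
      # through linked markers, as with a causal variant absent from an
      # array
      frq <- colMeans(geno, na.rm = TRUE) / 2
      maf <- pmin(frq, 1 - frq)
      cand <- map$snp[maf >= (sc$qtl$min_maf %||% 0.35)]
      if (length(cand) < sc$qtl$n) cand <- map$snp
      qsnp <- with_seed(seed + 3, sample(cand, sc$qtl$n))
      pq <- frq[match(qsnp, map$snp)]
      # split the requested share of genetic variance equally over QTL
      share <- sc$qtl$pct_genetic / 100 * sc$var_u / sc$qtl$n
      a <- sqrt(share / (2 * pq * (1 - pq)))
      qtl <- data.frame(snp = qsnp, a = a, d = 0)
    }
    truth <- truth_record(var_u = sc$var_u * (1 - sc$qtl$pct_genetic / 100 * (sc$qtl$n > 0)),
                          var_dam = sc$var_dam, var_e = sc$var_e, qtl = qtl)
    groups <- paste0("G", seq_len(sc$n_groups))
    sim <- simulate_challenge(ped, geno, truth,
                              heating_curves = default_heating_curves(groups),
                              seed = seed + 4)
    write_pedigree(ped, file.path(out_dir, "pedigree.tsv"))
    write_snp_map(map, file.path(out_dir, "snp_map.tsv"))
    write_vcf(geno, map, file.path(out_dir, "genotypes.vcf"))
    write_phenotypes(sim$pheno, file.path(out_dir, "challenge_raw.tsv"))
    write_truth(truth, file.path(out_dir, "truth_components.tsv"),
                file.path(out_dir, "truth_qtl.tsv"))
    harvest <- NULL
    if (sc$n_harvest > 0) {
      hids <- with_seed(seed + 5,
                        sample(ped$id[ped$generation > 0], sc$n_harvest))
      harvest <- simulate_harvest(ped, geno, truth,
                                  n_violations = sc$n_violations,
                                  ids = hids, seed = seed + 6)
      write_phenotypes(harvest$pheno, file.path(out_dir, "harvest_raw.tsv"))
    }
    panel <- geno
    if (!is.null(qtl) && isTRUE(sc$qtl$hidden))
      panel <- geno[, setdiff(colnames(geno), qtl$snp), drop = FALSE]
    list(ped = ped, map = map, geno = geno, panel = panel, truth = truth,
         sim = sim, harvest = harvest)
  })

  # --- standardize ---------------------------------------------------------
  res$pheno <- stage("standardize", {
    ph <- standardize_rtle(res$sim$sim$pheno)
    ph <- cumulative_degrees(ph, res$sim$sim$heating_curves)
    write_phenotypes(ph, file.path(out_dir, "challenge_pheno.tsv"))
    harvest <- NULL
    if (!is.null(res$sim$harvest)) {
      hf <- derive_and_filter_harvest(res$sim$harvest$pheno)
      write_phenotypes(hf$table, file.path(out_dir, "harvest_pheno.tsv"))
      .write_tsv(hf$report, file.path(out_dir, "harvest_removals.tsv"))
      harvest <- hf
    }
    list(challenge = ph, harvest = harvest)
  })

  # --- qc ------------------------------------------------------------------
  res$qc <- stage("qc", {
    qi <- qc_individuals(res$sim$panel, config$qc$ind_min_call)
    qs <- qc_snps(qi$genotypes, config$qc$snp_min_call, config$qc$min_maf,
                  config$qc$min_hwe_p)
    write_qc_report(qs$report, file.path(out_dir, "qc_snps.tsv"))
    say("QC: %d individuals and %d SNPs removed",
        qi$report$n_removed, qs$report$n_removed)
    qs$genotypes
  })

  geno_qc <- res$qc %||% res$sim$panel

  # --- relmat --------------------------------------------------------------
  res$relmat <- stage("relmat", {
    A <- a_matrix(res$sim$ped)
    ids <- rownames(geno_qc)
    G <- g_matrix(geno_qc, blend_weight = config$relmat$blend_weight,
                  a_matrix = A)
    write_relmat(G, file.path(out_dir, "g_matrix.tsv"))
    list(A = A, G = G)
  })

  # --- reml ----------------------------------------------------------------
  res$reml <- stage("reml", {
    ph <- res$pheno$challenge
    fit_dam <- reml_fit(ph, "tle", res$relmat$G,
                        maxit = config$reml$maxit, tol = config$reml$tol)
    fit_nodam <- reml_fit(ph, "tle", res$relmat$G, dam_traits = character(0),
                          maxit = config$reml$maxit, tol = config$reml$tol)
    cmp <- aic_compare(fit_dam, fit_nodam)
    write_reml_report(fit_dam, file.path(out_dir, "reml_tle_dam.tsv"))
    write_reml_report(fit_nodam, file.path(out_dir, "reml_tle_nodam.tsv"))
    say("h2 = %.3f, dam ratio = %.3f, dam model %s by AIC",
        fit_dam$h2, fit_dam$dam_ratio,
        if (cmp$selected == 1) "selected" else "rejected")
    list(fit_dam = fit_dam, fit_nodam = fit_nodam, aic = cmp)
  })

  # --- gwas ----------------------------------------------------------------
  res$gwas <- stage("gwas", {
    gc <- config$gwas
    cfg <- gibbs_config(n_cycles = gc$n_cycles, burn_in = gc$burn_in,
                        thin = gc$thin, alpha = gc$alpha, beta = gc$beta,
                        h2_prior = gc$h2_prior, seed = seed + 10)
    fit <- bayescpi_fit(res$pheno$challenge, geno_qc, cfg, map = res$sim$map)
    write_gwas_result(fit, file.path(out_dir, "gwas_snps.tsv"))
    write_gebv(fit, file.path(out_dir, "gwas_gebv.tsv"))
    .write_tsv(fit$traces, file.path(out_dir, "gwas_trace.tsv"))
    fit
  })

  # --- callqtl -------------------------------------------------------------
  res$qtl <- stage("callqtl", {
    q <- call_qtl(res$gwas, config$qtl$peak_threshold,
                  config$qtl$support_threshold, config$qtl$window_bp)
    if (nrow(q)) q <- variance_explained(q, res$gwas, geno_qc)
    if (!is.null(config$annotation) && nrow(q))
      q <- annotate_regions(q, config$annotation)
    write_qtl_report(q, file.path(out_dir, "qtl_regions.tsv"))
    say("%d QTL called", nrow(q))
    q
  })

  # --- contrast ------------------------------------------------------------
  res$contrasts <- stage("contrast", {
    if (is.null(res$qtl) || !nrow(res$qtl)) {
      list()
    } else {
      cs <- lapply(res$qtl$peak_snp, function(s)
        peak_contrast(res$pheno$challenge, res$reml$fit_dam, geno_qc, s))
      write_contrast_report(cs, file.path(out_dir, "peak_contrasts.tsv"))
      cs
    }
  })

  # --- isocheck ------------------------------------------------------------
  res$isocheck <- stage("isocheck", {
    founders <- res$sim$ped$id[res$sim$ped$generation == 0]
    pair <- with_seed(seed + 20, sample(founders, 2))
    lines <- synthesize_isogenic_pair(res$sim$geno, pair[1], pair[2],
                                      res$sim$map, seed = seed + 21)
    rep <- isogenic_concordance(
      res$gwas,
      data.frame(snp = lines$snp, allele = lines$allele_a),
      data.frame(snp = lines$snp, allele = lines$allele_b),
      res$sim$map, config$isocheck$logbf_threshold)
    .write_tsv(as.data.frame(rep), file.path(out_dir, "isogenic_report.tsv"))
    rep
  })

  # --- summary -------------------------------------------------------------
  summ <- file.path(out_dir, "summary.txt")
  con <- file(summ, "w")
  sink(con)
  cat("troutherm pipeline summary\n")
  cat(sprintf("seed: %s  config_md5: %s\n\n", seed, .cfg_hash(config)))
  if (!is.null(res$pheno)) {
    cat("Descriptive statistics (rTLE):\n")
    d <- descriptives(res$pheno$challenge$rtle)
    cat(sprintf("  N %d  mean %.1f  SD %.1f  min %.1f  max %.1f  CV %.1f%%\n\n",
                d$n, d$mean, d$sd, d$min, d$max, d$cv))
  }
  if (!is.null(res$reml)) {
    cat("Variance components (TLE, genomic):\n")
    cat(sprintf("  h2 = %.3f (SE %.3f), dam ratio = %.3f (SE %.3f), AIC %.1f (dam) vs %.1f (no dam)\n\n",
                res$reml$fit_dam$h2, res$reml$fit_dam$h2_se,
                res$reml$fit_dam$dam_ratio, res$reml$fit_dam$dam_ratio_se,
                res$reml$fit_dam$AIC, res$reml$fit_nodam$AIC))
  }
  if (!is.null(res$qtl)) {
    cat("QTL regions:\n")
    print(as.data.frame(res$qtl), row.names = FALSE)
    cat("\n")
  }
  if (!is.null(res$contrasts) && length(res$contrasts)) {
    cat("Peak contrasts:\n")
    for (x in res$contrasts)
      cat(sprintf("  %s: diff %.0f%% of SD (favourable %s), Tukey p %.3g, dominance %.3f (p %.3g)\n",
                  x$snp, x$diff_pct_sd, x$favourable_homozygote, x$tukey_p,
                  x$dominance, x$dominance_p))
    cat("\n")
  }
  if (!is.null(res$isocheck)) {
    cat("Isogenic concordance:\n")
    print(as.data.frame(res$isocheck), row.names = FALSE)
  }
  sink()
  close(con)
  say("done; outputs in %s", out_dir)
  invisible(res)
}
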