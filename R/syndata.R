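# Synthetic study generator: factorial-mating pedigree, gene-drop genotypes,
# thermal-challenge and harvest phenotypes with a configurable variance
# structure, plus a truth record for recovery testing.

#' Build a factorial-mating pedigree
#'
#' Founders are grouped into independent mating blocks; within each block
#' every sire is mated to every dam (full factorial). The default block
#' structure emulates a commercial rainbow-trout mating design of 10 blocks
#' holding 9 or 10 sires and 7 or 8 dams, i.e. 99 sires and 76 dams in total.
#'
#' @param n_blocks number of independent mating blocks.
#' @param sires_per_block,dams_per_block integer vectors (recycled to
#'   `n_blocks`) giving the number of sires/dams per block.
#' @param offspring_per_pair number of offspring produced by every mated
#'   pair (ignored when `n_offspring` is given).
#' @param n_offspring optional total number of offspring; when given, each
#'   offspring is assigned to a mated pair drawn uniformly at random, which
#'   emulates survival thinning of a large egg pool.
#' @param seed optional integer seed; the global RNG stream is untouched.
#' @return a `data.frame` with columns `id`, `sire`, `dam` (NA for
#'   founders), `generation` (0 = founder) and `block`, ordered so parents
#'   precede offspring. The seed is recorded as an attribute.
#' @export
make_pedigree <- function(n_blocks = 10,
                          sires_per_block = c(rep(10L, 9), 9L),
                          dams_per_block = c(rep(8L, 6), rep(7L, 4)),
                          offspring_per_pair = 2L,
                          n_offspring = NULL,
                          seed = NULL) {
  if (n_blocks < 1) stopf("n_blocks must be >= 1")
  sires_per_block <- rep_len(as.integer(sires_per_block), n_blocks)
  dams_per_block <- rep_len(as.integer(dams_per_block), n_blocks)
  if (any(sires_per_block < 1) || any(dams_per_block < 1))
    stopf("sires_per_block and dams_per_block must all be >= 1")
  if (is.null(n_offspring) && offspring_per_pair < 1)
    stopf("offspring_per_pair must be >= 1")

  sire_ids <- sprintf("S%03d", seq_len(sum(sires_per_block)))
  dam_ids <- sprintf("D%03d", seq_len(sum(dams_per_block)))
  sire_block <- rep(seq_len(n_blocks), sires_per_block)
  dam_block <- rep(seq_len(n_blocks), dams_per_block)

  # all sire x dam pairs within each block
  pairs <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    expand.grid(sire = sire_ids[sire_block == b],
                dam = dam_ids[dam_block == b],
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))

  off <- with_seed(seed, {
    if (is.null(n_offspring)) {
      idx <- rep(seq_len(nrow(pairs)), each = offspring_per_pair)
    } else {
      if (n_offspring < 1) stopf("n_offspring must be >= 1")
      idx <- sample.int(nrow(pairs), n_offspring, replace = TRUE)
    }
    pairs[idx, , drop = FALSE]
  })

  founder <- data.frame(
    id = c(sire_ids, dam_ids),
    sire = NA_character_, dam = NA_character_,
    generation = 0L,
    block = c(sire_block, dam_block),
    stringsAsFactors = FALSE)
  prog <- data.frame(
    id = sprintf("F%05d", seq_len(nrow(off))),
    sire = off$sire, dam = off$dam,
    generation = 1L,
    block = sire_block[match(off$sire, sire_ids)],
    stringsAsFactors = FALSE)
  ped <- rbind(founder, prog)
  rownames(ped) <- NULL
  attr(ped, "seed") <- seed
  ped
}

#' Build a SNP map with founder allele frequencies
#'
#' @param n_snps number of SNPs.
#' @param n_chr number of chromosomes (named `"1"`, `"2"`, ...).
#' @param chr_length_bp chromosome length in bp.
#' @param maf_range founder minor-allele-frequency range for the simulated
#'   reference-allele frequencies.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `snp`, `chr`, `pos` (1-based bp,
#'   strictly increasing within chromosome), `ref`, `alt`, `freq` (founder
#'   reference-allele frequency).
#' @export
make_snp_map <- function(n_snps = 3000, n_chr = 10, chr_length_bp = 1.2e7,
                         maf_range = c(0.1, 0.5), seed = NULL) {
  if (n_snps < 1 || n_chr < 1) stopf("n_snps and n_chr must be >= 1")
  with_seed(seed, {
    chr <- sort(rep_len(seq_len(n_chr), n_snps))
    pos <- unlist(lapply(split(chr, chr), function(g) {
      sort(sample.int(chr_length_bp, length(g)))
    }), use.names = FALSE)
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    # reference allele is the minor or major allele at random
    flip <- runif(n_snps) < 0.5
    freq <- ifelse(flip, maf, 1 - maf)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(snp = sprintf("SNP%06d", seq_len(n_snps)),
               chr = as.character(chr), pos = pos, ref = ref, alt = unname(alt),
               freq = freq, stringsAsFactors = FALSE)
  })
}

#' Drop genes through a pedigree
#'
#' Phased haplotypes are tracked for every animal. Founder haplotypes are
#' drawn from a Gaussian-copula haplotype-block model: loci inside an
#' `ld_block_bp` window share a latent block factor, on which each SNP
#' loads with a squared loading drawn from `ld_rho_range`, so founder
#' linkage disequilibrium is strong but heterogeneous within a block and
#' absent between blocks -- a stylised version of the blocky LD of a
#' closed commercial line -- while marginal allele frequencies follow
#' `founder_freq`. Founder genotypes are the union of two independent
#' haplotypes and therefore sit at Hardy-Weinberg proportions. Each
#' offspring receives one recombined gamete per parent (crossovers
#' Poisson with mean `morgans_per_chr` per chromosome, uniform
#' positions), so offspring genotypes are Mendelian-consistent with the
#' parental gametes. Genotypes are coded as the count of the reference
#' allele (0/1/2). `ld_rho_range = c(0, 0)` gives founders at linkage
#' equilibrium (independent loci).
#'
#' @param pedigree pedigree `data.frame` ordered parents-before-offspring
#'   (as from [make_pedigree()]).
#' @param snp_map SNP map (as from [make_snp_map()]).
#' @param founder_freq reference-allele frequency per SNP (scalar or vector
#'   of length `nrow(snp_map)`); defaults to `snp_map$freq`.
#' @param missing_rate per-cell probability of a missing call in `[0, 1)`.
#' @param ld_block_bp haplotype-block length in bp.
#' @param ld_rho_range range of the squared latent loading of a SNP on its
#'   block factor (the latent correlation between two block mates is the
#'   product of their loadings).
#' @param morgans_per_chr expected number of crossovers per chromosome and
#'   meiosis.
#' @param seed optional integer seed.
#' @return integer matrix (individuals x SNPs) with `NA` for missing
#'   calls; the two phased haplotypes are attached as attributes `hap1`
#'   and `hap2` (0/1 matrices without missingness).
#' @export
gene_drop <- function(pedigree, snp_map, founder_freq = NULL,
                      missing_rate = 0, ld_block_bp = 1e6,
                      ld_rho_range = c(0.4, 0.95),
                      morgans_per_chr = 1, seed = NULL) {
  p <- nrow(snp_map)
  f <- founder_freq %||% snp_map$freq
  if (is.null(f)) stopf("founder_freq not given and snp_map has no freq column")
  f <- rep_len(f, p)
  if (any(f < 0 | f > 1)) stopf("founder allele frequencies must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")

  n <- nrow(pedigree)
  chrs <- unique(snp_map$chr)
  loci <- lapply(chrs, function(ch) which(snp_map$chr == ch))
  names(loci) <- chrs
  thr <- qnorm(f) # latent threshold giving P(allele = 1) = f

  with_seed(seed, {
    # every NA parent entry consumes one population gamete; founders
    # consume two. Drawn in one batch for vectorisation.
    n_hap <- sum(is.na(pedigree$sire)) + sum(is.na(pedigree$dam))

    # per-SNP block id and loading, drawn once per run
    block_id <- paste(snp_map$chr, (snp_map$pos - 1) %/% ld_block_bp)
    lam <- sqrt(runif(p, ld_rho_range[1], ld_rho_range[2]))
    blocks <- split(seq_len(p), block_id)

    draw_founder_haps <- function(m) {
      Z <- matrix(rnorm(m * p), m, p)
      if (max(ld_rho_range) > 0) {
        for (b in blocks) {
          u <- rnorm(m)
          Z[, b] <- u %o% lam[b] + Z[, b] * rep(sqrt(1 - lam[b]^2), each = m)
        }
      }
      (Z < matrix(thr, m, p, byrow = TRUE)) + 0L
    }

    founder_haps <- draw_founder_haps(max(n_hap, 2))
    hap_cursor <- 0
    founder_gamete <- function() {
      hap_cursor <<- hap_cursor + 1
      if (hap_cursor > nrow(founder_haps)) # more unknowns than pre-drawn
        founder_haps <<- rbind(founder_haps, draw_founder_haps(16))
      founder_haps[hap_cursor, ]
    }

    H1 <- matrix(0L, n, p, dimnames = list(pedigree$id, snp_map$snp))
    H2 <- H1
    row_of <- setNames(seq_len(n), pedigree$id)

    meiosis <- function(j) {
      # recombined gamete from individual in row j
      g <- integer(p)
      for (ch in chrs) {
        li <- loci[[ch]]
        pos <- snp_map$pos[li]
        n_x <- stats::rpois(1, morgans_per_chr)
        start <- sample.int(2L, 1)
        if (n_x == 0) {
          g[li] <- if (start == 1) H1[j, li] else H2[j, li]
        } else {
          bp <- sort(runif(n_x, 0, max(pos)))
          seg <- (start + findInterval(pos, bp)) %% 2L
          g[li] <- ifelse(seg == 1L, H1[j, li], H2[j, li])
        }
      }
      g
    }

    for (i in seq_len(n)) {
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      gam <- function(par) {
        if (is.na(par)) return(founder_gamete())
        j <- row_of[[par]]
        if (j >= i) stopf("pedigree not ordered parents-before-offspring at %s", pedigree$id[i])
        meiosis(j)
      }
      H1[i, ] <- gam(s)
      H2[i, ] <- gam(d)
    }

    geno <- H1 + H2
    storage.mode(geno) <- "integer"
    if (missing_rate > 0) {
      geno[matrix(runif(n * p) < missing_rate, n, p)] <- NA_integer_
    }
    attr(geno, "hap1") <- H1
    attr(geno, "hap2") <- H2
    attr(geno, "seed") <- seed
    geno
  })
}

#' Truth record for the simulators
#'
#' Bundles the generating values used by [simulate_challenge()] and
#' [simulate_harvest()]: variance components on the latent (unit phenotypic
#' variance) scale, fixed day effects, planted QTL, the secondary
#' body-weight trait, and the harvest-trait genetic covariance target.
#' Defaults are the study conditions this package emulates: heritability
#' 0.29 and maternal (dam) share 0.06 for the challenge trait, genetic
#' correlation -0.49 and phenotypic correlation -0.07 with juvenile body
#' weight.
#'
#' @param var_u,var_dam,var_e additive, dam and residual variances of the
#'   latent resistance (all >= 0).
#' @param day_effects optional named numeric vector of fixed group/day
#'   effects on the latent scale.
#' @param qtl optional `data.frame` with columns `snp`, `a` (additive
#'   effect of one reference-allele copy) and optionally `d` (dominance
#'   deviation of the heterozygote).
#' @param bw1 list describing the juvenile body-weight trait: `mean`, `sd`,
#'   `h2`, `rg_tle` (genetic correlation with latent resistance), `rp_tle`
#'   (phenotypic correlation).
#' @param harvest harvest-trait generating values, see
#'   [default_harvest_truth()].
#' @return object of class `truth_record`.
#' @export
truth_record <- function(var_u = 0.29, var_dam = 0.06, var_e = 0.65,
                         day_effects = NULL, qtl = NULL,
                         bw1 = list(mean = 87.4, sd = 12.2, h2 = 0.19,
                                    rg_tle = -0.49, rp_tle = -0.07),
                         harvest = default_harvest_truth()) {
  if (any(c(var_u, var_dam, var_e) < 0)) stopf("variance components must be >= 0")
  if (!is.null(qtl)) {
    if (!all(c("snp", "a") %in% names(qtl))) stopf("qtl needs columns snp and a")
    if (is.null(qtl$d)) qtl$d <- 0
  }
  structure(list(var_u = var_u, var_dam = var_dam, var_e = var_e,
                 day_effects = day_effects, qtl = qtl, bw1 = bw1,
                 harvest = harvest),
            class = "truth_record")
}

#' Default harvest-trait generating values
#'
#' Means, phenotypic SDs, heritabilities and genetic/phenotypic correlation
#' targets for body weight at harvest (BW2, g), fork length (FL, mm),
#' muscle fat content (Fat, %) and carcass yield (HGC, %), set to the
#' descriptive and genetic-parameter estimates of the emulated study.
#'
#' @return list with `traits`, `mu`, `sd`, `h2`, `rg` and `rp` (4 x 4
#'   correlation matrices).
#' @export
default_harvest_truth <- function() {
  traits <- c("bw2", "fl", "fat", "hgc")
  mu <- c(bw2 = 977.5, fl = 446.5, fat = 4.9, hgc = 78.7)
  sdv <- c(bw2 = 106.2, fl = 15.2, fat = 1.2, hgc = 1.0)
  h2 <- c(bw2 = 0.26, fl = 0.31, fat = 0.45, hgc = 0.61)
  rg <- diag(4); rp <- diag(4)
  dimnames(rg) <- dimnames(rp) <- list(traits, traits)
  rg["bw2", "fl"] <- rg["fl", "bw2"] <- 0.75
  rg["bw2", "fat"] <- rg["fat", "bw2"] <- -0.15
  rg["bw2", "hgc"] <- rg["hgc", "bw2"] <- 0.08
  rg["fl", "fat"] <- rg["fat", "fl"] <- -0.25
  rg["fl", "hgc"] <- rg["hgc", "fl"] <- 0.02
  rg["fat", "hgc"] <- rg["hgc", "fat"] <- 0.28
  rp["bw2", "fl"] <- rp["fl", "bw2"] <- 0.86
  rp["bw2", "fat"] <- rp["fat", "bw2"] <- 0.10
  rp["bw2", "hgc"] <- rp["hgc", "bw2"] <- 0.13
  rp["fl", "fat"] <- rp["fat", "fl"] <- 0.01
  rp["fl", "hgc"] <- rp["hgc", "fl"] <- 0.14
  rp["fat", "hgc"] <- rp["hgc", "fat"] <- 0.19
  list(traits = traits, mu = mu, sd = sdv, h2 = h2, rg = rg, rp = rp)
}

#' Piecewise-linear heating curve
#'
#' @param group group label.
#' @param t0 initial water temperature in deg C.
#' @param segments `data.frame` with columns `duration_h` and
#'   `rate_c_per_h`; the last segment may have infinite duration. Rates
#'   must be >= 0 so that temperature is non-decreasing.
#' @return object of class `heating_curve`.
#' @export
heating_curve <- function(group, t0 = 17.3,
                          segments = data.frame(duration_h = c(1.5, Inf),
                                                rate_c_per_h = c(3.1, 0.9))) {
  if (any(segments$rate_c_per_h < 0)) stopf("heating rates must be >= 0")
  if (any(segments$duration_h <= 0)) stopf("segment durations must be > 0")
  structure(list(group = group, t0 = t0, segments = segments),
            class = "heating_curve")
}

#' Temperature of a heating curve at given times
#'
#' @param curve a [heating_curve()].
#' @param t_min time(s) since challenge start, minutes.
#' @return temperature(s) in deg C.
#' @export
temp_at <- function(curve, t_min) {
  if (any(t_min < 0)) stopf("time must be >= 0")
  dur <- curve$segments$duration_h * 60
  rate <- curve$segments$rate_c_per_h / 60
  bounds <- cumsum(dur)
  base <- curve$t0 + cumsum(c(0, head(rate * dur, -1)))
  out <- numeric(length(t_min))
  for (k in seq_along(dur)) {
    lo <- if (k == 1) 0 else bounds[k - 1]
    inseg <- t_min > lo | (k == 1 & t_min == 0)
    inseg <- inseg & (t_min <= bounds[k])
    out[inseg] <- base[k] + rate[k] * (t_min[inseg] - lo)
  }
  beyond <- t_min > bounds[length(bounds)]
  if (any(beyond)) stopf("heating curve ends before requested time")
  out
}

#' Default heating curves per group (initial temperatures as observed in
#' the emulated challenge: mean 17.3 deg C, coolest start for the last
#' group, warmest for group 4).
#'
#' @param groups group labels.
#' @return named list of [heating_curve()] objects.
#' @export
default_heating_curves <- function(groups = paste0("G", 1:7)) {
  t0 <- if (length(groups) == 7) {
    c(17.5, 17.4, 17.2, 18.4, 17.3, 17.1, 16.1)
  } else {
    rep(17.3, length(groups))
  }
  setNames(lapply(seq_along(groups), function(i) heating_curve(groups[i], t0[i])),
           groups)
}

#' Default group time scales for the latent-to-time map (per-group mean and
#' SD of raw time to loss of equilibrium, minutes); for seven groups these
#' follow the printed group summaries of the emulated challenge.
#'
#' @param groups group labels.
#' @return `data.frame` with columns `group`, `mean_min`, `sd_min`.
#' @export
default_group_times <- function(groups = paste0("G", 1:7)) {
  if (length(groups) == 7) {
    data.frame(group = groups,
               mean_min = c(318.7, 394.9, 424.8, 424.9, 446.8, 407.4, 473.8),
               sd_min = c(14.1, 23.2, 24.4, 34.2, 34.0, 30.3, 61.6),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = groups, mean_min = 412, sd_min = 35,
               stringsAsFactors = FALSE)
  }
}

# shared helper: multivariate marker effects giving target additive
# (co)variance sum(2 p q) * Sigma_alpha = Sigma_g, using observed freqs
.marker_effects <- function(geno, Sigma_g, exclude = character(0)) {
  use <- setdiff(colnames(geno), exclude)
  Z <- geno[, use, drop = FALSE]
  pfreq <- colMeans(Z, na.rm = TRUE) / 2
  denom <- 2 * sum(pfreq * (1 - pfreq))
  if (denom <= 0) stopf("no polymorphic SNPs available for polygenic effects")
  k <- nrow(Sigma_g)
  L <- chol(Sigma_g / denom + diag(1e-12, k))
  alpha <- matrix(rnorm(length(use) * k), length(use), k) %*% L
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  u <- Zc %*% alpha
  list(u = u, alpha = alpha, snps = use)
}

#' Simulate a thermal-challenge phenotype table
#'
#' Latent resistance is decomposed as overall mean + fixed day effect +
#' IID dam effect + planted QTL effects + polygenic effect + residual.
#' The polygenic term is generated as a sum of many small marker effects on
#' the non-QTL SNPs so that the simulated genome is the single source of
#' genetic truth. Raw time to loss of equilibrium is a per-group monotone
#' (affine) map of latent resistance onto the group's time scale, so fish
#' lose equilibrium in latent order and within-group standardisation
#' recovers the latent decomposition. Juvenile body weight is generated
#' jointly with the configured genetic and phenotypic correlations.
#'
#' @param pedigree pedigree `data.frame`.
#' @param genotypes genotype matrix from [gene_drop()] (no missing values
#'   needed; missing calls are mean-imputed for effect computation).
#' @param truth a [truth_record()].
#' @param heating_curves named list of [heating_curve()]s, one per group.
#' @param group_assignment optional named vector mapping fish id to group;
#'   defaults to a balanced random assignment over the heating-curve groups.
#' @param group_times optional `data.frame(group, mean_min, sd_min)` giving
#'   the per-group time scale; defaults to [default_group_times()].
#' @param ids fish to phenotype; defaults to all non-founders.
#' @param seed optional integer seed.
#' @return list of class `challenge_sim` with elements `pheno` (columns
#'   `id`, `group`, `rtle`, `bw1`, `dam`, `sire`), `components` (per-fish
#'   latent decomposition: `u`, `qtl`, `dam_eff`, `resid`, `tbv`),
#'   `heating_curves`, `truth` and `seed`.
#' @export
simulate_challenge <- function(pedigree, genotypes, truth = truth_record(),
                               heating_curves = default_heating_curves(),
                               group_assignment = NULL, group_times = NULL,
                               ids = NULL, seed = NULL) {
  ids <- ids %||% pedigree$id[pedigree$generation > 0]
  ids <- intersect(ids, rownames(genotypes))
  if (length(ids) < 2) stopf("need at least two phenotyped fish")
  ped <- pedigree[match(ids, pedigree$id), ]
  groups <- names(heating_curves)
  if (is.null(groups)) stopf("heating_curves must be a named list")
  gt <- group_times %||% default_group_times(groups)

  with_seed(seed, {
    grp <- group_assignment %||%
      setNames(sample(rep_len(groups, length(ids))), ids)
    grp <- grp[ids]
    if (any(!grp %in% groups)) stopf("missing heating curve for group(s): %s",
                                     paste(unique(grp[!grp %in% groups]), collapse = ", "))

    G <- genotypes[ids, , drop = FALSE]
    if (anyNA(G)) { # mean-impute for effect computation
      mu_g <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G), arr.ind = TRUE)
      G[idx] <- mu_g[idx[, 2]]
    }

    qtl <- truth$qtl
    qtl_snps <- if (is.null(qtl)) character(0) else qtl$snp
    # bivariate polygenic effects: latent resistance + body weight
    var_u2 <- truth$bw1$h2 * truth$bw1$sd^2
    cov_g <- truth$bw1$rg_tle * sqrt(truth$var_u * var_u2)
    Sg <- matrix(c(truth$var_u, cov_g, cov_g, var_u2), 2)
    if (truth$var_u > 0 || var_u2 > 0) {
      me <- .marker_effects(G, Sg, exclude = qtl_snps)
      u <- me$u[, 1]; u_bw <- me$u[, 2]
      if (truth$var_u == 0) u <- numeric(length(ids))
      if (var_u2 == 0) u_bw <- numeric(length(ids))
    } else {
      u <- u_bw <- numeric(length(ids))
    }

    qtl_gv <- numeric(length(ids))
    qtl_add <- numeric(length(ids))
    if (!is.null(qtl)) {
      for (r in seq_len(nrow(qtl))) {
        z <- G[, qtl$snp[r]]
        qtl_add <- qtl_add + qtl$a[r] * (z - mean(z))
        qtl_gv <- qtl_gv + qtl$a[r] * (z - mean(z)) + qtl$d[r] * (z == 1)
      }
    }

    dams <- unique(ped$dam)
    dam_eff <- setNames(rnorm(length(dams), 0, sqrt(truth$var_dam)), dams)
    dam_v <- ifelse(is.na(ped$dam), 0, dam_eff[ped$dam])

    day_eff <- truth$day_effects %||% setNames(rep(0, length(groups)), groups)
    day_v <- day_eff[grp]

    e <- rnorm(length(ids), 0, sqrt(truth$var_e))
    latent <- day_v + dam_v + qtl_gv + u + e

    # residual correlation for body weight given phenotypic target
    cov_p <- truth$bw1$rp_tle * 1 * truth$bw1$sd
    cov_e <- cov_p - cov_g
    var_e2 <- (1 - truth$bw1$h2) * truth$bw1$sd^2
    var_e1 <- truth$var_e + truth$var_dam # non-genetic variance of latent
    b <- if (var_e1 > 0) cov_e / var_e1 else 0
    resid2_sd <- sqrt(max(var_e2 - b^2 * var_e1, 1e-8))
    bw1 <- truth$bw1$mean + u_bw + b * (dam_v + e) + rnorm(length(ids), 0, resid2_sd)

    gtm <- gt[match(grp, gt$group), ]
    rtle <- pmax(gtm$mean_min + gtm$sd_min * (latent - day_v), 1)

    pheno <- data.frame(id = ids, group = unname(grp), rtle = unname(rtle),
                        bw1 = unname(bw1), dam = ped$dam, sire = ped$sire,
                        stringsAsFactors = FALSE)
    comp <- data.frame(id = ids, u = unname(u), qtl = unname(qtl_gv),
                       qtl_add = unname(qtl_add),
                       dam_eff = unname(dam_v), resid = unname(e),
                       tbv = unname(u + qtl_add), stringsAsFactors = FALSE)
    structure(list(pheno = pheno, components = comp,
                   heating_curves = heating_curves, group_times = gt,
                   truth = truth, seed = seed),
              class = "challenge_sim")
  })
}

#' Simulate a harvest phenotype table with planted weight-sum violations
#'
#' Body weight (BW2), fork length, two fat-meter measurements, head weight,
#' headless gutted carcass weight and viscera weight are generated with the
#' configured genetic covariance structure (polygenic marker effects plus
#' correlated residuals). Component weights of non-violating records sum to
#' within 3 g of BW2; exactly `n_violations` records receive a planted
#' discrepancy larger than 10 g, for exercising the downstream consistency
#' filter.
#'
#' @param pedigree pedigree `data.frame`.
#' @param genotypes genotype matrix.
#' @param truth a [truth_record()]; the `harvest` element supplies the trait
#'   targets (see [default_harvest_truth()]).
#' @param n_violations number of records with a planted weight-sum
#'   discrepancy (> 10 g).
#' @param n_days number of slaughter days (fixed effect levels).
#' @param ids fish to phenotype; defaults to all non-founders.
#' @param seed optional integer seed.
#' @return list of class `harvest_sim` with elements `pheno` (columns `id`,
#'   `slaughter_day`, `bw2`, `fl`, `fat_ant`, `fat_post`, `headw`, `hgcw`,
#'   `viscw`, `dam`), `violations` (planted ids), `components` (additive
#'   values per trait) and `seed`.
#' @export
simulate_harvest <- function(pedigree, genotypes, truth = truth_record(),
                             n_violations = 24, n_days = 3, ids = NULL,
                             seed = NULL) {
  hv <- truth$harvest
  ids <- ids %||% pedigree$id[pedigree$generation > 0]
  ids <- intersect(ids, rownames(genotypes))
  n <- length(ids)
  if (n_violations > n) stopf("n_violations exceeds the number of fish")
  ped <- pedigree[match(ids, pedigree$id), ]

  Sg <- diag(sqrt(hv$h2) * hv$sd) %*% hv$rg %*% diag(sqrt(hv$h2) * hv$sd)
  Sp <- diag(hv$sd) %*% hv$rp %*% diag(hv$sd)
  Se <- Sp - Sg
  dimnames(Sg) <- dimnames(Se) <- list(hv$traits, hv$traits)
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stopf("genetic covariance target is not positive semi-definite (min eigenvalue %.3g)", min(ev))
  ev_e <- eigen(Se, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_e) < -1e-8 * max(ev_e))
    stopf("implied residual covariance is not positive semi-definite; lower the genetic correlations")

  with_seed(seed, {
    G <- genotypes[ids, , drop = FALSE]
    if (anyNA(G)) {
      mu_g <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G), arr.ind = TRUE)
      G[idx] <- mu_g[idx[, 2]]
    }
    me <- .marker_effects(G, Sg)
    E <- matrix(rnorm(n * 4), n, 4) %*% chol(Se + diag(1e-10, 4))
    vals <- sweep(me$u + E, 2, hv$mu, `+`)
    colnames(vals) <- hv$traits

    bw2 <- pmax(vals[, "bw2"], 200)
    fl <- pmax(vals[, "fl"], 200)
    fat <- pmax(vals[, "fat"], 0.5)
    hgc_frac <- pmin(pmax(vals[, "hgc"] / 100, 0.5), 0.95)

    hgcw <- bw2 * hgc_frac
    headw <- bw2 * (0.115 + rnorm(n, 0, 0.008))
    viscw <- pmax(bw2 - hgcw - headw + runif(n, -3, 3), 1)
    # re-balance so parts always sum within 3 g even after the floor
    fat_ant <- fat + rnorm(n, 0, 0.35)
    fat_post <- fat + rnorm(n, 0, 0.35)

    viol <- sample(ids, n_violations)
    vi <- match(viol, ids)
    # the planted shift must exceed the threshold even after the up-to-3-g
    # baseline slack of non-violating records partially cancels it
    shift <- (13.5 + rexp(n_violations, 1 / 15)) * sample(c(-1, 1), n_violations, replace = TRUE)
    hgcw[vi] <- pmax(hgcw[vi] + shift, 1)

    pheno <- data.frame(
      id = ids,
      slaughter_day = paste0("D", rep_len(seq_len(n_days), n)[sample.int(n)]),
      bw2 = bw2, fl = fl, fat_ant = fat_ant, fat_post = fat_post,
      headw = headw, hgcw = hgcw, viscw = viscw,
      dam = ped$dam, stringsAsFactors = FALSE)
    comp <- data.frame(id = ids, me$u, stringsAsFactors = FALSE)
    names(comp) <- c("id", paste0("u_", hv$traits))
    structure(list(pheno = pheno, violations = viol, components = comp,
                   truth = truth, seed = seed),
              class = "harvest_sim")
  })
}

#' Construct a synthetic isogenic line pair from two founders
#'
#' Takes two founder genotypes and homozygoses every locus (heterozygous
#' calls are resolved to one allele at random), yielding two fully
#' homozygous line genomes for concordance checking. The lines are
#' synthetic stand-ins for sequenced isogenic lines.
#'
#' @param genotypes genotype matrix containing the two founders.
#' @param founder_a,founder_b row names of the two founders (sensitive and
#'   resistant line ancestors).
#' @param snp_map SNP map supplying ref/alt alleles.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `snp`, `allele_a`, `allele_b` (one
#'   base each).
#' @export
synthesize_isogenic_pair <- function(genotypes, founder_a, founder_b, snp_map,
                                     seed = NULL) {
  with_seed(seed, {
    hom <- function(id) {
      g <- genotypes[id, snp_map$snp]
      g[is.na(g)] <- 1L
      pick_ref <- g == 2L | (g == 1L & runif(length(g)) < 0.5)
      ifelse(pick_ref, snp_map$ref, snp_map$alt)
    }
    data.frame(snp = snp_map$snp,
               allele_a = unname(hom(founder_a)),
               allele_b = unname(hom(founder_b)),
               stringsAsFactors = FALSE)
  })
}
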