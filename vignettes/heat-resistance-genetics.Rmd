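---
title: "Modelling the genetic architecture of acute hyperthermia resistance"
author: "troutherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the genetic architecture of acute hyperthermia resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When water temperature rises quickly, a rainbow trout eventually loses
equilibrium; the time from the start of the heating challenge to that
moment (rTLE, minutes) is a heritable measure of acute hyperthermia
resistance. `troutherm` re-implements, as a tested pipeline over
synthetic data, the full analysis used to characterise the genetic
architecture of this trait in a commercial line: phenotype
standardisation, genotype QC, pedigree and genomic relationship
matrices, REML variance components, a BayesC-pi genome-wide association
study with Bayes-factor QTL calling, genotype contrasts at peak SNPs,
and a concordance check against isogenic-line genomes. The raw data of
the motivating study are not public, so the package ships a
synthetic-data generator whose defaults reproduce the study's design
and published parameter estimates; every analysis step is then tested
by parameter recovery against that generator's truth records.

## The model

All genetic analyses are built on the maternal-effect animal model

$$y_{ijk} = \mu + day_i + dam_j + u_{ijk} + \varepsilon_{ijk},$$

where $y$ is the standardised resistance phenotype (TLE), $day_i$ a
fixed effect of the challenge day/group, $dam_j$ an IID random
common-environment effect of the dam, $u$ an additive genetic effect
with $\mathrm{Var}(u) = \sigma_u^2 K$ for a pedigree ($A$) or genomic
($G$) relationship matrix $K$, and $\varepsilon$ an IID residual.
Heritability is $h^2 = \sigma_u^2/\sigma_p^2$ and the dam share
$\sigma_{dam}^2/\sigma_p^2$ with
$\sigma_p^2 = \sigma_u^2 + \sigma_{dam}^2 + \sigma_\varepsilon^2$.

The GWAS replaces the polygenic term by an explicit sum over SNPs with
a spike-and-slab mixture,

$$TLE_{ijk} = \mu + day_i + dam_j + \sum_{l} \delta_{l} z_{kl} a_l
 + \varepsilon_{ijk},$$

with $z_{kl} \in \{0,1,2\}$ the reference-allele count, $\delta_l = 1$
with probability $\pi$ and $a_l \sim N(0, \sigma_a^2)$ when included.
Evidence per SNP is the Bayes factor comparing posterior to prior
inclusion odds, reported as $\mathrm{logBF} = 2\ln BF$ with thresholds
6 (peak) and 3 (support).

## What the generator emulates

* **Mating design.** Ten independent full-factorial blocks of 9-10
  sires by 7-8 dams (99 sires, 76 dams), with offspring either a fixed
  number per pair or a total allocated at random across pairs
  (survival thinning).
* **Genomes.** Founder haplotypes come from a Gaussian-copula
  haplotype-block model: loci within a 1-Mb block share a latent
  factor with per-SNP squared loadings drawn from $U(0.4, 0.95)$.
  This produces strong but heterogeneous within-block LD and none
  between blocks -- a deliberately stylised version of the blocky LD
  of a closed commercial line. Meioses recombine (Poisson crossovers,
  one expected per chromosome), so family co-segregation adds the
  usual long-range within-family disequilibrium. The desk-scale map
  (3,000 SNPs on 10 chromosomes of 12 Mb, ~40 kb spacing) is chosen so
  that the 200-kb support window of the QTL-calling rule contains
  several markers, as it does on the high-density imputed array the
  rule was designed for; array-scale maps are a configuration, not the
  default.
* **Challenge phenotypes.** Latent resistance is day effect + dam
  effect + planted QTL effects + polygenic effect + residual. The
  polygenic term is a sum of small effects on the non-QTL markers, so
  that REML and the Bayesian sampler see one consistent genome rather
  than two parallel genetic truths. The latent value is mapped onto
  each group's time scale by a per-group affine (hence monotone) map
  whose defaults follow the printed group means and SDs of the
  emulated challenge; an affine map keeps the configured variance
  fractions exactly recoverable after within-group standardisation,
  which is the property the tests rely on. Cumulative degree-minutes
  remain a strictly monotone transform of rTLE within a group, as in
  the study's heating profile (+3.1 degrees C/h for 1.5 h, then +0.9).
* **Causal variants for power studies.** A planted QTL placed *on* a
  genotyped SNP makes that SNP the unique best predictor, and the
  sampler's winner-takes-all inclusion leaves its neighbours empty --
  the singleton-artifact rule would then discard a true QTL. Power
  experiments therefore plant the causal variant at a simulated locus
  that is excluded from the analysis panel, so it is detected through
  linked markers, as a causal variant absent from an array would be.
  Causal loci are chosen at intermediate frequency (MAF >= 0.35),
  matching the reported QTL (MAF 0.21-0.46); rare causal variants are
  poorly tagged under any LD model and are not the regime the study's
  QTL represent.
* **Harvest traits.** Body weight, fork length, fat content and
  carcass yield are generated with the published heritabilities and
  genetic/phenotypic correlation targets via multivariate marker
  effects plus correlated residuals; component weights sum to body
  weight within 3 g except for a configurable number of planted
  violations (> 10 g), which the 10-g consistency filter must remove
  exactly.

What the generator does **not** emulate: genotyping-cluster artifacts
(the motivating study's chromosome-30 exclusion is exercised on a toy
map instead), recombination hotspots and sex chromosomes, genotype
errors beyond missingness, water-chemistry covariates, and the
acclimation-day confound beyond day effects -- the study itself could
not separate acclimation from heating-curve differences, so the
generator makes no attempt to.

## Estimation choices

* **REML.** One generic linear-covariance AI-REML engine
  ($V = \sum_i \theta_i V_i$) serves univariate and bivariate fits.
  Average-information steps are accepted only if the restricted
  log-likelihood does not decrease, with step halving and an EM-like
  scaled-gradient fallback otherwise; variances are floored at
  $10^{-8}\sigma_p^2$ and flagged when they end at the floor.
  Convergence is a relative parameter change below $10^{-8}$.
  Standard errors come from the inverse average-information matrix;
  ratios ($h^2$, dam share, $r_g$) use the first-order delta method.
  For trait pairs measured on disjoint animals (juvenile challenge vs
  harvest batch) the residual covariance is structurally zero and the
  parameter is dropped; for co-measured pairs it is estimated.
* **Dam term.** Fitted as IID common environment, not
  maternal-genetic, and by default only for the resistance trait --
  the AIC comparison (penalty 2 per variance parameter, ties to the
  simpler model) is exposed so that choice can be re-derived per
  dataset.
* **BayesC-pi.** Single-site Gibbs updates with the SNP visiting
  order fixed per run; $\pi$ is resampled from
  $\mathrm{Beta}(\alpha + m,\ (\beta-\alpha) + (p - m))$ given $m$
  included SNPs, i.e. a $\mathrm{Beta}(\alpha, \beta-\alpha)$ prior
  whose defaults scale the 400-in-420,079 expectation down to the
  panel. Variances carry scaled inverse chi-square priors with 4
  degrees of freedom. The SNP-effect scale spreads a prior
  heritability guess of 0.3 over an assumed architecture of ~400
  effect loci -- a property of the trait, deliberately *not* scaled
  down with panel size: concentrating the genetic variance prior on a
  handful of SNPs makes the effect prior so diffuse that
  chance-correlated SNPs reach logBF >= 6 on null data, destroying the
  calibration the evidence thresholds rely on. With the
  architecture-scaled prior, pure-noise phenotypes produce no SNPs
  above the evidence threshold while a planted QTL is still picked up
  immediately (its conditional effect variance then adapts upward
  through the inverse chi-square update). The Bayes-factor
  denominator uses the posterior mean of
  $\pi$ (a prior-$\pi$ mode is available); inclusion probabilities
  are clamped to $[1/n_{saved}, 1 - 1/n_{saved}]$ so logBF stays
  finite. Desk-scale chains run 20,000 cycles (2,000 burn-in, thin
  10); convergence is declared when two differently seeded chains
  give breeding values with $r > 0.99$.
* **QTL calling.** The "200 kb sliding window on both sides" rule is
  implemented as boundary chaining: any supporting SNP
  (logBF >= 3) within 200 kb of the current interval boundary extends
  it. Chaining reproduces both the published contiguous intervals and
  the singleton-artifact exclusion; a strict fixed-window variant is
  selectable. The denominator of "percent of genetic variance" is the
  empirical variance of the sampler's own GEBVs, which keeps peak and
  region shares on one scale; the region share uses the variance of
  the summed regional genomic value and is therefore LD-aware.
* **Peak contrasts.** "Corrected for dam and day" subtracts the null
  model's day BLUEs and dam BLUPs; the SNP is not co-fitted. For the
  dominance effect (heterozygote mean minus the homozygote midpoint),
  a one-sample t-test against the *observed* midpoint treats an
  estimated quantity as a known constant and rejects far above the
  nominal rate on purely additive loci (about 17% at 5% nominal in
  our calibration runs, because the midpoint's sampling variance is
  comparable to the heterozygote mean's). The default test therefore
  uses a z statistic whose standard error combines the heterozygote
  mean's variance with a quarter of each homozygote mean's variance,
  which restores the nominal size; the naive midpoint t-test remains
  available as `dominance_test = "midpoint-t"` for comparability.

## Problem sizes and tolerances

Recovery experiments run at n = 600-1,000 offspring, 1,200-3,000 SNPs
and 20 replicates; at these sizes the Monte-Carlo standard error of a
20-replicate mean heritability is about 0.025, well inside the +-0.05
band used for the recovery checks, and a single REML fit or 8,000-cycle
sampler run takes seconds. These sizes are the package's desk-scale
defaults for a reproducible test suite; nothing in the methods depends
on them, and array-scale settings are plain configuration.

## Known limitations

The LD model is blocky by construction, so LD decay *within* a block is
flat rather than distance-dependent; credibility-interval widths should
not be over-interpreted on synthetic data. The informative
$\mathrm{Beta}(\alpha, \beta - \alpha)$ prior keeps the posterior $\pi$
near the prior rate unless the data insist otherwise, which mirrors the
referenced software but means "posterior mean inclusion count" and
"$\pi \times p$" agree only approximately. Bivariate AI-REML with a
near-singular genetic covariance (|r_g| -> 1) is bounded away from the
boundary at 0.999 rather than reparameterised. The generator's truth
records make recovery tests possible but say nothing about model
misspecification on real data (non-Gaussian residuals, genotype x
environment, maternal-genetic rather than common-environment dam
effects).
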