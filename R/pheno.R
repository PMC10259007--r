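# Phenotype construction: within-group standardisation of time to loss of
# equilibrium, cumulative degree-minutes, harvest trait derivation with the
# 10-g weight-sum consistency filter, and descriptive statistics.

#' Standardise raw time to loss of equilibrium within groups
#'
#' Centres raw time to loss of equilibrium (rTLE) to mean 0 and scales it to
#' sample standard deviation 1 (denominator n - 1) within each phenotyping
#' group/day, producing the unitless TLE phenotype used by all downstream
#' genetic analyses.
#'
#' @param table `data.frame` with at least columns `rtle` and `group`.
#' @param rtle_col,group_col column names holding the raw time and group.
#' @return the input table with an added `tle` column.
#' @export
standardize_rtle <- function(table, rtle_col = "rtle", group_col = "group") {
  x <- table[[rtle_col]]
  g <- table[[group_col]]
  if (is.null(x) || is.null(g)) stopf("columns '%s' and '%s' are required", rtle_col, group_col)
  if (any(!is.finite(x))) stopf("non-finite rTLE values present")
  if (any(is.na(g))) stopf("every fish needs a group label")
  sizes <- table(g)
  if (any(sizes < 2))
    stopf("group(s) with a single fish (SD undefined): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  tle <- x
  for (gr in names(sizes)) {
    i <- g == gr
    tle[i] <- (x[i] - mean(x[i])) / sd(x[i])
  }
  table$tle <- tle
  table
}

#' Cumulative degree-minutes up to loss of equilibrium
#'
#' For each fish, sums the excess of water temperature over the initial
#' temperature at every whole minute of the challenge (t = 1, 2, ...,
#' floor(rTLE)): CTU = sum_t (T(t) - T(0)). A strictly monotone transform
#' of rTLE within a group.
#'
#' @param table `data.frame` with columns `rtle` and `group`.
#' @param heating_curves named list of [heating_curve()]s keyed by group.
#' @return the table with an added `ctu` column (degree-minutes).
#' @export
cumulative_degrees <- function(table, heating_curves) {
  ctu <- numeric(nrow(table))
  for (gr in unique(table$group)) {
    curve <- heating_curves[[gr]]
    if (is.null(curve)) stopf("no heating curve for group %s", gr)
    i <- which(table$group == gr)
    tmax <- floor(max(table$rtle[i]))
    temps <- if (tmax >= 1) temp_at(curve, seq_len(tmax)) else numeric(0)
    excess <- cumsum(temps - curve$t0)
    m <- floor(table$rtle[i])
    ctu[i] <- ifelse(m >= 1, excess[pmax(m, 1)], 0)
  }
  table$ctu <- ctu
  table
}

#' Derive harvest yields and apply the weight-sum consistency filter
#'
#' Computes carcass yield HGC% = HGCW / BW2 x 100 and fillet fat content as
#' the mean of the anterior and posterior fat-meter measurements, then
#' removes records whose component weights are inconsistent with body
#' weight: |BW2 - (HGCW + HeadW + ViscW)| > `threshold_g`.
#'
#' @param table harvest `data.frame` with columns `bw2`, `hgcw`, `headw`,
#'   `viscw`, `fat_ant`, `fat_post` and `id`.
#' @param threshold_g consistency threshold in grams.
#' @return list with `table` (surviving records, with `hgc_pct` and
#'   `fat_pct` added), `removed` (ids) and `report` (`data.frame` of id,
#'   reason, discrepancy in g).
#' @export
derive_and_filter_harvest <- function(table, threshold_g = 10) {
  need <- c("id", "bw2", "hgcw", "headw", "viscw", "fat_ant", "fat_post")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(table$bw2 == 0)) stopf("BW2 of zero encountered")
  if (any(c(table$hgcw, table$headw, table$viscw) < 0))
    stopf("component weights must be non-negative")
  table$hgc_pct <- table$hgcw / table$bw2 * 100
  table$fat_pct <- (table$fat_ant + table$fat_post) / 2
  disc <- table$bw2 - (table$hgcw + table$headw + table$viscw)
  bad <- abs(disc) > threshold_g
  report <- data.frame(id = table$id[bad],
                       reason = "weight_sum_inconsistency",
                       discrepancy_g = disc[bad],
                       stringsAsFactors = FALSE)
  list(table = table[!bad, , drop = FALSE],
       removed = table$id[bad],
       report = report)
}

#' Descriptive statistics with coefficient of variation
#'
#' Computes N, mean, SD, min, max and CV (= SD / mean x 100) of a numeric
#' vector. When per-group summaries are supplied instead (or additionally),
#' also returns the N-weighted pooled mean and the pooled SD combining
#' within- and between-group variation.
#'
#' @param x numeric vector (optional if `group_stats` given).
#' @param group_stats optional `data.frame` with columns `mean`, `sd`, `n`
#'   holding per-group summaries.
#' @return named list: `n`, `mean`, `sd`, `min`, `max`, `cv`, and (when
#'   `group_stats` is given) `pooled_mean`, `pooled_sd`, `pooled_n`.
#' @export
descriptives <- function(x = NULL, group_stats = NULL) {
  out <- list()
  if (!is.null(x)) {
    x <- x[is.finite(x)]
    if (!length(x)) stopf("need at least one finite value")
    m <- mean(x)
    s <- if (length(x) > 1) sd(x) else 0
    if (m == 0) stopf("CV undefined: mean is zero")
    out <- list(n = length(x), mean = m, sd = s, min = min(x), max = max(x),
                cv = s / m * 100)
  }
  if (!is.null(group_stats)) {
    gm <- group_stats$mean; gs <- group_stats$sd; gn <- group_stats$n
    N <- sum(gn)
    pm <- sum(gm * gn) / N
    pv <- (sum((gn - 1) * gs^2) + sum(gn * (gm - pm)^2)) / (N - 1)
    out$pooled_mean <- pm
    out$pooled_sd <- sqrt(pv)
    out$pooled_n <- N
  }
  out
}

#' Coefficient of variation
#'
#' @param mean,sd summary statistics (mean must be non-zero).
#' @return SD / mean x 100.
#' @export
cv_pct <- function(mean, sd) {
  if (any(mean == 0)) stopf("CV undefined: mean is zero")
  sd / mean * 100
}
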