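# QTL calling from per-SNP logBF: peak detection with a singleton-artifact
# filter, credibility intervals by boundary chaining of supporting SNPs,
# variance-explained summaries and gene annotation of QTL regions.

#' Call QTL regions from a GWAS result
#'
#' Peaks are SNPs whose logBF reaches `peak_threshold` (default 6, strong
#' evidence). A peak with no other SNP reaching `support_threshold`
#' (default 3) within `window_bp` is discarded as a genotyping artifact
#' (the singleton rule). The credibility interval around a retained peak
#' grows by chaining: any supporting SNP within `window_bp` of the current
#' boundary extends the boundary, until a window contains none. Overlapping
#' intervals on a chromosome are merged under the higher peak. A strict
#' fixed-window alternative (`method = "fixed"`) bounds the interval by the
#' supporting SNPs within one window of the peak itself.
#'
#' @param gwas_result a `gwas_result` whose `snps` table carries `chr`,
#'   `pos` and `logbf` (fit with a `map`).
#' @param peak_threshold minimum logBF at the peak SNP.
#' @param support_threshold minimum logBF for supporting/interval SNPs.
#' @param window_bp window size in bp on each side.
#' @param method interval construction rule, `"chain"` (default) or
#'   `"fixed"`.
#' @return `data.frame` of class `qtl_regions`, one row per QTL: `name`,
#'   `chr`, `peak_snp`, `peak_pos`, `peak_logbf`, `start`, `end`,
#'   `n_snps` (mapped SNPs inside the interval). Discarded singleton peaks
#'   are reported in the `artifacts` attribute.
#' @export
call_qtl <- function(gwas_result, peak_threshold = 6, support_threshold = 3,
                     window_bp = 200000, method = c("chain", "fixed")) {
  method <- match.arg(method)
  snps <- gwas_result$snps
  if (is.null(snps$chr) || is.null(snps$pos) || anyNA(snps$pos))
    stopf("GWAS result has no usable SNP map (chr/pos)")
  snps <- snps[order(snps$chr, snps$pos), ]

  regions <- list()
  artifacts <- list()
  for (ch in unique(snps$chr)) {
    s <- snps[snps$chr == ch, ]
    if (is.unsorted(s$pos, strictly = FALSE)) stopf("unsorted map on chromosome %s", ch)
    cand <- s[s$logbf >= peak_threshold, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$logbf), ]
    sup_pos <- s$pos[s$logbf >= support_threshold]
    chr_regions <- list()
    for (i in seq_len(nrow(cand))) {
      pk <- cand[i, ]
      absorbed <- any(vapply(chr_regions, function(r)
        pk$pos >= r$start && pk$pos <= r$end, logical(1)))
      if (absorbed) next
      support <- sup_pos[abs(sup_pos - pk$pos) <= window_bp & sup_pos != pk$pos]
      if (!length(support)) {
        artifacts[[length(artifacts) + 1]] <-
          data.frame(chr = ch, snp = pk$snp, pos = pk$pos, logbf = pk$logbf,
                     stringsAsFactors = FALSE)
        next
      }
      if (method == "chain") {
        left <- right <- pk$pos
        repeat {
          ext <- sup_pos[sup_pos < left & sup_pos >= left - window_bp]
          if (!length(ext)) break
          left <- min(ext)
        }
        repeat {
          ext <- sup_pos[sup_pos > right & sup_pos <= right + window_bp]
          if (!length(ext)) break
          right <- max(ext)
        }
      } else {
        inwin <- sup_pos[abs(sup_pos - pk$pos) <= window_bp]
        left <- min(inwin, pk$pos)
        right <- max(inwin, pk$pos)
      }
      # merge with overlapping existing regions; existing peaks are higher
      merged <- FALSE
      for (j in seq_along(chr_regions)) {
        r <- chr_regions[[j]]
        if (left <= r$end && right >= r$start) {
          chr_regions[[j]]$start <- min(left, r$start)
          chr_regions[[j]]$end <- max(right, r$end)
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        chr_regions[[length(chr_regions) + 1]] <-
          list(chr = ch, peak_snp = pk$snp, peak_pos = pk$pos,
               peak_logbf = pk$logbf, start = left, end = right)
      }
    }
    for (r in chr_regions) {
      r$n_snps <- sum(s$pos >= r$start & s$pos <= r$end)
      regions[[length(regions) + 1]] <- r
    }
  }

  out <- if (length(regions)) {
    df <- do.call(rbind, lapply(regions, as.data.frame, stringsAsFactors = FALSE))
    df <- df[order(df$chr, df$peak_pos), ]
    idx <- stats::ave(seq_len(nrow(df)), df$chr, FUN = seq_along)
    df <- data.frame(name = paste0("QTL", df$chr, "-", idx), df,
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  } else {
    data.frame(name = character(0), chr = character(0), peak_snp = character(0),
               peak_pos = numeric(0), peak_logbf = numeric(0),
               start = numeric(0), end = numeric(0), n_snps = integer(0),
               stringsAsFactors = FALSE)
  }
  attr(out, "artifacts") <- if (length(artifacts)) do.call(rbind, artifacts) else NULL
  class(out) <- c("qtl_regions", class(out))
  out
}

#' Fraction of genetic variance explained by a QTL
#'
#' The peak-SNP share is 2 p (1 - p) a^2 / var_u x 100 with observed
#' reference-allele frequency p and posterior mean effect a. The region
#' share is the empirical variance across individuals of the summed
#' regional genomic value (sum of centred genotype x effect over the
#' region's SNPs) over var_u x 100; this regional value accounts for LD
#' between the region's SNPs. var_u is the empirical variance of the total
#' GEBVs, so both shares are on the sampler's own genetic-value scale.
#'
#' @param regions `qtl_regions` from [call_qtl()].
#' @param gwas_result the `gwas_result` the regions were called from.
#' @param genotypes genotype matrix covering the region SNPs.
#' @return `regions` with added columns `pct_var_peak` and
#'   `pct_var_region`.
#' @export
variance_explained <- function(regions, gwas_result, genotypes) {
  var_u <- var(gwas_result$gebv)
  if (var_u <= 0) stopf("zero total genetic variance")
  snps <- gwas_result$snps
  pct_peak <- pct_region <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    pk <- snps[snps$snp == r$peak_snp, ]
    pct_peak[i] <- 2 * pk$freq * (1 - pk$freq) * pk$effect^2 / var_u * 100
    insnps <- snps$snp[snps$chr == r$chr & snps$pos >= r$start & snps$pos <= r$end]
    insnps <- intersect(insnps, colnames(genotypes))
    if (!length(insnps)) { pct_region[i] <- NA_real_; next }
    Z <- genotypes[, insnps, drop = FALSE]
    storage.mode(Z) <- "double"
    if (anyNA(Z)) {
      mu <- colMeans(Z, na.rm = TRUE)
      idx <- which(is.na(Z), arr.ind = TRUE)
      Z[idx] <- mu[idx[, 2]]
    }
    Zc <- sweep(Z, 2, colMeans(Z))
    gv <- drop(Zc %*% snps$effect[match(insnps, snps$snp)])
    pct_region[i] <- var(gv) / var_u * 100
  }
  regions$pct_var_peak <- pct_peak
  regions$pct_var_region <- pct_region
  regions
}

#' Annotate QTL regions with gene counts
#'
#' Counts (and lists) the genes whose annotated interval overlaps a QTL
#' credibility interval by at least 1 bp (closed 1-based intervals).
#'
#' @param regions `qtl_regions`.
#' @param annotation a `GRanges`, or path to a GFF3 / BED file. For GFF3
#'   input, features of type `gene` are used when present.
#' @return `regions` with added `n_genes` and `genes` (comma-separated)
#'   columns. A chromosome-name mismatch between regions and annotation
#'   raises a warning naming the missing chromosomes.
#' @export
annotate_regions <- function(regions, annotation) {
  gr <- annotation
  if (is.character(gr)) gr <- rtracklayer::import(gr)
  if (!nrow(regions)) {
    regions$n_genes <- integer(0)
    regions$genes <- character(0)
    return(regions)
  }
  if (length(gr)) {
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    gene_name <- gr$Name %||% gr$name %||% gr$gene_id %||% gr$ID
    if (is.null(gene_name)) gene_name <- paste0("feature", seq_along(gr))
    gene_name <- as.character(gene_name)
    miss <- setdiff(unique(regions$chr), as.character(GenomeInfoDb::seqnames(gr)))
    if (length(miss))
      warning(sprintf("chromosome(s) %s absent from the annotation",
                      paste(miss, collapse = ", ")), call. = FALSE)
  } else {
    gene_name <- character(0)
  }
  reg_gr <- GenomicRanges::GRanges(regions$chr,
                                   IRanges::IRanges(regions$start, regions$end))
  n_genes <- integer(nrow(regions))
  genes <- character(nrow(regions))
  if (length(gr)) {
    # seqlevel mismatches already produced our own warning above
    hits <- suppressWarnings(GenomicRanges::findOverlaps(reg_gr, gr))
    for (i in seq_len(nrow(regions))) {
      g <- unique(gene_name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
      n_genes[i] <- length(g)
      genes[i] <- paste(g, collapse = ",")
    }
  }
  regions$n_genes <- n_genes
  regions$genes <- genes
  regions
}

#' Write a QTL region table to TSV (positions also in Mb, rounded to 2
#' decimals as conventionally reported)
#'
#' @param regions `qtl_regions`.
#' @param path output path.
#' @export
write_qtl_report <- function(regions, path) {
  df <- as.data.frame(regions)
  df$peak_pos_mb <- round(df$peak_pos / 1e6, 2)
  df$start_mb <- round(df$start / 1e6, 2)
  df$end_mb <- round(df$end / 1e6, 2)
  .write_tsv(df, path)
}
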