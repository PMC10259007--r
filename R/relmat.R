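# Relationship matrices: pedigree-based numerator relationship matrix (A,
# tabular method) and VanRaden method-1 genomic relationship matrix (G),
# with optional blending for invertibility.

#' Pedigree (numerator) relationship matrix
#'
#' Tabular-method recursion: for animal i with parents s and d,
#' A[i, j] = (A[s, j] + A[d, j]) / 2 for j < i and
#' A[i, i] = 1 + A[s, d] / 2, so the diagonal equals one plus the
#' inbreeding coefficient. Unknown parents contribute zero relationship.
#'
#' @param pedigree `data.frame` with columns `id`, `sire`, `dam`, ordered
#'   parents-before-offspring.
#' @return symmetric matrix with dimnames set to the animal ids.
#' @export
a_matrix <- function(pedigree) {
  n <- nrow(pedigree)
  ids <- pedigree$id
  if (anyDuplicated(ids)) stopf("duplicated animal ids in pedigree")
  row_of <- setNames(seq_len(n), ids)
  si <- row_of[pedigree$sire]; si[is.na(pedigree$sire)] <- NA
  di <- row_of[pedigree$dam]; di[is.na(pedigree$dam)] <- NA
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    stopf("pedigree not ordered parents-before-offspring (or contains a cycle)")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- (if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0)
      A[j, i] <- A[i, j] <- rel / 2
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' VanRaden method-1 genomic relationship matrix
#'
#' G = M M' / (2 * sum(p (1 - p))) where M is the genotype matrix with
#' columns centred by twice the observed reference-allele frequency.
#' Missing genotypes are mean-imputed per SNP before centring. Optionally
#' blended with a pedigree matrix as w G + (1 - w) A to guarantee positive
#' definiteness.
#'
#' @param genotypes individuals x SNPs matrix coded 0/1/2 (post-QC).
#' @param blend_weight weight w on G in the blend; 1 returns the raw G.
#' @param a_matrix pedigree relationship matrix covering (at least) the
#'   genotyped individuals; required when `blend_weight < 1`.
#' @param freq optional reference-allele frequencies; defaults to observed.
#' @return symmetric matrix with individual ids as dimnames and attributes
#'   `blend_weight` and `freq`.
#' @export
g_matrix <- function(genotypes, blend_weight = 1, a_matrix = NULL, freq = NULL) {
  if (blend_weight < 0 || blend_weight > 1) stopf("blend_weight must lie in [0, 1]")
  Z <- genotypes
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
  }
  p <- freq %||% (colMeans(Z) / 2)
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stopf("need at least two polymorphic SNPs")
  Z <- Z[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(Z, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  if (blend_weight < 1) {
    if (is.null(a_matrix)) stopf("a_matrix required for blending")
    ids <- rownames(G)
    if (!all(ids %in% rownames(a_matrix)))
      stopf("a_matrix does not cover all genotyped individuals")
    G <- blend_weight * G + (1 - blend_weight) * a_matrix[ids, ids]
  }
  attr(G, "blend_weight") <- blend_weight
  attr(G, "freq") <- p
  G
}

#' Write / read a relationship matrix as TSV with an id header
#'
#' @param mat relationship matrix with dimnames.
#' @param path file path.
#' @export
write_relmat <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}
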