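## VanRaden (method 1) genomic relationship matrices, with optional
## leave-one-chromosome-out (LOCO) exclusion, and PCA of population
## structure on G.

#' Build a VanRaden genomic relationship matrix
#'
#' \eqn{G = ZZ'/(2\sum_j p_j(1-p_j))} with \eqn{Z = M - 2p}, M the 0/1/2
#' dosage matrix (animals x SNPs). Centering frequencies default to the
#' allele frequencies of the analysed sample. Monomorphic SNPs contribute
#' nothing and are dropped. With \code{excludeChrom} set, SNPs on that
#' chromosome are left out (the LOCO matrix used by the association scan).
#'
#' @param genotypes animals x SNPs dosage matrix in \{0,1,2\} with animal IDs
#'   as rownames (see [alleleDosage()]).
#' @param chrom chromosome per SNP (needed for \code{excludeChrom}).
#' @param freqs optional per-SNP centering frequency; default
#'   \code{colMeans(genotypes)/2}.
#' @param excludeChrom optional chromosome to leave out.
#' @param ridge value added to the diagonal for downstream factorisation
#'   stability; 0 disables.
#' @return A [GRM-class] object.
#' @export
buildGRM <- function(genotypes, chrom = NULL, freqs = NULL,
                     excludeChrom = NA_character_, ridge = 0) {
  m <- as.matrix(genotypes)
  if (is.null(rownames(m))) rownames(m) <- paste0("A", seq_len(nrow(m)))
  keep <- rep(TRUE, ncol(m))
  if (!is.na(excludeChrom)) {
    if (is.null(chrom)) stop("chrom required to exclude a chromosome")
    keep <- chrom != excludeChrom
  }
  if (!any(keep)) stop("all SNPs excluded from GRM")
  m <- m[, keep, drop = FALSE]
  p <- if (is.null(freqs)) colMeans(m) / 2 else freqs[keep]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs left for GRM")
  m <- m[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(m, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  if (ridge > 0) {
    G <- G + diag(ridge, nrow(G))
    message(sprintf("GRM: ridge %g added to diagonal", ridge))
  }
  G <- (G + t(G)) / 2
  new("GRM", values = G, freqs = unname(p),
      excludedChrom = as.character(excludeChrom))
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G; component scores are eigenvectors scaled by the
#' square root of their eigenvalues, and each component's variance fraction
#' is its eigenvalue over the trace.
#'
#' @param grm a [GRM-class].
#' @param k number of leading components.
#' @return list: \code{scores} (animals x k, columns PC1..PCk),
#'   \code{varFrac} (length-k variance fractions, non-increasing),
#'   \code{values} (eigenvalues).
#' @export
grmPCA <- function(grm, k = 2L) {
  G <- grmValues(grm)
  if (!all(is.finite(G))) stop("non-finite entries in GRM")
  if (k > nrow(G)) stop("k exceeds GRM dimension")
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sc <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam[seq_len(k)]), k)
  dimnames(sc) <- list(rownames(G), paste0("PC", seq_len(k)))
  list(scores = sc, varFrac = e$values[seq_len(k)] / sum(diag(G)),
       values = e$values)
}
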