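#' Construct a HaplotypePanel
#'
#' @param alleles 0/1 matrix, SNPs x haplotypes.
#' @param chrom chromosome per SNP.
#' @param pos bp position per SNP (strictly increasing within chromosome).
#' @param snpID optional SNP identifiers; defaults to \code{chrom_pos}.
#' @param animalID animal per haplotype column (each animal twice). Defaults
#'   to pairing consecutive columns.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(alleles, chrom, pos, snpID = NULL, animalID = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(snpID)) snpID <- paste(chrom, pos, sep = "_")
  if (is.null(animalID)) {
    if (ncol(alleles) %% 2L != 0L) stop("odd haplotype count needs explicit animalID")
    animalID <- rep(paste0("A", seq_len(ncol(alleles) / 2L)), each = 2L)
  }
  new("HaplotypePanel", alleles = alleles, chrom = as.character(chrom),
      pos = as.numeric(pos), snpID = as.character(snpID),
      animalID = as.character(animalID))
}

#' Construct an AncestryMatrix
#'
#' @param labels character matrix of IND/AFT/EUT labels, SNPs x haplotypes.
#' @inheritParams HaplotypePanel
#' @return An [AncestryMatrix-class] object.
#' @export
AncestryMatrix <- function(labels, chrom, pos, snpID = NULL, animalID = NULL) {
  labels <- as.matrix(labels)
  if (is.null(snpID)) snpID <- paste(chrom, pos, sep = "_")
  if (is.null(animalID)) {
    if (ncol(labels) %% 2L != 0L) stop("odd haplotype count needs explicit animalID")
    animalID <- rep(paste0("A", seq_len(ncol(labels) / 2L)), each = 2L)
  }
  new("AncestryMatrix", labels = labels, chrom = as.character(chrom),
      pos = as.numeric(pos), snpID = as.character(snpID),
      animalID = as.character(animalID))
}

#' @rdname HaplotypePanel
#' @param x a HaplotypePanel or AncestryMatrix.
#' @export
nSnps <- function(x) nrow(if (is(x, "HaplotypePanel")) x@alleles else x@labels)

#' @rdname HaplotypePanel
#' @export
nHaplotypes <- function(x) ncol(if (is(x, "HaplotypePanel")) x@alleles else x@labels)

#' @rdname HaplotypePanel
#' @export
animals <- function(x) unique(x@animalID)

#' @rdname HaplotypePanel
#' @export
chroms <- function(x) unique(x@chrom)

#' @rdname HaplotypePanel
#' @export
positions <- function(x) x@pos

#' @rdname HaplotypePanel
#' @export
alleles <- function(x) x@alleles

#' @rdname HaplotypePanel
#' @export
ancestryLabels <- function(x) x@labels

#' Subset a panel or ancestry matrix by SNP and/or haplotype index
#'
#' @param x a [HaplotypePanel-class] or [AncestryMatrix-class].
#' @param snps integer/logical SNP index (default all).
#' @param haps integer/logical haplotype-column index; must keep both
#'   haplotypes of every retained animal.
#' @return An object of the same class.
#' @export
subsetPanel <- function(x, snps = NULL, haps = NULL) {
  mat <- if (is(x, "HaplotypePanel")) x@alleles else x@labels
  if (is.null(snps)) snps <- seq_len(nrow(mat))
  if (is.null(haps)) haps <- seq_len(ncol(mat))
  cons <- if (is(x, "HaplotypePanel")) HaplotypePanel else AncestryMatrix
  cons(mat[snps, haps, drop = FALSE], x@chrom[snps], x@pos[snps],
       x@snpID[snps], x@animalID[haps])
}

#' Keep only the haplotypes of the given animals
#'
#' @param x a [HaplotypePanel-class] or [AncestryMatrix-class].
#' @param keep character vector of animal IDs to retain.
#' @return An object of the same class restricted to those animals.
#' @export
subsetAnimals <- function(x, keep) {
  idx <- which(x@animalID %in% keep)
  if (!length(idx)) stop("no haplotypes left after animal subset")
  subsetPanel(x, haps = idx)
}

#' Per-animal allele dosage matrix
#'
#' Sums the two haplotypes of each animal into a 0/1/2 dosage, returned as an
#' animals x SNPs matrix (the VanRaden orientation).
#'
#' @param panel a [HaplotypePanel-class].
#' @return integer matrix, animals x SNPs, rownames = animal IDs.
#' @export
alleleDosage <- function(panel) {
  ids <- animals(panel)
  h1 <- match(ids, panel@animalID)
  h2 <- length(panel@animalID) + 1L - match(ids, rev(panel@animalID))
  m <- t(panel@alleles[, h1, drop = FALSE] + panel@alleles[, h2, drop = FALSE])
  rownames(m) <- ids
  colnames(m) <- panel@snpID
  m
}

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d SNPs x %d haplotypes (%d animals), %d chromosome(s)\n",
              nSnps(object), nHaplotypes(object), length(animals(object)),
              length(chroms(object))))
})

setMethod("show", "AncestryMatrix", function(object) {
  fr <- colMeans(matrix(rowMeans(object@labels == "EUT"), ncol = 1))
  cat(sprintf("AncestryMatrix: %d SNPs x %d haplotypes (%d animals); mean EUT fraction %.3f\n",
              nSnps(object), nHaplotypes(object), length(animals(object)), fr))
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d animals, %d SNPs used%s; mean diagonal %.3f\n",
              nrow(object@values), length(object@freqs),
              if (is.na(object@excludedChrom)) "" else
                sprintf(" (chromosome %s excluded)", object@excludedChrom),
              mean(diag(object@values))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: sigma2g=%.4g sigma2pe=%.4g sigma2e=%.4g (logLik %.3f%s)\n",
              object@sigma2g, object@sigma2pe, object@sigma2e, object@logLik,
              if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "ScanResult", function(object) {
  tb <- object@table
  cat(sprintf("ScanResult [%s]: %d SNPs on %d chromosome(s); max -log10 p = %.2f%s\n",
              object@scan, nrow(tb), length(unique(tb$chrom)),
              suppressWarnings(max(tb$neglog10p, na.rm = TRUE)),
              if ("q" %in% names(tb)) sprintf("; min q = %.3g", min(tb$q, na.rm = TRUE))
              else ""))
})

#' Extract the per-SNP table of a scan
#'
#' @param x a [ScanResult-class].
#' @param ... ignored.
#' @return data.frame of per-SNP results.
#' @export
setMethod("as.data.frame", "ScanResult", function(x, ...) x@table)

#' @rdname GRM-class
#' @param x a GRM.
#' @export
grmValues <- function(x) x@values

ScanResult <- function(table, scan, pi0 = NA_real_) {
  new("ScanResult", table = table, scan = scan, pi0 = pi0)
}
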