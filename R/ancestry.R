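## Local-ancestry statistics: EUT-origin dosage coding for the GWA,
## recent-crossover counting and the recency filter that separates deep
## inter-se animals from recent crosses, and ancestry proportions.

#' EUT-origin allele dosage per animal
#'
#' Codes, at every SNP, the number of an animal's two alleles that descend
#' from the European-taurine (EUT) ancestor: 0, 1 or 2 copies. IND and AFT
#' both count as non-EUT (they are the two indigenous components). Missing
#' labels are a hard error; no imputation is attempted.
#'
#' @param ancestry an [AncestryMatrix-class].
#' @return integer matrix, SNPs x animals (columns named by animal ID).
#' @export
eutDosage <- function(ancestry) {
  l <- ancestry@labels
  ids <- animals(ancestry)
  h1 <- match(ids, ancestry@animalID)
  h2 <- length(ancestry@animalID) + 1L - match(ids, rev(ancestry@animalID))
  d <- (l[, h1, drop = FALSE] == "EUT") + (l[, h2, drop = FALSE] == "EUT")
  storage.mode(d) <- "integer"
  colnames(d) <- ids
  rownames(d) <- ancestry@snpID
  d
}

#' Count recent crossovers on one ancestry track
#'
#' A recent crossover is an adjacent-SNP transition between EUT and a
#' non-EUT (IND or AFT) label; IND-AFT switches are internal to the
#' indigenous genome and do not count. The count is standardised to
#' crossovers per Morgan at 1 Morgan = 100 Mbp.
#'
#' @param track character vector of IND/AFT/EUT labels along one chromosome.
#' @param lengthBp chromosome length in bp (> 0).
#' @return list: \code{count} (integer) and \code{perMorgan} (numeric).
#' @export
countCrossovers <- function(track, lengthBp) {
  if (!length(track)) stop("empty ancestry track")
  if (lengthBp <= 0) stop("chromosome length must be > 0")
  if (any(is.na(track))) stop("missing ancestry label in track")
  isE <- track == "EUT"
  count <- sum(isE[-1L] != isE[-length(isE)])
  list(count = count, perMorgan = count / (lengthBp / MORGAN_BP))
}

#' Per-animal crossover summary and recency score
#'
#' For every animal and chromosome, counts recent crossovers per Morgan on
#' each of the two haplotypes and ranks them (low, high). The recency score
#' of an animal is the unweighted mean over chromosomes of the lower
#' haplotype's per-Morgan count; recent crosses (e.g. F1s, backcrosses to a
#' pure parent) carry at least one near-intact haplotype and score near 0.
#' Chromosome length for the Morgan conversion is the position of the last
#' SNP on the chromosome.
#'
#' @param ancestry an [AncestryMatrix-class].
#' @return list: \code{perChrom} data.frame (animal, chrom, low, high, in
#'   crossovers per Morgan) and \code{score} named numeric per animal.
#' @export
recencyScore <- function(ancestry) {
  ids <- animals(ancestry)
  chromIds <- chroms(ancestry)
  h1 <- match(ids, ancestry@animalID)
  h2 <- length(ancestry@animalID) + 1L - match(ids, rev(ancestry@animalID))
  rows <- split(seq_len(nSnps(ancestry)),
                factor(ancestry@chrom, levels = chromIds))
  per <- do.call(rbind, lapply(chromIds, function(ch) {
    idx <- rows[[ch]]
    len <- max(ancestry@pos[idx])
    c1 <- vapply(h1, function(j)
      countCrossovers(ancestry@labels[idx, j], len)$perMorgan, 0)
    c2 <- vapply(h2, function(j)
      countCrossovers(ancestry@labels[idx, j], len)$perMorgan, 0)
    data.frame(animal = ids, chrom = ch,
               low = pmin(c1, c2), high = pmax(c1, c2))
  }))
  score <- vapply(split(per$low, factor(per$animal, levels = ids)), mean, 0)
  list(perChrom = per, score = score)
}

#' Filter out recently admixed animals
#'
#' Retains animals whose recency score (genome-average crossovers per Morgan
#' on the lower-count haplotype) is at least \code{threshold}; the default 3
#' follows the empirical "three or more crossovers per Morgan" rule. Animals
#' below the threshold are deemed too recently admixed for selection to have
#' left a detectable signature.
#'
#' @param scores output of [recencyScore()] (or its \code{score} element).
#' @param threshold crossovers per Morgan; animals with score >= threshold
#'   are retained.
#' @return list: \code{retained} and \code{removed} character vectors of
#'   animal IDs, plus the counts.
#' @export
filterRecent <- function(scores, threshold = 3) {
  s <- if (is.list(scores) && !is.null(scores$score)) scores$score else scores
  keep <- names(s)[s >= threshold]
  drop <- setdiff(names(s), keep)
  list(retained = keep, removed = drop,
       nRetained = length(keep), nRemoved = length(drop))
}

#' Genome-wide ancestry proportions
#'
#' Per-animal fraction of SNP alleles (over both haplotypes, SNP-weighted)
#' labelled with each ancestral pool, and the cohort mean.
#'
#' @param ancestry an [AncestryMatrix-class].
#' @return list: \code{perAnimal} (animals x 3 matrix, rows sum to 1) and
#'   \code{cohort} (named mean fractions).
#' @export
globalProportions <- function(ancestry) {
  ids <- animals(ancestry)
  h1 <- match(ids, ancestry@animalID)
  h2 <- length(ancestry@animalID) + 1L - match(ids, rev(ancestry@animalID))
  per <- vapply(POOLS, function(pool) {
    (colMeans(ancestry@labels[, h1, drop = FALSE] == pool) +
     colMeans(ancestry@labels[, h2, drop = FALSE] == pool)) / 2
  }, numeric(length(ids)))
  per <- matrix(per, nrow = length(ids), dimnames = list(ids, POOLS))
  list(perAnimal = per, cohort = colMeans(per))
}

#' Dominant ancestry of a genomic region
#'
#' Mean local-ancestry fraction per pool over the region's SNPs and the
#' retained animals; the label is the pool with the largest fraction. Exact
#' ties are broken by the fixed pool order IND, AFT, EUT with a warning.
#'
#' @param ancestry an [AncestryMatrix-class].
#' @param chrom region chromosome.
#' @param startBp,endBp closed bp interval.
#' @param animalsKeep animal IDs to average over (default: all).
#' @return list: \code{label} and \code{fractions} (named numeric, sums to 1).
#' @export
regionDominantAncestry <- function(ancestry, chrom, startBp, endBp,
                                   animalsKeep = NULL) {
  if (is.null(animalsKeep)) animalsKeep <- animals(ancestry)
  snps <- which(ancestry@chrom == chrom &
                ancestry@pos >= startBp & ancestry@pos <= endBp)
  if (!length(snps)) stop("region overlaps no SNP")
  haps <- which(ancestry@animalID %in% animalsKeep)
  sub <- ancestry@labels[snps, haps, drop = FALSE]
  fr <- vapply(POOLS, function(pool) mean(sub == pool), 0)
  top <- which(fr == max(fr))
  if (length(top) > 1L) {
    warning("dominant-ancestry tie; broken by pool order IND, AFT, EUT")
  }
  list(label = POOLS[top[1L]], fractions = fr)
}
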