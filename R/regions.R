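## Seed-and-extend candidate-region calling. A seed SNP (q below the seed
## threshold, or p below the suggestive threshold for GWA) opens a region;
## the region grows while any SNP within 500 Kbp beyond the current
## last-identified SNP (each direction) passes the suggestive threshold,
## that SNP becoming the new boundary. Boundaries are the outermost
## identified SNP positions (1-based, closed); regions grown from different
## seeds that touch or overlap are merged. Regions are returned as GRanges.

#' @importFrom GenomicRanges GRanges reduce findOverlaps pintersect seqnames
#'   start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

## grow one seed: values below `thresh` qualify; window in bp from the last
## identified SNP; returns range of member indices (sorted-by-pos indexing)
.growSeed <- function(pos, val, seedIdx, thresh, windowBp) {
  lo <- hi <- seedIdx
  repeat {
    cand <- which(pos > pos[hi] & pos <= pos[hi] + windowBp & val < thresh)
    if (!length(cand)) break
    hi <- max(cand)
  }
  repeat {
    cand <- which(pos < pos[lo] & pos >= pos[lo] - windowBp & val < thresh)
    if (!length(cand)) break
    lo <- min(cand)
  }
  c(lo, hi)
}

.callRegions <- function(tab, val, seedThresh, suggestiveThresh, windowBp,
                         source) {
  out <- list()
  for (ch in unique(tab$chrom)) {
    i <- which(tab$chrom == ch & !is.na(val))
    if (!length(i)) next
    o <- i[order(tab$pos[i])]
    pos <- tab$pos[o]; v <- val[o]
    seeds <- which(v < seedThresh)
    if (!length(seeds)) next
    spans <- unique(t(vapply(seeds, function(s)
      .growSeed(pos, v, s, suggestiveThresh, windowBp), integer(2))))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ch, IRanges::IRanges(pos[spans[, 1]], pos[spans[, 2]])))
    mem <- lapply(seq_along(gr), function(k)
      o[pos >= GenomicRanges::start(gr)[k] & pos <= GenomicRanges::end(gr)[k]])
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_snps = vapply(mem, length, 0L),
      top_stat = vapply(mem, function(ix) min(val[ix], na.rm = TRUE), 0),
      top_snp = vapply(mem, function(ix) tab$snp_id[ix[which.min(val[ix])]], ""),
      source = source
    )
    out[[ch]] <- gr
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_snps = integer(0), top_stat = numeric(0), top_snp = character(0),
      source = character(0))
    return(gr)
  }
  unname(do.call(c, unname(out)))
}

#' Call candidate regions from a selection scan
#'
#' Seeds at SNPs with q below \code{seedQ} (default 0.1) and extends with
#' the scan-specific suggestive q threshold within a 500-Kbp step from the
#' last identified SNP. The suggestive defaults are 0.5 for iHS and 0.25
#' for Rsb.
#'
#' @param scan [ScanResult-class] with q-values attached.
#' @param seedQ seed q threshold.
#' @param suggestiveQ suggestive q threshold (default by scan type).
#' @param windowBp extension window (bp) measured from the last identified
#'   SNP.
#' @return GRanges of candidate regions with \code{n_snps},
#'   \code{top_stat} (top-SNP q), \code{top_snp}, \code{source}.
#' @export
callSosRegions <- function(scan, seedQ = 0.1, suggestiveQ = NULL,
                           windowBp = 5e5) {
  tab <- scan@table
  if (!"q" %in% names(tab)) stop("scan needs q-values; run attachQvalues()")
  if (is.null(suggestiveQ)) {
    suggestiveQ <- switch(scan@scan, ihs = 0.5, rsb = 0.25,
                          stop("suggestiveQ has no default for scan ", scan@scan))
  }
  .callRegions(tab, tab$q, seedQ, suggestiveQ, windowBp, scan@scan)
}

#' Call candidate regions from a GWA scan
#'
#' Identical mechanics with a single suggestive p-value threshold (default
#' 1e-3) used for both seeding and extension.
#'
#' @param scan [ScanResult-class] (GWA allele or origin scan).
#' @param pThresh suggestive p threshold.
#' @param windowBp extension window in bp.
#' @return GRanges as [callSosRegions()] (\code{top_stat} is the top-SNP p).
#' @export
callGwaRegions <- function(scan, pThresh = 1e-3, windowBp = 5e5) {
  tab <- scan@table
  .callRegions(tab, tab$p, pThresh, pThresh, windowBp, scan@scan)
}

#' Overlaps between two region sets
#'
#' All pairs with at least 1 bp intersection, with the shared interval and
#' its length (width of the closed bp intersection).
#'
#' @param a,b GRanges (e.g. from [callGwaRegions()] and [callSosRegions()]).
#' @return data.frame: chrom, a_start/a_end, b_start/b_end,
#'   overlap_start/overlap_end, overlap_bp.
#' @export
intersectRegions <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b)
  if (!length(hits)) {
    return(data.frame(chrom = character(0), a_start = numeric(0),
                      a_end = numeric(0), b_start = numeric(0),
                      b_end = numeric(0), overlap_start = numeric(0),
                      overlap_end = numeric(0), overlap_bp = numeric(0)))
  }
  qa <- a[S4Vectors::queryHits(hits)]
  qb <- b[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::pintersect(qa, qb)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(qa)),
    a_start = GenomicRanges::start(qa), a_end = GenomicRanges::end(qa),
    b_start = GenomicRanges::start(qb), b_end = GenomicRanges::end(qb),
    overlap_start = GenomicRanges::start(ov),
    overlap_end = GenomicRanges::end(ov),
    overlap_bp = GenomicRanges::width(ov)
  )
}

#' Attach dominant ancestry to called regions
#'
#' Labels each region with the ancestral pool holding the largest mean
#' local-ancestry fraction over the region's SNPs and the retained animals
#' (the subset the selection scans were run on).
#'
#' @param regions GRanges from a region caller.
#' @param ancestry [AncestryMatrix-class].
#' @param animalsKeep animal IDs the scan used (default all).
#' @return the GRanges with a \code{dominant_ancestry} metadata column.
#' @export
annotateDominantAncestry <- function(regions, ancestry, animalsKeep = NULL) {
  if (!length(regions)) {
    S4Vectors::mcols(regions)$dominant_ancestry <- character(0)
    return(regions)
  }
  lab <- vapply(seq_along(regions), function(k) {
    regionDominantAncestry(ancestry,
                           as.character(GenomicRanges::seqnames(regions)[k]),
                           GenomicRanges::start(regions)[k],
                           GenomicRanges::end(regions)[k],
                           animalsKeep)$label
  }, "")
  S4Vectors::mcols(regions)$dominant_ancestry <- lab
  regions
}
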