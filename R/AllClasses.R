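#' @import methods
#' @importFrom stats approx cor cummax dist ecdf lm median optim pchisq pnorm
#'   predict qnorm quantile rbeta rbinom rnorm rpois runif sd setNames
#'   smooth.spline var
#' @importFrom utils read.table write.table head tail
NULL

POOLS <- c("IND", "AFT", "EUT")

#' HaplotypePanel: phased biallelic haplotypes on a physical map
#'
#' Stores a 0/1 allele matrix (SNPs in rows, haplotypes in columns) together
#' with per-SNP chromosome and base-pair position, SNP identifiers, and the
#' haplotype-to-animal mapping (two haplotypes per animal, consecutive
#' columns). Positions must be strictly increasing within each chromosome;
#' the map convention throughout the package is 1 Morgan = 100 Mbp.
#'
#' @slot alleles integer matrix of 0/1 alleles, SNPs x haplotypes.
#' @slot chrom character vector, chromosome per SNP (SNPs grouped by
#'   chromosome, in map order).
#' @slot pos numeric vector of bp positions per SNP.
#' @slot snpID character vector of SNP identifiers.
#' @slot animalID character vector, one entry per haplotype column giving the
#'   animal each haplotype belongs to; each animal appears exactly twice.
#'
#' @export
setClass("HaplotypePanel",
  representation(
    alleles  = "matrix",
    chrom    = "character",
    pos      = "numeric",
    snpID    = "character",
    animalID = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  a <- object@alleles
  if (!is.numeric(a) && !is.integer(a)) msg <- c(msg, "alleles must be numeric")
  if (nrow(a) != length(object@chrom)) msg <- c(msg, "chrom length != SNP count")
  if (nrow(a) != length(object@pos)) msg <- c(msg, "pos length != SNP count")
  if (nrow(a) != length(object@snpID)) msg <- c(msg, "snpID length != SNP count")
  if (ncol(a) != length(object@animalID)) {
    msg <- c(msg, "animalID length != haplotype count")
  }
  if (length(a) && !all(a %in% c(0L, 1L))) msg <- c(msg, "alleles must be 0/1")
  for (ch in unique(object@chrom)) {
    p <- object@pos[object@chrom == ch]
    if (any(diff(p) <= 0)) {
      msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
    }
  }
  if (length(object@animalID)) {
    tab <- table(object@animalID)
    if (any(tab != 2L)) msg <- c(msg, "each animal must own exactly 2 haplotypes")
  }
  if (length(msg)) msg else TRUE
})

#' AncestryMatrix: per-allele local-ancestry labels
#'
#' Per-SNP, per-haplotype ancestral-population labels from
#' \code{c("IND","AFT","EUT")} (Bos indicus, African taurine, European
#' taurine), aligned with a [HaplotypePanel]: same SNP grid, same haplotype
#' columns. Missing labels are not permitted; crossover counting and dosage
#' coding refuse to impute.
#'
#' @slot labels character matrix, SNPs x haplotypes, entries in POOLS.
#' @slot chrom,pos,snpID,animalID map and haplotype metadata as in
#'   [HaplotypePanel].
#'
#' @export
setClass("AncestryMatrix",
  representation(
    labels   = "matrix",
    chrom    = "character",
    pos      = "numeric",
    snpID    = "character",
    animalID = "character"
  )
)

setValidity("AncestryMatrix", function(object) {
  msg <- character()
  l <- object@labels
  if (nrow(l) != length(object@chrom)) msg <- c(msg, "chrom length != SNP count")
  if (nrow(l) != length(object@pos)) msg <- c(msg, "pos length != SNP count")
  if (ncol(l) != length(object@animalID)) {
    msg <- c(msg, "animalID length != haplotype count")
  }
  if (length(l) && (any(is.na(l)) || !all(l %in% POOLS))) {
    msg <- c(msg, "labels must be complete and in {IND, AFT, EUT}")
  }
  if (length(object@animalID)) {
    tab <- table(object@animalID)
    if (any(tab != 2L)) msg <- c(msg, "each animal must own exactly 2 haplotypes")
  }
  if (length(msg)) msg else TRUE
})

#' GRM: VanRaden genomic relationship matrix
#'
#' Symmetric animal-by-animal relationship matrix
#' \eqn{G = ZZ'/(2\sum p(1-p))} with \eqn{Z = M - 2p}, optionally built
#' excluding one chromosome (leave-one-chromosome-out, LOCO).
#'
#' @slot values symmetric numeric matrix with animal IDs as dimnames.
#' @slot freqs numeric vector of centering allele frequencies actually used
#'   (polymorphic SNPs only).
#' @slot excludedChrom character, the chromosome left out, or NA.
#'
#' @export
setClass("GRM",
  representation(
    values        = "matrix",
    freqs         = "numeric",
    excludedChrom = "character"
  )
)

setValidity("GRM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(v) && max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (is.null(rownames(v))) msg <- c(msg, "values must carry animal IDs as dimnames")
  if (length(msg)) msg else TRUE
})

#' VarianceComponents: REML estimates under the repeated-records animal model
#'
#' Holds the three variance components of the milk-yield-deviation mixed
#' model: polygenic additive (sigma2_g, with covariance proportional to a
#' GRM), permanent environment (sigma2_pe, iid per animal), and residual
#' (sigma2_e, iid per record), plus the restricted log-likelihood at the
#' optimum and the chromosome excluded from the GRM they were fitted under.
#'
#' @export
setClass("VarianceComponents",
  representation(
    sigma2g       = "numeric",
    sigma2pe      = "numeric",
    sigma2e       = "numeric",
    logLik        = "numeric",
    excludedChrom = "character",
    converged     = "logical"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (any(c(object@sigma2g, object@sigma2pe, object@sigma2e) < 0)) {
    msg <- c(msg, "variance components must be non-negative")
  }
  if (!is.finite(object@logLik)) msg <- c(msg, "logLik must be finite")
  if (length(msg)) msg else TRUE
})

#' ScanResult: per-SNP statistics for one genome scan
#'
#' A thin S4 container around a per-SNP table shared by all four scans
#' (GWA allele effects, GWA ancestral-origin effects, iHS, Rsb). The table
#' always carries \code{chrom}, \code{pos}, \code{snp_id}, a p-value column
#' \code{p} with its \code{neglog10p} companion, and (after
#' [attachQvalues()]) \code{q}. Scan-specific columns (effect/se for GWA,
#' raw/standardised statistics and flags for the homozygosity scans) ride
#' along.
#'
#' @slot table data.frame of per-SNP results.
#' @slot scan character scan label, one of \code{"gwa_allele"},
#'   \code{"gwa_origin"}, \code{"ihs"}, \code{"rsb"}.
#' @slot pi0 numeric, Storey pi0 estimate once q-values are attached (NA before).
#'
#' @export
setClass("ScanResult",
  representation(table = "data.frame", scan = "character", pi0 = "numeric"),
  prototype(pi0 = NA_real_)
)

setValidity("ScanResult", function(object) {
  need <- c("chrom", "pos", "snp_id", "p", "neglog10p")
  miss <- setdiff(need, names(object@table))
  if (length(miss)) {
    return(sprintf("scan table missing columns: %s", paste(miss, collapse = ", ")))
  }
  pv <- object@table$p
  if (any(!is.na(pv) & (pv <= 0 | pv > 1))) return("p values must lie in (0, 1]")
  TRUE
})
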