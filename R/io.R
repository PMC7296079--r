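## Plain-text interchange formats: phased VCF (via VariantAnnotation on
## read), a haplotype-matrix TSV dialect (chrom, pos, ref, alt, then two
## columns per animal), local-ancestry TSV, phenotype CSV, scan TSV, region
## TSV/BED and dense GRM TSV. All writers emit text only.

#' Write a haplotype panel as TSV
#'
#' Dialect: header \code{chrom}, \code{pos}, \code{ref}, \code{alt}, then
#' two 0/1 columns per animal named \code{<animal>_h1}, \code{<animal>_h2}.
#'
#' @param panel [HaplotypePanel-class].
#' @param path output file.
#' @export
writeHaplotypesTSV <- function(panel, path) {
  df <- data.frame(chrom = panel@chrom, pos = panel@pos,
                   ref = "A", alt = "C", check.names = FALSE)
  m <- as.data.frame(panel@alleles)
  names(m) <- paste0(panel@animalID, "_h", rep(1:2, length.out = ncol(m)))
  write.table(cbind(df, m), path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a haplotype panel from TSV
#'
#' @param path file written by [writeHaplotypesTSV()].
#' @return A [HaplotypePanel-class].
#' @export
readHaplotypesTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  hapCols <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  animalID <- sub("_h[12]$", "", hapCols)
  HaplotypePanel(as.matrix(df[hapCols]), df$chrom, df$pos, animalID = animalID)
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' Biallelic sites with phased GT fields (\code{0|1}); one sample per
#' animal.
#'
#' @param panel [HaplotypePanel-class].
#' @param path output file (uncompressed \code{.vcf}).
#' @export
writeHaplotypesVCF <- function(panel, path) {
  ids <- animals(panel)
  h1 <- match(ids, panel@animalID)
  h2 <- length(panel@animalID) + 1L - match(ids, rev(panel@animalID))
  gt <- matrix(paste0(panel@alleles[, h1], "|", panel@alleles[, h2]),
               nrow = nSnps(panel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  body <- cbind(panel@chrom, format(panel@pos, scientific = FALSE, trim = TRUE),
                panel@snpID, "A", "C", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
}

#' Read phased haplotypes from a VCF
#'
#' Accepts biallelic, fully phased records only; unphased or multiallelic
#' records are rejected and counted in a message.
#'
#' @param path a VCF file.
#' @return A [HaplotypePanel-class].
#' @export
readHaplotypesVCF <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VariantAnnotation is required to read VCF")
  }
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::fixed(v)$ALT
  multi <- S4Vectors::elementNROWS(alt) != 1L
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- !multi & phased
  nBad <- sum(!keep)
  if (nBad) message(nBad, " record(s) rejected (unphased or multiallelic)")
  if (!any(keep)) stop("no usable phased biallelic records in ", path)
  gt <- gt[keep, , drop = FALSE]
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  nH <- 2L * ncol(gt)
  m <- matrix(0L, nrow(gt), nH)
  m[, seq(1L, nH, 2L)] <- a1
  m[, seq(2L, nH, 2L)] <- a2
  HaplotypePanel(m,
                 as.character(GenomicRanges::seqnames(rr))[keep],
                 GenomicRanges::start(rr)[keep],
                 snpID = rownames(gt),
                 animalID = rep(colnames(gt), each = 2L))
}

#' Write local-ancestry labels as TSV
#'
#' Header \code{chrom}, \code{pos}, then one IND/AFT/EUT column per
#' haplotype named \code{<animal>_h1}, \code{<animal>_h2}.
#'
#' @param ancestry [AncestryMatrix-class].
#' @param path output file.
#' @export
writeAncestryTSV <- function(ancestry, path) {
  m <- as.data.frame(ancestry@labels)
  names(m) <- paste0(ancestry@animalID, "_h", rep(1:2, length.out = ncol(m)))
  write.table(cbind(data.frame(chrom = ancestry@chrom, pos = ancestry@pos), m),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read local-ancestry labels from TSV
#'
#' @param path file in the [writeAncestryTSV()] layout.
#' @return An [AncestryMatrix-class].
#' @export
readAncestryTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  hapCols <- setdiff(names(df), c("chrom", "pos"))
  animalID <- sub("_h[12]$", "", hapCols)
  AncestryMatrix(as.matrix(df[hapCols]), df$chrom, df$pos, animalID = animalID)
}

#' Phenotype CSV reader/writer
#'
#' Columns \code{animal_id}, \code{record_id}, \code{value}.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
writePhenotypesCSV <- function(pheno, path) {
  write.table(pheno[c("animal_id", "record_id", "value")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
}

#' @rdname writePhenotypesCSV
#' @export
readPhenotypesCSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   colClasses = c(animal_id = "character"))
  if (!all(c("animal_id", "record_id", "value") %in% names(df))) {
    stop("phenotype CSV needs animal_id, record_id, value")
  }
  df
}

#' Scan TSV writer/reader
#'
#' One row per SNP with the scan's full table.
#'
#' @param scan [ScanResult-class].
#' @param path file path.
#' @export
writeScanTSV <- function(scan, path) {
  write.table(scan@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeScanTSV
#' @param scanType scan label to restore.
#' @export
readScanTSV <- function(path, scanType) {
  ScanResult(read.table(path, header = TRUE, sep = "\t", check.names = FALSE),
             scanType)
}

#' Write called regions as TSV and BED
#'
#' The TSV mirrors a candidate-region table (chromosome, interval in Mbp,
#' top-SNP statistic, dominant ancestry where attached); the BED export is
#' 0-based half-open.
#'
#' @param regions GRanges from a region caller.
#' @param path output TSV path.
#' @export
writeRegionsTSV <- function(regions, path) {
  df <- as.data.frame(regions)
  df$seqnames <- as.character(df$seqnames)
  names(df)[names(df) == "seqnames"] <- "chrom"
  df$region_mbp <- sprintf("%.2f-%.2f", df$start / 1e6, df$end / 1e6)
  write.table(df[setdiff(names(df), c("width", "strand"))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @rdname writeRegionsTSV
#' @export
writeRegionsBED <- function(regions, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   name = if (length(regions))
                     paste0(S4Vectors::mcols(regions)$source, "_",
                            seq_along(regions)) else character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Dense GRM TSV writer/reader
#'
#' A square matrix with a header row of animal IDs.
#'
#' @param grm [GRM-class].
#' @param path file path.
#' @export
writeGRMTSV <- function(grm, path) {
  write.table(grmValues(grm), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
}

#' @rdname writeGRMTSV
#' @export
readGRMTSV <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
  rownames(m) <- colnames(m)
  new("GRM", values = (m + t(m)) / 2, freqs = numeric(0),
      excludedChrom = NA_character_)
}
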