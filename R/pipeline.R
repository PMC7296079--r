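## End-to-end driver: simulate (or load) -> ancestry statistics -> recency
## filter -> GRM/PCA -> dual-effect GWA -> iHS (all-samples and/or filtered
## scenario) -> Rsb (filtered admixed vs reference) -> q-values -> region
## calling -> GWA x SoS overlap -> manifest.

#' Assemble a pipeline configuration
#'
#' Returns the full configuration with every threshold at its documented
#' default; override any element by name. Thresholds: \code{crossover}
#' (recency filter, crossovers per Morgan), \code{maf} (iHS), \code{decay}
#' (EHH/EHHS), \code{binStep} (iHS standardisation), \code{seedQ} and the
#' scan-specific suggestive q for region calling, \code{gwaP} (suggestive
#' GWA p), \code{windowBp} (region extension step).
#'
#' @param ... overrides, e.g. \code{seed = 7}, \code{scenario = "both"}.
#' @return a named list; serialises losslessly through JSON via
#'   [writePipelineConfig()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outDir = NULL,
    scenario = "both",          # "all", "filtered" or "both" for iHS
    simulate = list(nSnps = 300L, nChrom = 2L, spacingBp = 5e4,
                    nAnimals = 60L, nHapPerPool = 150L,
                    generations = 16L, popSize = 150L,
                    backcross = list(n = 30L, sires = 3L, pool = "EUT"),
                    sweep = list(chrom = "chr1", coreSnp = NULL,
                                 targetFreq = 0.6, halfWidthBp = 1e6),
                    qtl = NULL,
                    varcomp = list(sigma2g = 1, sigma2pe = 0.5, sigma2e = 1,
                                   records = 3L),
                    referenceAnimals = 30L),
    paths = list(haplotypes = NULL, ancestry = NULL, phenotypes = NULL,
                 reference = NULL),
    thresholds = list(crossover = 3, maf = 0.05, decay = 0.05,
                      binStep = 0.025, seedQ = 0.1, suggestiveIhsQ = 0.5,
                      suggestiveRsbQ = 0.25, gwaP = 1e-3, windowBp = 5e5)
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    } else {
      cfg[[nm]] <- mods[[nm]]
    }
  }
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, cfg)
}

.pipelineInputs <- function(cfg) {
  p <- cfg$paths
  if (!is.null(p$haplotypes)) {
    panel <- if (grepl("\\.vcf$", p$haplotypes)) readHaplotypesVCF(p$haplotypes)
             else readHaplotypesTSV(p$haplotypes)
    ancestry <- readAncestryTSV(p$ancestry)
    pheno <- if (!is.null(p$phenotypes)) readPhenotypesCSV(p$phenotypes) else NULL
    reference <- if (!is.null(p$reference)) {
      if (grepl("\\.vcf$", p$reference)) readHaplotypesVCF(p$reference)
      else readHaplotypesTSV(p$reference)
    } else NULL
    return(list(panel = panel, ancestry = ancestry, pheno = pheno,
                reference = reference, truth = NULL))
  }
  s <- cfg$simulate
  sim <- simulateCohort(nSnps = s$nSnps, nChrom = s$nChrom,
                        spacingBp = s$spacingBp, nAnimals = s$nAnimals,
                        nHapPerPool = s$nHapPerPool,
                        generations = s$generations, popSize = s$popSize,
                        backcross = s$backcross,
                        blockSize = s$blockSize, nPrototypes = s$nPrototypes,
                        seed = cfg$seed)
  panel <- sim$panel
  truth <- list(generations = sim$generations)
  if (!is.null(s$sweep)) {
    # post-admixture selection acts on the established (deep) animals;
    # recently introduced genomes have not been exposed to it
    deepHaps <- which(panel@animalID %in%
                        names(sim$generations)[sim$generations > 1L])
    if (!length(deepHaps)) deepHaps <- NULL
    sw <- injectSweep(panel, s$sweep$chrom, s$sweep$coreSnp,
                      s$sweep$targetFreq, s$sweep$halfWidthBp,
                      haps = deepHaps, seed = cfg$seed + 10L)
    panel <- sw$panel
    truth$sweep <- list(coreIndex = sw$coreIndex, coreAllele = sw$coreAllele,
                        corePos = panel@pos[sw$coreIndex],
                        chrom = s$sweep$chrom)
  }
  grm <- buildGRM(alleleDosage(panel), chrom = panel@chrom)
  pheno <- simulatePhenotypes(panel, sim$ancestry, qtl = s$qtl,
                              varcomp = s$varcomp, grm = grm,
                              seed = cfg$seed + 20L)
  truth$qtl <- s$qtl
  reference <- simulateAdmixture(sim$founders, s$referenceAnimals,
                                 proportions = c(IND = 0.75, AFT = 0.25, EUT = 0),
                                 generations = 8L, seed = cfg$seed + 30L)$panel
  list(panel = panel, ancestry = sim$ancestry, pheno = pheno,
       reference = reference, founders = sim$founders, truth = truth)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or loaded inputs and (optionally)
#' writes all declared outputs plus a JSON manifest recording the seed and
#' every threshold, so a rerun with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param cfg configuration from [pipelineConfig()].
#' @return list: inputs, crossover summary, retained animals, proportions,
#'   GRM/PCA, GWA scans, iHS scans per scenario, Rsb scan, called regions,
#'   GWA-vs-SoS overlaps, manifest.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  th <- cfg$thresholds
  inp <- .pipelineInputs(cfg)
  panel <- inp$panel; ancestry <- inp$ancestry

  xo <- recencyScore(ancestry)
  filt <- filterRecent(xo, th$crossover)
  props <- globalProportions(ancestry)

  grm <- buildGRM(alleleDosage(panel), chrom = panel@chrom)
  pca <- grmPCA(grm, k = 2L)

  gwa <- if (!is.null(inp$pheno)) {
    gwaScan(inp$pheno, panel, ancestry)
  } else NULL

  # polarity over the entire data set: cohort, reference population and (in
  # simulation mode) the ancestral reference panels
  pooled <- c(list(panel),
              if (!is.null(inp$reference)) list(inp$reference),
              inp$founders)
  polarity <- suppressWarnings(polarizeAlleles(pooled))
  scen <- cfg$scenario
  ihsScans <- list()
  if (scen %in% c("all", "both")) {
    raw <- ihsScan(panel, polarity, maf = th$maf, decay = th$decay)
    ihsScans$all <- attachQvalues(standardizeIhs(raw, binStep = th$binStep))
  }
  if (scen %in% c("filtered", "both")) {
    if (!filt$nRetained) stop("recency filter retained no animals; ",
                              "lower the crossover threshold")
    fp <- subsetAnimals(panel, filt$retained)
    raw <- ihsScan(fp, polarity, maf = th$maf, decay = th$decay)
    ihsScans$filtered <- attachQvalues(standardizeIhs(raw, binStep = th$binStep))
  }

  rsb <- if (!is.null(inp$reference)) {
    fp <- if (filt$nRetained) subsetAnimals(panel, filt$retained) else panel
    attachQvalues(rsbScan(fp, inp$reference, decay = th$decay))
  } else NULL

  keyIhs <- if (!is.null(ihsScans$filtered)) ihsScans$filtered else ihsScans$all
  regions <- list()
  if (!is.null(keyIhs)) {
    regions$ihs <- annotateDominantAncestry(
      callSosRegions(keyIhs, seedQ = th$seedQ, suggestiveQ = th$suggestiveIhsQ,
                     windowBp = th$windowBp),
      ancestry, if (filt$nRetained) filt$retained else NULL)
  }
  if (!is.null(rsb)) {
    regions$rsb <- annotateDominantAncestry(
      callSosRegions(rsb, seedQ = th$seedQ, suggestiveQ = th$suggestiveRsbQ,
                     windowBp = th$windowBp),
      ancestry, if (filt$nRetained) filt$retained else NULL)
  }
  overlaps <- NULL
  if (!is.null(gwa)) {
    regions$gwa <- callGwaRegions(gwa$allele, pThresh = th$gwaP,
                                  windowBp = th$windowBp)
    sos <- c(if (!is.null(regions$ihs)) regions$ihs,
             if (!is.null(regions$rsb)) regions$rsb)
    if (!is.null(sos)) overlaps <- intersectRegions(regions$gwa, sos)
  }

  manifest <- list(package = "admixscan",
                   version = as.character(utils::packageVersion("admixscan")),
                   seed = cfg$seed, scenario = cfg$scenario, thresholds = th,
                   n_animals = length(animals(panel)), n_snps = nSnps(panel),
                   n_retained = filt$nRetained, n_removed = filt$nRemoved)

  out <- list(panel = panel, ancestry = ancestry, pheno = inp$pheno,
              truth = inp$truth, crossovers = xo, filter = filt,
              proportions = props, grm = grm, pca = pca, gwa = gwa,
              ihs = ihsScans, rsb = rsb, regions = regions,
              overlaps = overlaps, manifest = manifest)

  if (!is.null(cfg$outDir)) .writePipelineOutputs(out, cfg)
  out
}

.writePipelineOutputs <- function(out, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(cfg$outDir, f)
  writeHaplotypesTSV(out$panel, fp("haplotypes.tsv"))
  writeAncestryTSV(out$ancestry, fp("ancestry.tsv"))
  if (!is.null(out$pheno)) writePhenotypesCSV(out$pheno, fp("phenotypes.csv"))
  write.table(out$crossovers$perChrom, fp("crossovers.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  writeLines(out$filter$retained, fp("retained_animals.txt"))
  writeGRMTSV(out$grm, fp("grm.tsv"))
  write.table(data.frame(animal = rownames(out$pca$scores), out$pca$scores),
              fp("pca.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(out$gwa)) {
    writeScanTSV(out$gwa$allele, fp("scan_gwa_allele.tsv"))
    writeScanTSV(out$gwa$origin, fp("scan_gwa_origin.tsv"))
  }
  for (nm in names(out$ihs)) {
    writeScanTSV(out$ihs[[nm]], fp(sprintf("scan_ihs_%s.tsv", nm)))
  }
  if (!is.null(out$rsb)) writeScanTSV(out$rsb, fp("scan_rsb.tsv"))
  for (nm in names(out$regions)) {
    writeRegionsTSV(out$regions[[nm]], fp(sprintf("regions_%s.tsv", nm)))
    writeRegionsBED(out$regions[[nm]], fp(sprintf("regions_%s.bed", nm)))
  }
  if (!is.null(out$overlaps)) {
    write.table(out$overlaps, fp("overlaps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(NULL)
}
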