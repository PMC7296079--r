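## Forward simulation of an admixed cohort from three divergent ancestral
## pools (IND/AFT/EUT proxies). Everything downstream (crossover filtering,
## GWA, iHS/Rsb) is exercised against cohorts produced here, with the true
## ancestry of every allele tracked through each meiosis.

MORGAN_BP <- 1e8  # map convention used throughout: 1 Morgan = 100 Mbp

#' Sample ancestral-pool allele frequencies under Balding-Nichols drift
#'
#' Draws a base allele frequency per SNP and, for each of the three ancestral
#' pools, a drifted frequency from a Beta distribution with mean equal to the
#' base frequency and variance \eqn{p(1-p)F_{ST}}. With \eqn{F_{ST}=0} the
#' drifted frequency equals the base frequency exactly.
#'
#' @param nSnps number of SNPs.
#' @param baseRange length-2 range of the uniform base-frequency draw.
#' @param fst named numeric of per-pool Fst values in \[0, 1), names
#'   IND/AFT/EUT. Defaults emulate strongly diverged indicine vs taurine
#'   pools.
#' @param seed integer seed; same seed gives a bitwise-identical table.
#' @return data.frame with columns \code{base}, \code{IND}, \code{AFT},
#'   \code{EUT}; the per-pool Fst is kept in \code{attr(, "fst")}.
#' @export
sampleAncestralFreqs <- function(nSnps, baseRange = c(0.1, 0.9),
                                 fst = c(IND = 0.2, AFT = 0.1, EUT = 0.1),
                                 seed = 1L) {
  if (nSnps < 1) stop("nSnps must be >= 1")
  fst <- fst[POOLS]
  if (any(is.na(fst)) || any(fst < 0) || any(fst >= 1)) {
    stop("fst must be named for IND/AFT/EUT and lie in [0, 1)")
  }
  withr::with_seed(seed, {
    base <- runif(nSnps, baseRange[1], baseRange[2])
    drift <- vapply(POOLS, function(pool) {
      f <- fst[[pool]]
      if (f == 0) return(base)
      rbeta(nSnps, base * (1 - f) / f, (1 - base) * (1 - f) / f)
    }, numeric(nSnps))
    out <- data.frame(base = base, drift)
    attr(out, "fst") <- fst
    out
  })
}

#' Simulate founder haplotype panels for the three ancestral pools
#'
#' Draws phased 0/1 haplotypes per pool from the pool's drifted allele
#' frequencies. By default SNPs are independent within pool; with
#' \code{blockSize} set, background linkage disequilibrium is added by
#' copying each haplotype, block by block, from one of \code{nPrototypes}
#' pool-specific prototype haplotypes (allele-frequency expectation is
#' unchanged). Block LD is what makes recently admixed animals carry long
#' shared ancestral haplotypes, the nuisance signal the crossover filter is
#' designed to remove.
#'
#' @param freqs output of [sampleAncestralFreqs()].
#' @param map data.frame with columns \code{chrom} and \code{pos} (bp),
#'   one row per SNP of \code{freqs}.
#' @param nHapPerPool haplotypes per pool (even, >= 2); scalar or named per
#'   pool.
#' @param seed integer seed.
#' @param blockSize optional number of consecutive SNPs per LD block.
#' @param nPrototypes prototypes per block when \code{blockSize} is set.
#' @return named list of three [HaplotypePanel-class] objects (IND, AFT, EUT).
#' @export
simulateFounderHaplotypes <- function(freqs, map, nHapPerPool = 50L, seed = 1L,
                                      blockSize = NULL, nPrototypes = 4L) {
  if (nrow(freqs) != nrow(map)) stop("freqs and map disagree on SNP count")
  if (length(nHapPerPool) == 1L) {
    nHapPerPool <- setNames(rep(nHapPerPool, 3L), POOLS)
  }
  if (any(nHapPerPool < 2L)) stop("need at least 2 haplotypes per pool")
  nsnp <- nrow(freqs)
  withr::with_seed(seed, {
    panels <- lapply(POOLS, function(pool) {
      p <- freqs[[pool]]
      nh <- nHapPerPool[[pool]]
      if (is.null(blockSize)) {
        m <- matrix(rbinom(nsnp * nh, 1L, rep(p, nh)), nrow = nsnp)
      } else {
        m <- matrix(0L, nsnp, nh)
        for (ch in unique(map$chrom)) {
          idx <- which(map$chrom == ch)
          starts <- seq(1L, length(idx), by = blockSize)
          for (s in starts) {
            rows <- idx[s:min(s + blockSize - 1L, length(idx))]
            proto <- matrix(rbinom(length(rows) * nPrototypes, 1L,
                                   rep(p[rows], nPrototypes)),
                            nrow = length(rows))
            pick <- sample.int(nPrototypes, nh, replace = TRUE)
            m[rows, ] <- proto[, pick, drop = FALSE]
          }
        }
      }
      colnames(m) <- paste0(pool, "_h", seq_len(nh))
      HaplotypePanel(m, map$chrom, map$pos,
                     animalID = rep(paste0(pool, "_", seq_len(nh / 2)), each = 2L))
    })
    names(panels) <- POOLS
    panels
  })
}

## segment lists: a haplotype on one chromosome is (ends, src) with ends the
## increasing right endpoints (bp, last = chromosome length) and src the
## founder-haplotype column providing alleles on (ends[i-1], ends[i]].

.cutSegments <- function(ends, src, from, to) {
  js <- which(ends > from)[1L]
  je <- which(ends >= to)[1L]
  segEnds <- ends[js:je]
  segEnds[length(segEnds)] <- to
  list(ends = segEnds, src = src[js:je])
}

.gamete <- function(hapA, hapB, chromLen) {
  lapply(seq_along(chromLen), function(ci) {
    len <- chromLen[ci]
    nx <- rpois(1L, len / MORGAN_BP)
    cur <- sample.int(2L, 1L)
    if (nx == 0L) {
      return(if (cur == 1L) hapA[[ci]] else hapB[[ci]])
    }
    bounds <- c(0, sort(runif(nx, 0, len)), len)
    ends <- numeric(0); src <- integer(0)
    for (k in seq_len(length(bounds) - 1L)) {
      h <- if (cur == 1L) hapA[[ci]] else hapB[[ci]]
      piece <- .cutSegments(h$ends, h$src, bounds[k], bounds[k + 1L])
      ends <- c(ends, piece$ends); src <- c(src, piece$src)
      cur <- 3L - cur
    }
    keep <- c(src[-1L] != src[-length(src)], TRUE)  # compact equal-source runs
    list(ends = ends[keep], src = src[keep])
  })
}

#' Simulate forward-in-time admixture with tracked ancestry tracts
#'
#' Founds a closed population from the three ancestral pools (each founder is
#' a pure individual from one pool, pools drawn with probability
#' \code{proportions}) and random-mates it for the requested number of
#' non-overlapping generations. Crossovers per meiosis per chromosome are
#' Poisson with mean equal to the chromosome length in Morgans at
#' 1 Morgan = 100 Mbp (Haldane, no interference). The returned ancestry is
#' the true tract ancestry of every allele; tract boundaries are the actual
#' crossover positions.
#'
#' Per-animal generation depths (a vector in \code{generations}) yield a
#' mixed cohort of recent crosses and deep inter-se animals: animals of depth
#' g are drawn without replacement from the generation-g population.
#'
#' @param founders named list of IND/AFT/EUT [HaplotypePanel-class] objects
#'   on a shared SNP grid (see [simulateFounderHaplotypes()]).
#' @param nAnimals number of admixed animals to return.
#' @param proportions named founding-pool probabilities (IND, AFT, EUT);
#'   the default mirrors a heavily European-taurine dairy admixture.
#' @param generations scalar or per-animal integer vector (>= 1).
#' @param popSize per-generation population size (>= animals drawn from any
#'   one generation); default \code{nAnimals}.
#' @param backcross optional \code{list(n =, sires =, pool = "EUT")}:
#'   appends \code{n} recent backcross animals, each carrying one gamete
#'   from one of \code{sires} pure-pool sire individuals (the recurrent-
#'   introgression pattern of AI matings to a few imported bulls) and one
#'   gamete from the final admixed generation. These animals are labelled
#'   generation 1; paternal half-sibs share long intact sire segments.
#' @param seed integer seed.
#' @return list with elements \code{panel} ([HaplotypePanel-class]),
#'   \code{ancestry} ([AncestryMatrix-class]), \code{tracts} (per haplotype,
#'   per chromosome, data.frame \code{start}/\code{end}/\code{pool} of true
#'   ancestry tracts, half-open \code{(start, end]} bp), and
#'   \code{generations} (per-animal depth).
#' @export
simulateAdmixture <- function(founders, nAnimals,
                              proportions = c(IND = 0.24, AFT = 0.03, EUT = 0.73),
                              generations = 10L, popSize = NULL,
                              backcross = NULL, seed = 1L) {
  stopifnot(all(POOLS %in% names(founders)))
  ref <- founders[[1L]]
  for (p in founders[-1L]) {
    if (!identical(p@chrom, ref@chrom) || !identical(p@pos, ref@pos)) {
      stop("founder pools must share one SNP grid")
    }
  }
  proportions <- proportions[POOLS] / sum(proportions[POOLS])
  if (any(generations < 1L)) stop("generations must be >= 1")
  gvec <- if (length(generations) == 1L) rep(as.integer(generations), nAnimals)
          else as.integer(generations)
  if (length(gvec) != nAnimals) stop("generations must be scalar or length nAnimals")
  N <- if (is.null(popSize)) nAnimals else popSize
  gmax <- max(gvec)
  for (g in unique(gvec)) {
    if (sum(gvec == g) > N) stop("more animals requested from one generation than popSize")
  }

  chromIds <- unique(ref@chrom)
  chromLen <- vapply(chromIds, function(ch) max(ref@pos[ref@chrom == ch]), 0)
  F <- do.call(cbind, lapply(founders[POOLS], function(p) p@alleles))
  poolOfHap <- rep(POOLS, vapply(founders[POOLS], nHaplotypes, 0L))
  poolCols <- split(seq_along(poolOfHap), poolOfHap)

  withr::with_seed(seed, {
    newHap <- function(src) lapply(seq_along(chromLen), function(ci)
      list(ends = chromLen[ci], src = src))
    pop <- lapply(seq_len(N), function(i) {
      pool <- sample(POOLS, 1L, prob = proportions)
      srcs <- sample(poolCols[[pool]], 2L, replace = TRUE)
      list(newHap(srcs[1L]), newHap(srcs[2L]))
    })
    gens <- vector("list", gmax)
    for (g in seq_len(gmax)) {
      pop <- lapply(seq_len(N), function(i) {
        par <- sample.int(N, 2L, replace = FALSE)
        list(.gamete(pop[[par[1L]]][[1L]], pop[[par[1L]]][[2L]], chromLen),
             .gamete(pop[[par[2L]]][[1L]], pop[[par[2L]]][[2L]], chromLen))
      })
      gens[[g]] <- pop
    }

    chosen <- vector("list", nAnimals)
    for (g in unique(gvec)) {
      who <- which(gvec == g)
      pick <- sample.int(N, length(who))
      chosen[who] <- gens[[g]][pick]
    }
    if (!is.null(backcross)) {
      pool <- if (is.null(backcross$pool)) "EUT" else backcross$pool
      sires <- lapply(seq_len(backcross$sires), function(i) {
        srcs <- sample(poolCols[[pool]], 2L, replace = TRUE)
        list(newHap(srcs[1L]), newHap(srcs[2L]))
      })
      bc <- lapply(seq_len(backcross$n), function(i) {
        sire <- sires[[sample.int(length(sires), 1L)]]
        dam <- gens[[gmax]][[sample.int(N, 1L)]]
        list(.gamete(sire[[1L]], sire[[2L]], chromLen),
             .gamete(dam[[1L]], dam[[2L]], chromLen))
      })
      chosen <- c(chosen, bc)
      gvec <- c(gvec, rep(1L, backcross$n))
      nAnimals <- nAnimals + backcross$n
    }

    nsnp <- nSnps(ref)
    alleleM <- matrix(0L, nsnp, 2L * nAnimals)
    labelM <- matrix("", nsnp, 2L * nAnimals)
    tracts <- vector("list", 2L * nAnimals)
    snpIdxByChrom <- split(seq_len(nsnp), factor(ref@chrom, levels = chromIds))
    for (a in seq_len(nAnimals)) {
      for (h in 1:2) {
        col <- 2L * (a - 1L) + h
        tr <- vector("list", length(chromIds))
        for (ci in seq_along(chromIds)) {
          seg <- chosen[[a]][[h]][[ci]]
          rows <- snpIdxByChrom[[ci]]
          j <- findInterval(ref@pos[rows], seg$ends, left.open = TRUE) + 1L
          srcAt <- seg$src[j]
          alleleM[rows, col] <- F[cbind(rows, srcAt)]
          labelM[rows, col] <- poolOfHap[srcAt]
          pools <- poolOfHap[seg$src]
          r <- rle(pools)
          cend <- seg$ends[cumsum(r$lengths)]
          tr[[ci]] <- data.frame(start = c(0, cend[-length(cend)]),
                                 end = cend, pool = r$values)
        }
        names(tr) <- chromIds
        tracts[[col]] <- tr
      }
    }
    ids <- paste0("A", seq_len(nAnimals))
    animalID <- rep(ids, each = 2L)
    colnames(alleleM) <- paste0(animalID, "_h", rep(1:2, nAnimals))
    list(panel = HaplotypePanel(alleleM, ref@chrom, ref@pos, ref@snpID, animalID),
         ancestry = AncestryMatrix(labelM, ref@chrom, ref@pos, ref@snpID, animalID),
         tracts = setNames(tracts, colnames(alleleM)),
         generations = setNames(gvec, ids))
  })
}

#' Inject a selective sweep into a haplotype panel
#'
#' Copies a randomly chosen donor haplotype's alleles, over a flank of
#' \code{halfWidthBp} either side of the core SNP, onto randomly chosen
#' recipient haplotypes until the carrier frequency of the donor's flank
#' haplotype reaches \code{targetFreq}. This manufactures the extended block
#' of identical haplotypes (high LD, low variation) that EHH-based scans are
#' designed to detect. Alleles outside the flank are untouched.
#'
#' @param panel a [HaplotypePanel-class].
#' @param chrom chromosome of the core SNP.
#' @param coreSnp index of the core SNP within that chromosome.
#' @param targetFreq target carrier frequency in (0, 1].
#' @param halfWidthBp flank half-width in bp.
#' @param haps optional haplotype-column subset the sweep acts on (donor,
#'   recipients and the carrier-frequency target). Selection operates on the
#'   established admixed population, so passing the haplotypes of deep
#'   inter-se animals emulates a post-admixture sweep that recently
#'   introduced genomes have not been exposed to; default all haplotypes.
#' @param seed integer seed.
#' @return list: \code{panel} (modified panel), \code{coreIndex} (global SNP
#'   index), \code{coreAllele} (donor allele at the core), \code{flank}
#'   (global indices of homogenised SNPs), \code{carriers} (haplotype columns
#'   carrying the swept flank).
#' @export
injectSweep <- function(panel, chrom, coreSnp, targetFreq, halfWidthBp,
                        haps = NULL, seed = 1L) {
  if (targetFreq <= 0 || targetFreq > 1) stop("targetFreq must be in (0, 1]")
  if (halfWidthBp <= 0) stop("halfWidthBp must be > 0")
  onChr <- which(panel@chrom == chrom)
  if (!length(onChr)) stop("no such chromosome: ", chrom)
  if (is.null(coreSnp)) {
    # a sweep rises from an initially rare haplotype: default core is the SNP
    # nearest the chromosome centre whose minor allele is rare (so the core
    # allele tags the swept flank cleanly)
    sub <- if (is.null(haps)) panel@alleles[onChr, , drop = FALSE]
           else panel@alleles[onChr, haps, drop = FALSE]
    fr <- rowMeans(sub)
    mafOk <- which(pmin(fr, 1 - fr) <= 0.1 & pmin(fr, 1 - fr) > 0)
    if (!length(mafOk)) stop("no rare-minor-allele SNP available for a core")
    centre <- mean(range(panel@pos[onChr]))
    coreSnp <- mafOk[which.min(abs(panel@pos[onChr][mafOk] - centre))]
  }
  if (coreSnp < 1L || coreSnp > length(onChr)) stop("core SNP outside chromosome")
  core <- onChr[coreSnp]
  corePos <- panel@pos[core]
  if (corePos - halfWidthBp < min(panel@pos[onChr]) ||
      corePos + halfWidthBp > max(panel@pos[onChr])) {
    warning("sweep flank truncated at chromosome end")
  }
  flank <- onChr[abs(panel@pos[onChr] - corePos) <= halfWidthBp]
  m <- panel@alleles
  if (is.null(haps)) haps <- seq_len(ncol(m))
  nh <- length(haps)
  withr::with_seed(seed, {
    minorAllele <- as.integer(mean(m[core, haps]) < 0.5)
    minorCarriers <- haps[m[core, haps] == minorAllele]
    if (!length(minorCarriers)) stop("core SNP is monomorphic")
    # the favoured haplotype rides the minor allele, as a real partial sweep
    # of a derived allele would; the core allele then tags the swept flank
    donor <- minorCarriers[sample.int(length(minorCarriers), 1L)]
    donorSeq <- m[flank, donor]
    isCarrier <- colSums(m[flank, haps, drop = FALSE] != donorSeq) == 0L
    targetCount <- round(targetFreq * nh)
    if (sum(isCarrier) > targetCount) {
      stop("target carrier frequency below current carrier frequency")
    }
    if (sum(isCarrier) < targetCount) {
      recip <- sample(haps[!isCarrier], targetCount - sum(isCarrier))
      m[flank, recip] <- donorSeq
      isCarrier <- colSums(m[flank, haps, drop = FALSE] != donorSeq) == 0L
    }
    out <- panel
    out@alleles <- m
    list(panel = out, coreIndex = core, coreAllele = donorSeq[match(core, flank)],
         flank = flank, carriers = haps[isCarrier])
  })
}

#' Simulate repeated-record phenotypes under the dual-effect mixed model
#'
#' Generates milk-yield-deviation-like records
#' \eqn{y = \mu + X\beta + Wu + Wpe + e}: per-QTL contributions from the
#' ancestral-origin effect (per EUT-origin allele copy) and the residual
#' allele effect (per alternate-allele copy), an animal polygenic value with
#' covariance \eqn{\sigma^2_g G}, an iid permanent-environment value per
#' animal, and an iid residual per record.
#'
#' @param panel a [HaplotypePanel-class].
#' @param ancestry the aligned [AncestryMatrix-class].
#' @param qtl data.frame with columns \code{snp} (global SNP index),
#'   \code{originEffect}, \code{alleleEffect}; NULL for a pure null.
#' @param varcomp list with \code{sigma2g}, \code{sigma2pe}, \code{sigma2e}
#'   (all >= 0) and \code{records} (records per animal, scalar or vector).
#' @param grm [GRM-class] over the panel's animals (needed when
#'   \code{sigma2g > 0}).
#' @param mu overall mean.
#' @param seed integer seed.
#' @return data.frame \code{animal_id}, \code{record_id}, \code{value}.
#' @export
simulatePhenotypes <- function(panel, ancestry, qtl = NULL,
                               varcomp = list(sigma2g = 1, sigma2pe = 0.5,
                                              sigma2e = 1, records = 3L),
                               grm = NULL, mu = 0, seed = 1L) {
  ids <- animals(panel)
  q <- length(ids)
  recs <- varcomp$records
  if (is.null(recs)) recs <- 1L
  if (length(recs) == 1L) recs <- rep(as.integer(recs), q)
  if (any(recs < 1L)) stop("at least one record per animal")
  gval <- rep(0, q)
  genetic <- rep(0, q)
  if (!is.null(qtl) && nrow(qtl)) {
    if (any(qtl$snp < 1L | qtl$snp > nSnps(panel))) stop("QTL locus absent from panel")
    dOrig <- eutDosage(ancestry)
    dAll <- alleleDosage(panel)
    for (k in seq_len(nrow(qtl))) {
      s <- qtl$snp[k]
      oe <- if (is.null(qtl$originEffect)) 0 else qtl$originEffect[k]
      ae <- if (is.null(qtl$alleleEffect)) 0 else qtl$alleleEffect[k]
      if (!is.finite(oe) || !is.finite(ae)) stop("QTL effects must be finite")
      genetic <- genetic + oe * dOrig[s, ids] + ae * dAll[ids, s]
    }
  }
  withr::with_seed(seed, {
    if (varcomp$sigma2g > 0) {
      if (is.null(grm)) stop("grm required when sigma2g > 0")
      G <- grmValues(grm)[ids, ids]
      L <- chol(G + diag(1e-8, q))
      gval <- sqrt(varcomp$sigma2g) * drop(crossprod(L, rnorm(q)))
    }
    pe <- if (varcomp$sigma2pe > 0) rnorm(q, 0, sqrt(varcomp$sigma2pe)) else rep(0, q)
    n <- sum(recs)
    aIdx <- rep(seq_len(q), recs)
    e <- if (varcomp$sigma2e > 0) rnorm(n, 0, sqrt(varcomp$sigma2e)) else rep(0, n)
    data.frame(
      animal_id = ids[aIdx],
      record_id = unlist(lapply(recs, seq_len)),
      value = mu + genetic[aIdx] + gval[aIdx] + pe[aIdx] + e,
      stringsAsFactors = FALSE
    )
  })
}

#' One-call simulation of a complete admixed cohort
#'
#' Convenience wrapper: frequencies, founder pools, admixture. Used by the
#' examples, the test fixtures and the pipeline's simulate stage.
#'
#' @param nSnps SNPs per chromosome.
#' @param nChrom number of chromosomes.
#' @param spacingBp distance between adjacent SNPs (bp).
#' @param nAnimals admixed cohort size.
#' @param nHapPerPool founder haplotypes per ancestral pool.
#' @param proportions,generations,popSize,backcross passed to
#'   [simulateAdmixture()].
#' @param fst per-pool drift, passed to [sampleAncestralFreqs()].
#' @param blockSize,nPrototypes founder LD blocks, passed to
#'   [simulateFounderHaplotypes()].
#' @param seed integer seed; internal stages derive distinct sub-seeds.
#' @return as [simulateAdmixture()], plus \code{founders} and \code{map}.
#' @export
simulateCohort <- function(nSnps = 500L, nChrom = 2L, spacingBp = 1e5,
                           nAnimals = 100L, nHapPerPool = 60L,
                           proportions = c(IND = 0.24, AFT = 0.03, EUT = 0.73),
                           generations = 10L, popSize = NULL, backcross = NULL,
                           fst = c(IND = 0.2, AFT = 0.1, EUT = 0.1),
                           blockSize = NULL, nPrototypes = 4L, seed = 1L) {
  map <- data.frame(
    chrom = rep(paste0("chr", seq_len(nChrom)), each = nSnps),
    pos = rep(seq_len(nSnps) * spacingBp, nChrom)
  )
  freqs <- sampleAncestralFreqs(nrow(map), fst = fst, seed = seed)
  founders <- simulateFounderHaplotypes(freqs, map, nHapPerPool, seed = seed + 1L,
                                        blockSize = blockSize,
                                        nPrototypes = nPrototypes)
  sim <- simulateAdmixture(founders, nAnimals, proportions, generations,
                           popSize, backcross = backcross, seed = seed + 2L)
  c(sim, list(founders = founders, map = map))
}
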