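test_that("ancestral frequency tables follow the Balding-Nichols drift model", {
  # zero drift: the pools coincide with the base frequencies
  f0 <- sampleAncestralFreqs(50, fst = c(IND = 0, AFT = 0, EUT = 0), seed = 1)
  expect_identical(f0$IND, f0$base)
  expect_identical(f0$EUT, f0$base)

  # Beta variance p(1-p)Fst at base 0.5, Fst 0.2 -> 0.05
  f <- sampleAncestralFreqs(10000, baseRange = c(0.5, 0.5),
                            fst = c(IND = 0.2, AFT = 0, EUT = 0), seed = 2)
  expect_equal(var(f$IND), 0.5 * 0.5 * 0.2, tolerance = 0.05)
  expect_equal(mean(f$IND), 0.5, tolerance = 0.01)

  # determinism and bounds
  expect_identical(sampleAncestralFreqs(100, seed = 7),
                   sampleAncestralFreqs(100, seed = 7))
  expect_true(all(f$IND >= 0 & f$IND <= 1))
  expect_error(sampleAncestralFreqs(10, fst = c(IND = 1, AFT = 0, EUT = 0)))
  expect_error(sampleAncestralFreqs(0))
})

test_that("founder haplotypes sample the drifted pool frequencies", {
  map <- data.frame(chrom = "c1", pos = seq_len(60) * 1e5)
  fr <- sampleAncestralFreqs(60, seed = 3)
  fr$IND[1] <- 1  # degenerate frequency
  pools <- simulateFounderHaplotypes(fr, map, nHapPerPool = 1000L, seed = 4)
  expect_true(all(alleles(pools$IND)[1, ] == 1L))

  # binomial 99% interval at the drifted frequency, 1000 haplotypes
  for (pool in c("IND", "AFT", "EUT")) {
    p <- fr[[pool]][10]
    obs <- mean(alleles(pools[[pool]])[10, ])
    expect_lt(abs(obs - p), 2.58 * sqrt(p * (1 - p) / 1000) + 1e-12)
  }

  # realised differentiation matches the drift parameter: for two pools with
  # the same Fst the expected squared frequency contrast is 2 p(1-p) Fst
  frF <- sampleAncestralFreqs(4000, baseRange = c(0.3, 0.7),
                              fst = c(IND = 0.4, AFT = 0.4, EUT = 0), seed = 5)
  pls <- simulateFounderHaplotypes(frF, data.frame(chrom = "c1", pos = seq_len(4000) * 1e5),
                                   nHapPerPool = 500L, seed = 6)
  p1 <- rowMeans(alleles(pls$IND)); p2 <- rowMeans(alleles(pls$AFT))
  # E[(p1 - p2)^2] = 2 F p(1-p) for two pools drifting independently at F
  fstHat <- mean((p1 - p2)^2) / mean(2 * frF$base * (1 - frF$base))
  expect_equal(fstHat, 0.4, tolerance = 0.05)
})

test_that("block-LD founders keep the pool allele frequencies", {
  map <- data.frame(chrom = "c1", pos = seq_len(200) * 1e5)
  fr <- sampleAncestralFreqs(200, seed = 11)
  pools <- simulateFounderHaplotypes(fr, map, nHapPerPool = 600L, seed = 12,
                                     blockSize = 20L, nPrototypes = 4L)
  # prototypes add block variance per SNP but leave expected frequencies
  obs <- rowMeans(alleles(pools$EUT))
  expect_lt(abs(mean(obs) - mean(fr$EUT)), 0.03)
  expect_gt(cor(obs, fr$EUT), 0.7)
})

test_that("forward admixture produces single-ancestry F1 tracts and the target mix", {
  sim <- sharedSim()
  # deterministic given seed
  sim2 <- simulateCohort(nSnps = 120L, nChrom = 2L, spacingBp = 1e5,
                         nAnimals = 60L, nHapPerPool = 80L,
                         proportions = c(IND = 0.25, AFT = 0.05, EUT = 0.7),
                         generations = 8L, popSize = 120L, seed = 1234L)
  expect_identical(alleles(sim$panel), alleles(sim2$panel))
  expect_identical(ancestryLabels(sim$ancestry), ancestryLabels(sim2$ancestry))

  # F1 haplotypes carry intact single-ancestry chromosomes
  f1 <- simulateAdmixture(sim$founders, 20L, generations = 1L, seed = 2L)
  for (h in seq_len(8)) {
    for (ch in chroms(f1$panel)) {
      expect_length(unique(f1$tracts[[h]][[ch]]$pool), 1L)
    }
  }

  # cohort mean EUT ancestry approaches the admixture-proportion target
  big <- simulateCohort(nSnps = 60L, nChrom = 1L, nAnimals = 250L,
                        nHapPerPool = 200L,
                        proportions = c(IND = 0.25, AFT = 0.05, EUT = 0.7),
                        generations = 3L, seed = 31L)
  expect_equal(unname(globalProportions(big$ancestry)$cohort["EUT"]), 0.7,
               tolerance = 0.06)

  # ancestry labels equal the tract projection at every SNP (tracts are the
  # ground truth the matrix is derived from; both paths must agree exactly)
  l <- ancestryLabels(sim$ancestry)
  for (h in c(1L, 33L, 120L)) {
    for (ch in chroms(sim$panel)) {
      idx <- which(sim$panel@chrom == ch)
      tr <- sim$tracts[[h]][[ch]]
      lab <- tr$pool[findInterval(sim$panel@pos[idx], tr$end,
                                  left.open = TRUE) + 1L]
      expect_identical(unname(l[idx, h]), lab)
    }
  }
})

test_that("crossover accumulation grows with generation depth", {
  sim <- sharedSim()
  shallow <- simulateAdmixture(sim$founders, 40L,
                               proportions = c(IND = 0.5, AFT = 0, EUT = 0.5),
                               generations = 2L, popSize = 80L, seed = 55L)
  deep <- simulateAdmixture(sim$founders, 40L,
                            proportions = c(IND = 0.5, AFT = 0, EUT = 0.5),
                            generations = 10L, popSize = 80L, seed = 55L)
  nj <- function(sim) mean(vapply(sim$tracts, function(tr)
    sum(vapply(tr, nrow, 0L) - 1L), 0))
  expect_gt(nj(deep), nj(shallow))
})

test_that("backcross animals carry one intact pure sire haplotype", {
  sim <- sharedSim()
  bc <- simulateAdmixture(sim$founders, 10L, generations = 6L, popSize = 40L,
                          backcross = list(n = 12L, sires = 2L, pool = "EUT"),
                          seed = 77L)
  expect_identical(unname(bc$generations),
                   c(rep(6L, 10L), rep(1L, 12L)))
  # the sire gamete is all-EUT
  bcHaps <- which(bc$panel@animalID %in% names(bc$generations)[bc$generations == 1L])
  sireCols <- bcHaps[seq(1L, length(bcHaps), by = 2L)]
  expect_true(all(ancestryLabels(bc$ancestry)[, sireCols] == "EUT"))
})

test_that("sweep injection reaches the target carrier count and raises EHH", {
  pan <- randomPanel(80, 100, seed = 9)
  sw <- injectSweep(pan, "c1", 40L, targetFreq = 0.6, halfWidthBp = 1e6,
                    seed = 10)
  flank <- sw$flank
  donorSeq <- alleles(sw$panel)[flank, sw$carriers[1]]
  share <- colSums(alleles(sw$panel)[flank, , drop = FALSE] != donorSeq) == 0
  expect_identical(sum(share), 60L)

  # EHH of the swept allele at the core never decreases within the flank
  for (t in c(38L, 42L, 36L, 44L)) {
    before <- bruteEHH(pan, 40L, alleles(sw$panel)[40L, sw$carriers[1]], t)
    after <- bruteEHH(sw$panel, 40L, alleles(sw$panel)[40L, sw$carriers[1]], t)
    expect_gte(after, before - 1e-12)
  }

  # a target equal to the current carrier frequency is a no-op: build a
  # panel where every minor-allele carrier already shares one haplotype
  m2 <- alleles(randomPanel(80, 100, seed = 13))
  m2[, 1:30] <- m2[, 1]
  m2[40, 1:30] <- 1L; m2[40, 31:100] <- 0L
  pan2 <- matPanel(m2)
  sw2 <- injectSweep(pan2, "c1", 40L, targetFreq = 0.3, halfWidthBp = 1e6,
                     seed = 11)
  expect_identical(alleles(sw2$panel), alleles(pan2))
  # and a lower one is an error
  expect_error(injectSweep(pan2, "c1", 40L, targetFreq = 0.1,
                           halfWidthBp = 1e6, seed = 12),
               "below current")
})

test_that("phenotype simulation follows the dual-effect repeated-record model", {
  l <- matrix("IND", 4, 6)
  l[, 5:6] <- "EUT"               # animal 3 is EUT/EUT everywhere
  anc <- matAncestry(l)
  m <- matrix(0L, 4, 6)
  pan <- matPanel(m, spacing = 1e6)
  qtl <- data.frame(snp = 2L, originEffect = 0.5, alleleEffect = 0)
  ph <- simulatePhenotypes(pan, anc, qtl = qtl,
                           varcomp = list(sigma2g = 0, sigma2pe = 0,
                                          sigma2e = 0, records = 1L),
                           seed = 1)
  # EUT/EUT scores exactly 2 x 0.5 = 1.0 above IND/IND, no noise
  expect_equal(ph$value[3] - ph$value[1], 1.0)

  # residual-only variance: chi-square interval at 10,000 records
  ph2 <- simulatePhenotypes(pan, anc, qtl = NULL,
                            varcomp = list(sigma2g = 0, sigma2pe = 0,
                                           sigma2e = 1, records = 3334L),
                            seed = 2)
  expect_equal(var(ph2$value), 1, tolerance = 0.05)

  # permanent environment with no residual: records repeat exactly
  ph3 <- simulatePhenotypes(pan, anc, qtl = NULL,
                            varcomp = list(sigma2g = 0, sigma2pe = 0.5,
                                           sigma2e = 0, records = 3L),
                            seed = 3)
  within <- tapply(ph3$value, ph3$animal_id, function(v) diff(range(v)))
  expect_true(all(within == 0))

  expect_error(simulatePhenotypes(pan, anc,
                                  qtl = data.frame(snp = 99L, originEffect = 1,
                                                   alleleEffect = 0),
                                  varcomp = list(sigma2g = 0, sigma2pe = 0,
                                                 sigma2e = 1, records = 1L)),
               "absent")
})
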