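test_that("allele polarisation follows the pooled majority with a tie rule", {
  m <- rbind(c(1, 1, 1, 0, 0, 1, 1, 1, 0, 1),   # freq 0.7 -> allele 1 ancestral
             c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))   # exact tie -> allele 0
  pan <- matPanel(m)
  expect_warning(pol <- polarizeAlleles(pan), "50/50")
  expect_identical(pol$ancestral, c(1L, 0L))
  expect_identical(pol$derived, c(0L, 1L))

  # invariant to haplotype ordering
  pan2 <- matPanel(m[, 10:1])
  expect_identical(suppressWarnings(polarizeAlleles(pan2))$ancestral,
                   pol$ancestral)
})

test_that("EHH matches hand-worked identical-pair counts", {
  # carriers extend over haplotypes {00, 00, 01, 11}: 1 identical pair of 6
  pan <- matPanel(rbind(c(1, 1, 1, 1),
                        c(0, 0, 0, 1),
                        c(0, 0, 1, 1)))
  cv <- ehhCurve(pan, 1L, 1L, decay = 0)
  expect_equal(cv$right$ehh[2], 2 / 12)
  # at the first extension haplotypes are {0,0,0,1}: 3 identical pairs of 6
  expect_equal(cv$right$ehh[1], 6 / 12)

  # complete homozygosity and complete heterogeneity
  panHom <- matPanel(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_equal(ehhCurve(panHom, 1L, 1L, decay = 0)$right$ehh, c(1, 1))
  expect_error(ehhCurve(matPanel(rbind(c(1, 0, 0, 0), c(0, 1, 0, 1))), 1L, 1L),
               "fewer than 2")
})

test_that("EHH equals the brute-force pair-counting oracle on random panels", {
  for (rep in 1:30) {
    pan <- randomPanel(nsnp = sample(5:25, 1), nhap = sample(4:16, 1),
                       seed = 1000 + rep)
    m <- alleles(pan)
    core <- sample(nSnps(pan), 1)
    for (al in 0:1) {
      if (sum(m[core, ] == al) < 2) next
      cv <- ehhCurve(pan, core, al, decay = 0)
      for (k in seq_len(nrow(cv$right))) {
        t <- core + k
        expect_equal(cv$right$ehh[k], bruteEHH(pan, core, al, t),
                     tolerance = 1e-12)
      }
      for (k in seq_len(nrow(cv$left))) {
        expect_equal(cv$left$ehh[k], bruteEHH(pan, core, al, core - k),
                     tolerance = 1e-12)
      }
      # monotone non-increasing away from the core
      expect_true(all(diff(cv$right$ehh) <= 1e-12))
      expect_true(all(diff(cv$left$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integrates to the interpolated decay crossing", {
  # one-sided curve (0 M, 1.0) -> (0.01 M, 0.04), threshold 0.05:
  # crossing at 0.01 * (1 - 0.05) / (1 - 0.04); trapezoid to the crossing
  cur <- list(left = data.frame(pos = numeric(0), ehh = numeric(0)),
              right = data.frame(pos = 1e6, ehh = 0.04), corePos = 0)
  xc <- 0.01 * 0.95 / 0.96
  expect_equal(ihh(cur, 0.05)$ihh, xc * (1 + 0.05) / 2, tolerance = 1e-12)

  # EHH that stays 1 to the chromosome end: rectangle, flagged truncated
  cur2 <- list(left = data.frame(pos = numeric(0), ehh = numeric(0)),
               right = data.frame(pos = c(1e6, 2e6), ehh = c(1, 1)),
               corePos = 0)
  r2 <- ihh(cur2, 0.05)
  expect_equal(r2$ihh, 0.02)
  expect_true(r2$truncated)

  # linearity in the abscissa: halving map distances halves the integral
  cur3 <- list(left = cur2$left,
               right = data.frame(pos = c(5e5, 1e6), ehh = c(1, 1)),
               corePos = 0)
  expect_equal(ihh(cur3, 0.05)$ihh, 0.01)
})

test_that("raw iHS is the log ratio of the two allele integrals", {
  pan <- randomPanel(40, 30, seed = 3000)
  pol <- suppressWarnings(polarizeAlleles(pan))
  raw <- ihsScan(pan, pol, maf = 0.05)
  s <- which(!is.na(raw$ihs_raw))[1]
  core <- match(raw$snp_id[s], pan@snpID)
  ia <- ihh(ehhCurve(pan, core, pol$ancestral[core]))$ihh
  id <- ihh(ehhCurve(pan, core, pol$derived[core]))$ihh
  expect_equal(raw$ihs_raw[s], log(ia / id), tolerance = 1e-12)
  # sub-MAF SNPs are excluded
  f1 <- rowMeans(alleles(pan))
  expect_true(all(pmin(f1, 1 - f1)[match(raw$snp_id, pan@snpID)] > 0.05))
})

test_that("frequency-bin standardisation has exact moments and Gaussian p", {
  # population-SD convention on {1, 2, 3}
  raw <- data.frame(chrom = "c1", pos = 1:60 * 1e5, snp_id = paste0("s", 1:60),
                    derived_freq = rep(c(0.2, 0.4), each = 30),
                    ihh_a = 1, ihh_d = 1,
                    ihs_raw = rnorm(60), truncated = FALSE)
  raw$ihs_raw[1:3] <- c(1, 2, 3)
  sc <- standardizeIhs(raw, minBin = 5L)
  tab <- as.data.frame(sc)
  for (b in unique(tab$bin)) {
    z <- tab$stat_std[tab$bin == b]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-10)
  }

  # the two-sided Gaussian transform: z = 0 -> 0; z = +/-1.959964 -> 1.30103
  raw3 <- raw[1:3, ]; raw3$ihs_raw <- c(1, 2, 3)
  expect_equal(admixscan:::.neglog10pGauss(0), 0)
  expect_equal(admixscan:::.neglog10pGauss(1.959964), 1.30103, tolerance = 1e-4)
  expect_equal(admixscan:::.neglog10pGauss(-1.959964),
               admixscan:::.neglog10pGauss(1.959964))

  # hand z-scores within one bin
  one <- data.frame(chrom = "c1", pos = 1:3 * 1e5, snp_id = paste0("s", 1:3),
                    derived_freq = 0.3, ihh_a = 1, ihh_d = 1,
                    ihs_raw = c(1, 2, 3), truncated = FALSE)
  z <- as.data.frame(standardizeIhs(one, minBin = 1L))$stat_std
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
})

test_that("EHHS matches the corrected-heterozygosity oracle and iES integrates", {
  # six-haplotype toy: integrate the brute-force EHHS values with an
  # independent trapezoid (same decay rule) and compare against ies()
  pan <- matPanel(rbind(c(1, 1, 1, 0, 0, 0),
                        c(1, 0, 1, 0, 1, 0),
                        c(1, 1, 0, 0, 0, 1),
                        c(0, 1, 1, 1, 0, 0),
                        c(1, 0, 0, 1, 1, 0)), spacing = 2e5)
  core <- 3L
  oracleSide <- function(ts) {
    v <- c(1, vapply(ts, function(t) bruteEHHS(pan, core, t), 0))
    x <- c(0, abs(pan@pos[ts] - pan@pos[core])) / 1e8
    below <- which(v < 0.05)
    if (length(below)) {
      k <- below[1]
      frac <- (v[k - 1] - 0.05) / (v[k - 1] - v[k])
      x <- c(x[seq_len(k - 1)], x[k - 1] + frac * (x[k] - x[k - 1]))
      v <- c(v[seq_len(k - 1)], 0.05)
    }
    sum(diff(x) * (head(v, -1) + tail(v, -1)) / 2)
  }
  expect_equal(ies(pan, core)$ies, oracleSide(4:5) + oracleSide(2:1),
               tolerance = 1e-12)

  # all haplotypes identical over a 0.01 M flank: one-sided contribution 0.01
  panSame <- matPanel(rbind(c(1, 1, 1, 0, 0, 0),
                            matrix(rep(c(1, 1, 1, 0, 0, 0), 2),
                                   nrow = 2, byrow = TRUE)),
                      spacing = 5e5)
  r <- ies(panSame, 1L)
  expect_equal(r$ies, 0.01)
  expect_true(r$truncated)

  # monomorphic core is skipped
  panMono <- matPanel(rbind(c(1, 1, 1, 1), c(0, 1, 0, 1)))
  expect_true(is.na(ies(panMono, 1L)$ies))
})

test_that("Rsb is centred and null for identical panels", {
  pan <- randomPanel(50, 24, seed = 5000)
  r0 <- rsbScan(pan, pan)
  expect_true(all(as.data.frame(r0)$stat_raw == 0))

  panB <- randomPanel(50, 24, seed = 5001)
  r <- suppressMessages(rsbScan(pan, panB))
  tab <- as.data.frame(r)
  expect_equal(median(tab$stat_std), 0, tolerance = 1e-12)
  expect_true(all(tab$p > 0 & tab$p <= 1))
})
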