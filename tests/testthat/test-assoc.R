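# a small repeated-records phenotype world shared within this file
assocWorld <- function(nAnimals = 120L, qtl = NULL, sg = 1, seed = 61L) {
  sim <- simulateCohort(nSnps = 60L, nChrom = 2L, spacingBp = 2e5,
                        nAnimals = nAnimals, nHapPerPool = 150L,
                        generations = 10L, popSize = max(nAnimals, 150L),
                        seed = seed)
  grm <- buildGRM(alleleDosage(sim$panel), chrom = sim$panel@chrom)
  ph <- simulatePhenotypes(sim$panel, sim$ancestry, qtl = qtl,
                           varcomp = list(sigma2g = sg, sigma2pe = 0.5,
                                          sigma2e = 1, records = 3L),
                           grm = grm, seed = seed + 1L)
  list(sim = sim, grm = grm, ph = ph)
}

test_that("REML recovers variance structure and hits the null-heritability limit", {
  w <- assocWorld(nAnimals = 200L, sg = 1, seed = 41L)
  vc <- fitNullREML(w$ph, w$grm)
  # total animal-level variance and residual recovered; the g/pe split is
  # weakly identified when G is close to I, so it is tested as a sum
  expect_equal(vc@sigma2g + vc@sigma2pe, 1.5, tolerance = 0.45)
  expect_equal(vc@sigma2e, 1, tolerance = 0.25)
  expect_true(vc@converged)

  # pure iid noise: the polygenic component collapses to the boundary
  phNull <- w$ph
  withr::with_seed(42, phNull$value <- rnorm(nrow(phNull)))
  expect_warning(vc0 <- fitNullREML(phNull, w$grm), "boundary")
  expect_lt(vc0@sigma2g, 0.05)
})

test_that("duplicating records shifts variance from the record level", {
  w <- assocWorld(nAnimals = 100L, sg = 1, seed = 43L)
  vc1 <- fitNullREML(w$ph, w$grm)
  dup <- rbind(w$ph, transform(w$ph, record_id = record_id + 100L))
  vc2 <- fitNullREML(dup, w$grm)
  # per-record residual share must not grow when each record is duplicated,
  # while the animal-level components stay consistent
  expect_lte(vc2@sigma2e, vc1@sigma2e * 1.05)
  expect_equal(vc1@sigma2g + vc1@sigma2pe, vc2@sigma2g + vc2@sigma2pe,
               tolerance = 0.35)
})

test_that("GLS recovers exact effects on noise-free data and flags degeneracy", {
  # noise-free: phenotype is exactly mu + 0.4 * origin - 0.3 * allele
  q <- 40L
  withr::with_seed(7, {
    o <- sample(0:2, q, replace = TRUE)
    a <- sample(0:2, q, replace = TRUE)
  })
  ids <- paste0("A", seq_len(q))
  names(o) <- names(a) <- ids
  ph <- data.frame(animal_id = rep(ids, each = 2), record_id = rep(1:2, q),
                   value = rep(1 + 0.4 * o - 0.3 * a, each = 2))
  G <- diag(q); dimnames(G) <- list(ids, ids)
  grm <- new("GRM", values = G, freqs = numeric(0), excludedChrom = NA_character_)
  vc <- new("VarianceComponents", sigma2g = 0.2, sigma2pe = 0.1, sigma2e = 1,
            logLik = 0, excludedChrom = NA_character_, converged = TRUE)
  r <- testSnp(ph, o, a, vc, grm)
  expect_equal(r$origin_effect, 0.4, tolerance = 1e-8)
  expect_equal(r$allele_effect, -0.3, tolerance = 1e-8)

  # an exactly zero GLS estimate gives Wald 0 and p = 1
  y <- c(1, -1, -1, 1)
  o2 <- setNames(c(2, 1, 2, 1), paste0("B", 1:4))  # orthogonal to y
  a2 <- setNames(c(0, 1, 0, 1), paste0("B", 1:4))
  ph2 <- data.frame(animal_id = paste0("B", 1:4), record_id = 1L, value = y)
  G2 <- diag(4); dimnames(G2) <- list(paste0("B", 1:4), paste0("B", 1:4))
  grm2 <- new("GRM", values = G2, freqs = numeric(0), excludedChrom = NA_character_)
  r2 <- testSnp(ph2, o2, a2, vc, grm2)
  expect_equal(r2$origin_effect, 0, tolerance = 1e-10)
  expect_equal(r2$origin_p, 1, tolerance = 1e-8)

  # constant origin dosage: origin not estimable, allele still reported
  o3 <- setNames(rep(2, 4), paste0("B", 1:4))
  r3 <- testSnp(ph2, o3, a2, vc, grm2)
  expect_true(is.na(r3$origin_effect))
  expect_false(is.na(r3$allele_effect))
})

test_that("the GLS engine agrees with a dense matrix-inversion oracle", {
  w <- assocWorld(nAnimals = 40L, sg = 1, seed = 47L)
  vc <- fitNullREML(w$ph, w$grm)
  ids <- unique(w$ph$animal_id)
  W <- outer(w$ph$animal_id, ids, `==`) * 1
  V <- vc@sigma2g * W %*% grmValues(w$grm)[ids, ids] %*% t(W) +
       vc@sigma2pe * tcrossprod(W) + vc@sigma2e * diag(nrow(w$ph))
  s <- 10L
  o <- eutDosage(w$sim$ancestry)[s, ids]
  a <- alleleDosage(w$sim$panel)[ids, s]
  X <- cbind(1, W %*% o, W %*% a)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% w$ph$value)
  se <- sqrt(diag(solve(t(X) %*% Vi %*% X)))
  r <- testSnp(w$ph, o, a, vc, w$grm)
  expect_equal(r$origin_effect, beta[2], tolerance = 1e-8)
  expect_equal(r$allele_effect, beta[3], tolerance = 1e-8)
  expect_equal(r$origin_se, se[2], tolerance = 1e-8)
})

test_that("a strong origin QTL is mapped at its locus and permutation kills it", {
  qtl <- data.frame(snp = 20L, originEffect = 1.2, alleleEffect = 0)
  w <- assocWorld(nAnimals = 120L, qtl = qtl, sg = 0.3, seed = 49L)
  scans <- suppressWarnings(gwaScan(w$ph, w$sim$panel, w$sim$ancestry,
                                    qvalues = FALSE))
  tab <- as.data.frame(scans$origin)
  peak <- tab[which.max(tab$neglog10p), ]
  # broad admixture peaks: the top origin signal sits on the QTL chromosome
  # within a few tract lengths of the causal SNP
  expect_identical(as.character(peak$chrom), "chr1")
  expect_lt(abs(peak$pos - w$sim$panel@pos[20L]), 6e6)
  expect_gt(max(tab$neglog10p, na.rm = TRUE), 3)

  phPerm <- w$ph
  withr::with_seed(50, {
    perm <- sample(unique(w$ph$animal_id))
    names(perm) <- unique(w$ph$animal_id)
    phPerm$animal_id <- perm[w$ph$animal_id]
  })
  scansP <- suppressWarnings(gwaScan(phPerm, w$sim$panel, w$sim$ancestry,
                                     qvalues = FALSE))
  expect_lt(max(as.data.frame(scansP$origin)$neglog10p, na.rm = TRUE),
            max(tab$neglog10p, na.rm = TRUE))
})
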