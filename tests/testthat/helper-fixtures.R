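# fixtures and independent oracles shared across the suite; everything is
# generated in code at test time

.fixtures <- new.env(parent = emptyenv())

# one moderate admixed cohort reused by several files
sharedSim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulateCohort(
      nSnps = 120L, nChrom = 2L, spacingBp = 1e5, nAnimals = 60L,
      nHapPerPool = 80L, proportions = c(IND = 0.25, AFT = 0.05, EUT = 0.7),
      generations = 8L, popSize = 120L, seed = 1234L
    )
  }
  .fixtures$sim
}

# a panel straight from a 0/1 matrix (SNPs x haplotypes, even column count)
matPanel <- function(m, spacing = 1e5, chrom = "c1") {
  HaplotypePanel(m, rep(chrom, nrow(m)), seq_len(nrow(m)) * spacing)
}

randomPanel <- function(nsnp, nhap, seed, spacing = 1e5) {
  if (nhap %% 2L == 1L) nhap <- nhap + 1L
  withr::with_seed(seed, {
    m <- matrix(rbinom(nsnp * nhap, 1L, runif(nsnp, 0.15, 0.85)), nrow = nsnp)
    matPanel(m, spacing)
  })
}

# brute-force EHH oracle: enumerate carrier pairs and count identity over the
# core-to-t extension, independently of the partition-refinement scan
bruteEHH <- function(panel, core, allele, t) {
  m <- alleles(panel)
  carriers <- which(m[core, ] == allele)
  n <- length(carriers)
  rng <- if (t >= core) core:t else t:core
  same <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (all(m[rng, carriers[i]] == m[rng, carriers[j]])) same <- same + 1L
    }
  }
  2 * same / (n * (n - 1))
}

# brute-force EHHS oracle from the printed heterozygosity formulas
bruteEHHS <- function(panel, core, t) {
  m <- alleles(panel)
  ns <- ncol(m)
  rng <- if (t >= core) core:t else t:core
  key <- apply(m[rng, , drop = FALSE], 2L, paste, collapse = "")
  nk <- table(key)
  hst <- ns / (ns - 1) * (1 - sum(nk^2) / ns^2)
  n1 <- sum(m[core, ])
  hs <- ns / (ns - 1) * (1 - (n1^2 + (ns - n1)^2) / ns^2)
  (1 - hst) / (1 - hs)
}

# brute-force Storey q-values: double loop over the definition
bruteQvalues <- function(p, pi0) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(pi0 * m * p[cand] / rk[cand]))
  }, 0)
}

# project true ancestry tracts onto the SNP grid and count EUT/non-EUT
# junctions: the simulator-side oracle for crossover counting
tractJunctions <- function(tracts, chrom, pos) {
  tr <- tracts[[chrom]]
  lab <- tr$pool[findInterval(pos, tr$end, left.open = TRUE) + 1L]
  isE <- lab == "EUT"
  sum(isE[-1L] != isE[-length(isE)])
}

# build an AncestryMatrix from a labels matrix
matAncestry <- function(l, pos = NULL, chrom = "c1") {
  if (is.null(pos)) pos <- seq_len(nrow(l)) * 1e6
  AncestryMatrix(l, rep(chrom, nrow(l)), pos)
}
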