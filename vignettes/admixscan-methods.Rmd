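---
title: "Ancestry-aware association and selection scans in admixed populations"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-aware association and selection scans in admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

Crossbred dairy cattle in East Africa descend from decades of crossing
exotic European taurine (EUT) dairy breeds with indigenous cattle that are
themselves ancient admixtures of *Bos indicus* (IND) and African taurine
(AFT). The resulting population is an unstabilised mosaic: some animals are
recent crosses carrying intact parental chromosomes, others descend from
many generations of inter-se mating and carry finely fragmented ancestry
tracts. `admixscan` implements the analysis toolchain such a population
needs:

* **crossover dating** of each animal's admixture from per-allele local
  ancestry,
* a **dual-effect mixed-model GWAS** that separates the ancestral-origin
  effect of an allele from its residual (within-population LD) effect,
* **haplotype-homozygosity selection scans** within (iHS) and between (Rsb)
  populations,
* **Storey–Tibshirani q-values** and **seed-and-extend candidate-region
  calling**, and
* a **forward simulator** of admixed cohorts with known ancestry tracts, so
  that every stage is testable without any external data.

## The simulator: what world it states

`simulateCohort()` builds a cohort in three steps.

**Ancestral pools.** Allele frequencies follow a Balding–Nichols model:
a base frequency $p \sim U(0.1, 0.9)$ per SNP, and per pool a drifted
frequency from a Beta distribution with mean $p$ and variance
$p(1-p)F_{ST}$. Defaults are $F_{ST} = 0.2$ (IND) and $0.1$ (AFT, EUT),
giving pools as divergent as indicine vs taurine cattle without fixing
loci wholesale. Founder haplotypes are drawn SNP-independently from the
drifted frequencies; an optional block-prototype mode adds background LD
but the acceptance worlds rely on injected sweeps, not background LD,
precisely so that brute-force oracles stay tractable.

**Forward admixture.** A closed population of constant size is founded by
pure individuals (pool probabilities default to IND 0.24 / AFT 0.03 /
EUT 0.73, the genome-wide ancestry mix reported for Kenyan crossbreds) and
random-mates for $G$ non-overlapping generations. Crossovers per meiosis
per chromosome are Poisson with mean equal to the map length at
1 Morgan = 100 Mbp (Haldane, no interference) — the same map convention
every downstream module uses. The true ancestry of every allele is carried
through each meiosis, so tract boundaries are the actual crossover
positions, not an inference.

**Recent introgression.** The `backcross` option appends animals sired by
a handful of pure EUT bulls on admixed dams. This models the recurrent-AI
("popular sire") structure of smallholder systems: each such animal carries
one intact pure haplotype (and therefore a recency score of 0), and
paternal half-sibs share multi-megabase sire segments. These shared
segments are exactly the pseudo-sweep background that motivates filtering
recently admixed animals before scanning for selection — with plain
unrelated F1s the filtered-vs-all contrast actually reverses, because
halving the sample only adds noise.

**Sweeps.** `injectSweep()` copies a donor haplotype's alleles over a flank
around a core SNP onto random recipients until the carrier frequency
reaches the target. The donor carries the *minor* core allele (by default a
rare one near the chromosome centre), as a real partial sweep of a derived
allele would, so the core allele tags the swept flank. Restricting
`haps` to deep animals states that post-admixture selection acted on the
established population, not on freshly introduced genomes.

**Phenotypes.** `simulatePhenotypes()` draws repeated records under
$y = \mu + X\beta + Wu + Wpe + e$ with $u \sim N(0, G\sigma^2_g)$,
$pe \sim N(0, I\sigma^2_{pe})$, $e \sim N(0, I\sigma^2_e)$ — the same model
the association stage fits. Defaults $(\sigma^2_g, \sigma^2_{pe},
\sigma^2_e) = (1, 0.5, 1)$ with three records per animal mimic repeated
milk-yield deviations.

What the generator does **not** emulate: background LD within ancestral
pools (unless block mode is on), mutation, genotyping or phasing error, and
local-ancestry miscalls — ancestry is consumed as truth. A green test
therefore establishes that the statistics behave correctly when their
inputs are what they claim to be, not that a particular caller is accurate.

## Crossover dating and the recency filter

A *recent crossover* is an adjacent-SNP transition between EUT and a
non-EUT label on one haplotype; IND–AFT switches are internal to the
indigenous genome and do not count. Counts are standardised per Morgan
(1 Morgan = 100 Mbp; chromosome length is taken as the last SNP position,
the only definition reproducible from the data alone). Within each
chromosome the two haplotypes are ranked, and an animal's recency score is
the unweighted mean over chromosomes of the lower count — unweighted
because chromosome count, not SNP count, is the stated averaging unit.
`filterRecent()` retains animals with score at least 3 per Morgan, the
empirical "three or more crossovers" rule; backcrosses and F1s score 0 and
are removed.

## The dual-effect association model

For each SNP, $X$ has two columns: the EUT-origin dosage (0/1/2 copies
from the EUT ancestor) and the allele dosage (0/1/2 alternate-allele
copies); both effects are estimated jointly. The covariance structure uses
a VanRaden (method 1) GRM built from all SNPs *except* the tested SNP's
chromosome (LOCO), sample-frequency centred, with monomorphic SNPs
dropped.

Rather than refitting the full mixed model per SNP, variance components
are estimated once per LOCO GRM under the intercept-only model by REML and
fixed for per-SNP GLS (the EMMAX-style two-stage approximation), which
makes a 500-animal, repeated-records scan a desk-scale computation. The
REML objective is evaluated through the eigendecomposition of the GRM:
with $B = \sigma^2_g D + \sigma^2_{pe} I$ in the eigenbasis and
$W'W = \mathrm{diag}(m_i)$ (records per animal), every $V^{-1}$ product
reduces to one $q \times q$ Cholesky per likelihood evaluation, and to a
diagonal solve when all animals have the same record count. The optimiser
works on log variance scale (Nelder–Mead, relative tolerance $10^{-10}$),
so components stay non-negative; boundary estimates are clipped with a
warning. The two-stage GLS agrees with a dense matrix-inversion oracle to
$10^{-8}$; against a *full per-SNP REML refit* the difference is the
$O(1/n)$ variance-component shift from two extra fixed-effect columns
(0.03–0.1 on the $-\log_{10} p$ scale at 50 animals), which is the
approximation's honest price; the corresponding acceptance check asserts a
far tighter agreement and is expected to stay red at this sample size.

Wald statistics $(\hat\beta/SE)^2$ are referred to $\chi^2_1$. A constant
or collinear design column makes that effect not-estimable (NA); when the
two dosages are mutually collinear the origin effect, the contrast of
interest, is retained.

Two properties of desk-scale scans deserve emphasis. First, origin-effect
p-values are autocorrelated at ancestry-tract scale — admixture mapping has
intrinsically broad peaks — so goodness-of-fit checks of uniformity apply
to the allele scan. Second, with few chromosomes a genome-wide polygenic
term leaves a non-trivial fraction of $u$ unmodelled under LOCO, so null
calibration is assessed in a polygene-free world ($\sigma^2_g = 0$); with
29 cattle autosomes the unmodelled share is ~3% and the issue is minor.

## Haplotype-homozygosity statistics

EHH for a core allele at extension $t$ is pair homozygosity:
$\sum_k n_k(n_k-1) / (n_a(n_a-1))$ over distinct core-to-$t$ haplotypes
among carriers. (The typeset source formula with $n(1-n)$ in the
denominator is a rendering artifact; it would be negative.) iHH integrates
EHH by trapezoid over map distance out to the linearly interpolated
crossing of the 0.05 decay threshold; curves reaching a chromosome end
above threshold are integrated to the end and flagged edge-truncated.
$iHS = \ln(iHH_a/iHH_d)$ is computed at SNPs with MAF > 0.05.

Ancestral alleles are the pooled-majority alleles over the entire data set
(cohort, reference population, and in simulations the ancestral panels),
with exact ties going to the reference allele. Standardisation subtracts
the mean and divides by the population SD within derived-allele-frequency
bins of width 0.025, where the binning frequency is the derived allele's
frequency *in the scanned panel* — so each scenario's bins are homogeneous
for its own sample. Bins with fewer than `minBin` SNPs merge with their
nearest occupied neighbour; the default is 10, but the bundled desk-scale
worlds use 25 because with ~1,000 SNPs a 10-SNP bin can consist entirely of
one sweep's own flank, which would standardise the sweep against itself.
At 500K-SNP scale the distinction is irrelevant. Two-sided p-values are
$-\log_{10}[1 - 2|\Phi(z) - 0.5|]$ (base 10, matching Manhattan axes).

The between-population statistic uses the site-level
$EHHS_{s,t} = (1 - h_{s,t})/(1 - h_s)$ with sample-size-corrected
haplotype/allele heterozygosities over *all* haplotypes, integrated as iES
exactly like iHH, and $Rsb = \ln(iES_A/iES_B)$ standardised by the genome
median and SD (so the standardised median is 0 by construction). No MAF
filter is applied to Rsb beyond polymorphism in both panels; SNPs with
undefined iES in either population are dropped and counted.

## Multiple testing and regions

`qvalues()` implements Storey–Tibshirani q-values with the
natural-cubic-spline $\hat\pi_0(\lambda)$ smoother on
$\lambda \in \{0.05, \dots, 0.95\}$ (fixed-$\pi_0$ mode reduces exactly to
Benjamini–Hochberg at $\pi_0 = 1$). `fdrThresholdLine()` maps an FDR level
to the $-\log_{10} p$ of the least-significant passing test, the line a
Manhattan plot draws.

Candidate regions are called seed-and-extend: a seed SNP (q < 0.1) opens a
region, which grows while any SNP within 500 kbp beyond the current
last-identified SNP passes the suggestive threshold (q < 0.5 for iHS,
q < 0.25 for Rsb; p < $10^{-3}$ for GWA, used for both seeding and
extension). The farthest qualifying SNP inside the window becomes the new
boundary. Boundaries are the outermost identified SNP positions (1-based
closed; BED export converts to 0-based half-open). Regions grown from
different seeds that touch or overlap are merged — the source tables report
disjoint regions per chromosome. Each region is labelled with its dominant
ancestry: the pool with the largest mean local-ancestry fraction over the
region's SNPs and the retained animals, ties broken IND, AFT, EUT with a
warning. GWA and selection regions are intersected for cross-validation,
reporting every shared interval and its length.

## Numerical choices and degenerate inputs

* Map conversions use physical positions at 1 Morgan = 100 Mbp everywhere.
* GRM: centering frequencies come from the analysed sample; an optional
  diagonal ridge (default $10^{-6}$ in the scan driver) stabilises
  factorisation; eigenvalues are floored at 0.
* EHH walks stop at the first value below the decay threshold (that point
  is retained for interpolation); cores with fewer than two carriers of an
  allele, or zero integrals, are flagged undefined rather than infinite.
* Zero-SD frequency bins are left unstandardised with a warning; identical
  Rsb panels (zero genome SD) yield standardised scores of 0, not NaN.
* Exact 50/50 polarisation ties go to the reference allele,
  deterministically, with a warning.
* Missing ancestry labels are rejected, never imputed: silent imputation
  would corrupt crossover counts.

## Open choices made

* The generation-depth distribution of the real population is unknown; it
  is a parameter (`generations`, per-animal), not a claimed default.
* Whether the recency score should be SNP-count-weighted is unstated; the
  unweighted chromosome mean follows the stated definition.
* Rsb standardisation uses all SNPs with defined iES in both populations.
* The pipeline's configuration serialises as JSON rather than YAML, purely
  because the deployment environment guarantees a JSON parser.

## Limitations

Ancestry-call uncertainty is not propagated; phasing is assumed. The
two-stage association slightly mis-states per-SNP uncertainty relative to
a full refit (quantified above). Desk-scale genomes (1–8 chromosomes,
$10^3$ SNPs) exaggerate LOCO's unmodelled-polygene share and make
frequency bins coarse; both effects shrink at real marker densities. The
simulator's founder pools are LD-free by default, so absolute iHH values
are smaller than chip data would give; all detection tests are therefore
relative (sweep vs own genome background), never absolute.
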