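## Haplotype-homozygosity statistics, implemented from first principles.
##
## EHH at extension SNP t for core allele a:  sum_k n_k (n_k - 1) / (n_a
## (n_a - 1)), n_k the copy count of the k-th distinct core-to-t haplotype
## among the n_a carriers (Sabeti-style pair homozygosity; equals the
## probability that two random carriers are identical over the extension).
## iHH integrates EHH over map distance (1 Morgan = 100 Mbp) to the 0.05
## decay crossing; iHS = ln(iHH_ancestral / iHH_derived), standardised in
## derived-allele-frequency bins. The between-population statistic uses the
## site-level EHHS = (1 - h_{s,t}) / (1 - h_s) with sample-size-corrected
## haplotype/allele heterozygosities over ALL haplotypes; its integral iES
## enters Rsb = ln(iES_A / iES_B), standardised by genome median/SD.

DECAY_DEFAULT <- 0.05

## partition refinement: group ids (integers) refined by the allele vector
.refine <- function(group, allele) {
  key <- group * 2L + allele
  match(key, unique(key))
}

## walk outward from the core over snp indices `path` (excluding the core),
## tracking a statistic of the refined haplotype partition of the `cols`
## haplotypes. statFun(partition sizes) -> value in [0,1]. Stops after the
## first value < decay (that point is kept), when the partition statistic
## hits 0 (it can never recover), or at the path end. Renumbering uses a
## single tabulate pass, which also yields the partition sizes.
.walkEHH <- function(alleleMat, cols, group, path, statFun, decay) {
  n <- length(cols)
  nb <- 2L * n + 2L
  vals <- numeric(length(path))
  mapv <- integer(nb)
  k <- 0L
  for (t in path) {
    key <- group + group + alleleMat[t, cols] + 1L
    cnt <- tabulate(key, nbins = nb)
    pos <- which(cnt > 0L)
    mapv[pos] <- seq_along(pos)
    group <- mapv[key]
    k <- k + 1L
    v <- statFun(cnt[pos])
    vals[k] <- v
    if (v < decay || v == 0) break
  }
  vals[seq_len(k)]
}

#' Assign ancestral/derived alleles by pooled majority
#'
#' The ancestral allele at each SNP is the most common allele across the
#' pooled sample of all populations under analysis; exact 50/50 ties go to
#' the reference (0) allele with a warning.
#'
#' @param panels one [HaplotypePanel-class] or a list of panels on a shared
#'   SNP grid (pooled column-wise).
#' @return data.frame: \code{ancestral} (0/1 per SNP), \code{derived},
#'   \code{pooledFreq1} (pooled frequency of allele 1).
#' @export
polarizeAlleles <- function(panels) {
  if (is(panels, "HaplotypePanel")) panels <- list(panels)
  mats <- lapply(panels, alleles)
  f1 <- Reduce(`+`, lapply(mats, rowSums)) / sum(vapply(mats, ncol, 0L))
  anc <- ifelse(f1 > 0.5, 1L, 0L)
  if (any(f1 == 0.5)) {
    warning(sum(f1 == 0.5), " SNP(s) with a 50/50 pooled frequency; ",
            "reference allele declared ancestral")
  }
  data.frame(ancestral = anc, derived = 1L - anc, pooledFreq1 = f1)
}

#' Extended haplotype homozygosity curve around a core allele
#'
#' Computes EHH outward in both directions from the core SNP among the
#' carriers of the given core allele, stopping in each direction once EHH
#' falls below \code{decay} (the crossing point is retained) or the
#' chromosome ends. EHH at the core itself is 1 by definition.
#'
#' @param panel [HaplotypePanel-class] (one chromosome is extracted).
#' @param core global SNP index of the core.
#' @param allele core allele (0/1).
#' @param decay stop threshold for the walk.
#' @return list: \code{pos}/\code{ehh} (sorted left-to-right, including the
#'   core with EHH 1), \code{corePos}, \code{nCarriers}, \code{left} and
#'   \code{right} per-direction data.frames.
#' @export
ehhCurve <- function(panel, core, allele, decay = DECAY_DEFAULT) {
  ch <- panel@chrom[core]
  onC <- which(panel@chrom == ch)
  carriers <- which(panel@alleles[core, ] == allele)
  if (length(carriers) < 2L) {
    stop("fewer than 2 carriers of the core allele")
  }
  na <- length(carriers)
  denom <- na * (na - 1)
  statFun <- function(sizes) sum(sizes * (sizes - 1)) / denom
  ci <- match(core, onC)
  right <- if (ci < length(onC)) onC[(ci + 1L):length(onC)] else integer(0)
  left <- if (ci > 1L) onC[(ci - 1L):1L] else integer(0)
  g0 <- rep(1L, na)
  vr <- .walkEHH(panel@alleles, carriers, g0, right, statFun, decay)
  vl <- .walkEHH(panel@alleles, carriers, g0, left, statFun, decay)
  corePos <- panel@pos[core]
  rightDf <- data.frame(pos = panel@pos[right[seq_along(vr)]], ehh = vr)
  leftDf <- data.frame(pos = panel@pos[left[seq_along(vl)]], ehh = vl)
  list(pos = c(rev(leftDf$pos), corePos, rightDf$pos),
       ehh = c(rev(leftDf$ehh), 1, rightDf$ehh),
       corePos = corePos, nCarriers = na, left = leftDf, right = rightDf)
}

## integrate one side: ehh values outward from the core (core itself EHH 1 at
## distance 0), positions outward. Trapezoid in Morgans to the interpolated
## decay crossing; flagged truncated if the chromosome ends first.
.integrateSide <- function(posOut, ehhOut, corePos, decay) {
  x <- abs(posOut - corePos) / MORGAN_BP
  x <- c(0, x); v <- c(1, ehhOut)
  below <- which(v < decay)
  truncated <- !length(below)
  if (!truncated) {
    k <- below[1L]
    frac <- (v[k - 1L] - decay) / (v[k - 1L] - v[k])
    xc <- x[k - 1L] + frac * (x[k] - x[k - 1L])
    x <- c(x[seq_len(k - 1L)], xc)
    v <- c(v[seq_len(k - 1L)], decay)
  }
  area <- if (length(x) > 1L) sum(diff(x) * (head(v, -1) + tail(v, -1)) / 2) else 0
  list(area = area, truncated = truncated)
}

#' Integrated EHH (iHH) of a curve
#'
#' Trapezoidal integral of the EHH curve over map distance (1 Morgan =
#' 100 Mbp), each direction from the core to the linearly interpolated point
#' where EHH first crosses the decay threshold; directions that reach the
#' chromosome end above threshold are integrated to the end and flagged.
#'
#' @param curve output of [ehhCurve()].
#' @param decay homozygosity decay threshold.
#' @return list: \code{ihh} (both sides summed, Morgans), \code{truncated}.
#' @export
ihh <- function(curve, decay = DECAY_DEFAULT) {
  l <- .integrateSide(curve$left$pos, curve$left$ehh, curve$corePos, decay)
  r <- .integrateSide(curve$right$pos, curve$right$ehh, curve$corePos, decay)
  list(ihh = l$area + r$area, truncated = l$truncated || r$truncated)
}

#' Raw iHS scan over one panel
#'
#' At every SNP with minor allele frequency above \code{maf}, computes the
#' integrated EHH of the ancestral and the derived allele and the raw
#' \eqn{iHS = \ln(iHH_a/iHH_d)}. SNPs where either allele has fewer than two
#' carriers, or where \eqn{iHH_d = 0}, are flagged undefined rather than
#' reported as infinite.
#'
#' @param panel [HaplotypePanel-class].
#' @param polarity output of [polarizeAlleles()] on the pooled sample (must
#'   cover this panel's SNP grid).
#' @param maf minor-allele-frequency threshold (iHS only).
#' @param decay homozygosity decay threshold.
#' @return data.frame per analysed SNP: chrom, pos, snp_id, derived_freq,
#'   ihh_a, ihh_d, ihs_raw, truncated.
#' @export
ihsScan <- function(panel, polarity, maf = 0.05, decay = DECAY_DEFAULT) {
  f1 <- rowMeans(panel@alleles)
  keep <- pmin(f1, 1 - f1) > maf
  idx <- which(keep)
  res <- lapply(idx, function(s) {
    anc <- polarity$ancestral[s]
    der <- polarity$derived[s]
    ca <- sum(panel@alleles[s, ] == anc)
    cd <- ncol(panel@alleles) - ca
    if (ca < 2L || cd < 2L) {
      return(data.frame(ihh_a = NA_real_, ihh_d = NA_real_, ihs_raw = NA_real_,
                        truncated = NA))
    }
    ia <- ihh(ehhCurve(panel, s, anc, decay), decay)
    id <- ihh(ehhCurve(panel, s, der, decay), decay)
    raw <- if (id$ihh > 0 && ia$ihh > 0) log(ia$ihh / id$ihh) else NA_real_
    data.frame(ihh_a = ia$ihh, ihh_d = id$ihh, ihs_raw = raw,
               truncated = ia$truncated || id$truncated)
  })
  # ancestral/derived assignment comes from the pooled sample; the binning
  # frequency is the derived allele's frequency in the scanned panel itself
  # (it can exceed 0.5 where the panel departs from the pooled majority)
  derFreq <- ifelse(polarity$derived[idx] == 1L, f1[idx], 1 - f1[idx])
  cbind(data.frame(chrom = panel@chrom[idx], pos = panel@pos[idx],
                   snp_id = panel@snpID[idx], derived_freq = derFreq),
        do.call(rbind, res))
}

## two-sided Gaussian transform on the -log10 scale:
## p = -log10(1 - 2|Phi(z) - 0.5|) = -log10(2 * Phi(-|z|))
.neglog10pGauss <- function(z) {
  -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

#' Standardise a raw iHS scan within derived-allele-frequency bins
#'
#' Within each derived-frequency bin (step \code{binStep}) the raw iHS
#' values are centred by the bin mean and scaled by the bin standard
#' deviation (population convention, denominator n), so each bin has mean 0
#' and SD 1 exactly. Bins with fewer than \code{minBin} SNPs (or zero SD)
#' are merged with their nearest neighbour first. The two-sided p-value of
#' "no selection" is \eqn{-\log_{10}[1 - 2|\Phi(iHS)-0.5|]}.
#'
#' @param rawScan output of [ihsScan()].
#' @param binStep derived-frequency bin width.
#' @param minBin minimum SNPs per bin before merging.
#' @return A [ScanResult-class] (scan \code{"ihs"}) whose table adds
#'   \code{stat_raw}, \code{stat_std}, \code{bin}, \code{p},
#'   \code{neglog10p}.
#' @export
standardizeIhs <- function(rawScan, binStep = 0.025, minBin = 10L) {
  ok <- is.finite(rawScan$ihs_raw)
  breaks <- seq(0, 1, by = binStep)
  bin <- as.integer(cut(rawScan$derived_freq, breaks, include.lowest = TRUE))
  binUse <- bin
  counts <- table(factor(binUse[ok], levels = seq_len(length(breaks) - 1L)))
  occupied <- as.integer(names(counts)[counts > 0])
  small <- occupied[counts[as.character(occupied)] < minBin]
  while (length(small) && length(occupied) > 1L) {
    b <- small[1L]
    nb <- occupied[occupied != b]
    tgt <- nb[which.min(abs(nb - b))]
    binUse[binUse == b & !is.na(binUse)] <- tgt
    counts <- table(factor(binUse[ok], levels = seq_len(length(breaks) - 1L)))
    occupied <- as.integer(names(counts)[counts > 0])
    small <- occupied[counts[as.character(occupied)] < minBin]
  }
  z <- rep(NA_real_, nrow(rawScan))
  for (b in unique(binUse[ok])) {
    i <- which(binUse == b & ok)
    mu <- mean(rawScan$ihs_raw[i])
    sdv <- sqrt(mean((rawScan$ihs_raw[i] - mu)^2))
    if (sdv == 0) {
      warning("zero-SD frequency bin left unstandardised (", length(i), " SNPs)")
      next
    }
    z[i] <- (rawScan$ihs_raw[i] - mu) / sdv
  }
  nl10 <- .neglog10pGauss(z)
  tab <- data.frame(chrom = rawScan$chrom, pos = rawScan$pos,
                    snp_id = rawScan$snp_id, derived_freq = rawScan$derived_freq,
                    bin = binUse, stat_raw = rawScan$ihs_raw, stat_std = z,
                    p = 10^(-nl10), neglog10p = nl10,
                    truncated = rawScan$truncated)
  ScanResult(tab, "ihs")
}

#' Site-specific integrated EHH (iES) at a core SNP
#'
#' EHHS at extension t uses all haplotypes regardless of core allele:
#' \eqn{EHHS_{s,t} = (1 - h_{s,t}) / (1 - h_s)} with
#' \eqn{h_{s,t} = \frac{n}{n-1}(1 - \frac{1}{n^2}\sum_k n_k^2)} the
#' corrected haplotype heterozygosity from core to t and \eqn{h_s} the same
#' quantity over the two core alleles. EHHS equals 1 at the core and is
#' integrated exactly as iHH.
#'
#' @param panel [HaplotypePanel-class].
#' @param core global SNP index.
#' @param decay homozygosity decay threshold.
#' @return list: \code{ies}, \code{truncated}; NA ies if the core is
#'   monomorphic.
#' @export
ies <- function(panel, core, decay = DECAY_DEFAULT) {
  nh <- ncol(panel@alleles)
  if (nh < 2L) stop("need at least 2 haplotypes")
  n1 <- sum(panel@alleles[core, ])
  if (n1 == 0L || n1 == nh) return(list(ies = NA_real_, truncated = NA))
  hs <- nh / (nh - 1) * (1 - (n1^2 + (nh - n1)^2) / nh^2)
  statFun <- function(sizes) {
    hst <- nh / (nh - 1) * (1 - sum(sizes^2) / nh^2)
    (1 - hst) / (1 - hs)
  }
  ch <- panel@chrom[core]
  onC <- which(panel@chrom == ch)
  ci <- match(core, onC)
  right <- if (ci < length(onC)) onC[(ci + 1L):length(onC)] else integer(0)
  left <- if (ci > 1L) onC[(ci - 1L):1L] else integer(0)
  g0 <- 1L + panel@alleles[core, ]
  allCols <- seq_len(nh)
  vr <- .walkEHH(panel@alleles, allCols, g0, right, statFun, decay)
  vl <- .walkEHH(panel@alleles, allCols, g0, left, statFun, decay)
  corePos <- panel@pos[core]
  r <- .integrateSide(panel@pos[right[seq_along(vr)]], vr, corePos, decay)
  l <- .integrateSide(panel@pos[left[seq_along(vl)]], vl, corePos, decay)
  list(ies = l$area + r$area, truncated = l$truncated || r$truncated)
}

#' Cross-population Rsb scan
#'
#' Computes iES per SNP in each population on the intersected SNP grid, the
#' raw \eqn{Rsb = \ln(iES_A/iES_B)}, its genome-wide standardisation
#' \eqn{(Rsb - \mathrm{med}_{Rsb})/\sigma_{Rsb}}, and the two-sided Gaussian
#' \eqn{-\log_{10}} p. SNPs with undefined iES in either population are
#' dropped. No MAF filter is applied beyond polymorphism in both panels.
#'
#' @param panelA focal population (e.g. filtered admixed cohort).
#' @param panelB reference population (e.g. indigenous zebu).
#' @param decay homozygosity decay threshold.
#' @return A [ScanResult-class] (scan \code{"rsb"}) with \code{stat_raw},
#'   \code{stat_std}, \code{ies_a}, \code{ies_b}, flags.
#' @export
rsbScan <- function(panelA, panelB, decay = DECAY_DEFAULT) {
  keyA <- paste(panelA@chrom, panelA@pos)
  keyB <- paste(panelB@chrom, panelB@pos)
  common <- intersect(keyA, keyB)
  if (!length(common)) stop("no shared SNPs between the two panels")
  ia <- match(common, keyA); ib <- match(common, keyB)
  resA <- lapply(ia, function(s) ies(panelA, s, decay))
  resB <- lapply(ib, function(s) ies(panelB, s, decay))
  iesA <- vapply(resA, `[[`, 0, "ies")
  iesB <- vapply(resB, `[[`, 0, "ies")
  raw <- ifelse(is.finite(iesA) & is.finite(iesB) & iesA > 0 & iesB > 0,
                log(iesA / iesB), NA_real_)
  ok <- is.finite(raw)
  if (sum(ok) < 2L) stop("too few SNPs with defined iES in both populations")
  if (any(!ok)) message(sum(!ok), " SNP(s) dropped: iES undefined in one population")
  sdv <- sd(raw[ok])
  z <- (raw[ok] - median(raw[ok])) / if (sdv > 0) sdv else 1
  nl10 <- .neglog10pGauss(z)
  tab <- data.frame(chrom = panelA@chrom[ia], pos = panelA@pos[ia],
                    snp_id = panelA@snpID[ia],
                    ies_a = iesA, ies_b = iesB, stat_raw = raw,
                    truncated = vapply(resA, `[[`, NA, "truncated") |
                                vapply(resB, `[[`, NA, "truncated"))[ok, ]
  tab$stat_std <- z
  tab$p <- 10^(-nl10)
  tab$neglog10p <- nl10
  ScanResult(tab, "rsb")
}
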