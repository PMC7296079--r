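## Dual-effect mixed-model GWA. Per SNP the model
##   y = 1 mu + X beta + W u + W pe + e
## jointly carries the ancestral-origin allele effect (per EUT-origin copy)
## and the residual SNP allele effect (per alternate-allele copy) in beta.
## u ~ N(0, G sigma2g) under a leave-one-chromosome-out GRM, pe ~ N(0, I
## sigma2pe) per animal, e ~ N(0, I sigma2e) per record; W maps records to
## animals. Variance components are estimated once per LOCO GRM under the
## null and fixed for per-SNP generalised least squares (the EMMAX-style
## two-stage approximation); an exact per-SNP REML refit is provided for
## cross-checks.
##
## All solves ride on the eigendecomposition G = U D U': with
## B = sigma2g D + sigma2pe, J = B^{-1} + W'W/sigma2e in the eigenbasis is
## diag(1/B) + U' diag(m) U / sigma2e, and V^{-1} products reduce to one
## q x q Cholesky per likelihood evaluation.

.mmContext <- function(pheno, grm) {
  ids <- unique(pheno$animal_id)
  Gall <- grmValues(grm)
  missing <- setdiff(ids, rownames(Gall))
  if (length(missing)) {
    stop("phenotyped animals absent from GRM: ", paste(head(missing, 5), collapse = ", "))
  }
  G <- Gall[ids, ids]
  aIdx <- match(pheno$animal_id, ids)
  m <- tabulate(aIdx, length(ids))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  mEqual <- max(m) == min(m)
  Um2 <- if (mEqual) NULL else crossprod(U, U * m)  # U' diag(m) U
  list(ids = ids, y = pheno$value, aIdx = aIdx, m = m, n = nrow(pheno),
       q = length(ids), U = U, d = d, Um2 = Um2, mEqual = mEqual)
}

## Minner = diag(1/B) + U' diag(m) U / sigma2e and its solve/logdet
.innerFactor <- function(ctx, s2g, s2pe, s2e) {
  bb <- s2g * ctx$d + s2pe
  if (any(bb <= 0)) return(NULL)
  if (ctx$mEqual) {
    diagM <- 1 / bb + ctx$m[1] / s2e
    list(diagonal = diagM, logdet = sum(log(diagM)), logdetB = sum(log(bb)))
  } else {
    M <- ctx$Um2 / s2e
    diag(M) <- diag(M) + 1 / bb
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(chol = ch, logdet = 2 * sum(log(diag(ch))), logdetB = sum(log(bb)))
  }
}

.innerSolve <- function(fac, x) {
  if (!is.null(fac$diagonal)) return(x / fac$diagonal)
  backsolve(fac$chol, backsolve(fac$chol, x, transpose = TRUE))
}

## quadratic-form engine: X record-level n x p, y record-level
.remlPieces <- function(ctx, X, fac, s2e) {
  cols <- cbind(X, ctx$y)
  colA <- rowsum(cols, ctx$aIdx)              # W' x, q x (p+1)
  colT <- crossprod(ctx$U, colA)              # U' W' x
  colS <- .innerSolve(fac, colT)              # Minner^{-1} U' W' x
  cross <- crossprod(cols) / s2e - crossprod(colT, colS) / s2e^2
  p <- ncol(X)
  list(XtVX = cross[seq_len(p), seq_len(p), drop = FALSE],
       XtVy = cross[seq_len(p), p + 1L],
       ytVy = cross[p + 1L, p + 1L])
}

.remlNegLogLik <- function(logpar, ctx, X) {
  s2 <- exp(logpar)
  fac <- .innerFactor(ctx, s2[1], s2[2], s2[3])
  if (is.null(fac)) return(1e10)
  pc <- .remlPieces(ctx, X, fac, s2[3])
  logdetV <- ctx$n * log(s2[3]) + fac$logdetB + fac$logdet
  XtVXi <- tryCatch(solve(pc$XtVX), error = function(e) NULL)
  if (is.null(XtVXi)) return(1e10)
  quad <- pc$ytVy - drop(crossprod(pc$XtVy, XtVXi %*% pc$XtVy))
  ld2 <- determinant(pc$XtVX, logarithm = TRUE)$modulus
  0.5 * (logdetV + ld2 + quad)
}

#' REML variance components under the repeated-records animal model
#'
#' Estimates \eqn{(\sigma^2_g, \sigma^2_{pe}, \sigma^2_e)} by restricted
#' maximum likelihood under the intercept-only model (optionally with extra
#' fixed covariates, which is how the exact per-SNP refit is obtained). The
#' optimiser works on log variance scale, so estimates are non-negative by
#' construction; components driven to the lower boundary are reported with a
#' warning.
#'
#' @param pheno data.frame \code{animal_id}, \code{record_id}, \code{value}.
#' @param grm [GRM-class] containing every phenotyped animal.
#' @param covariates optional record-level fixed-covariate matrix (columns in
#'   addition to the intercept).
#' @param reltol relative convergence tolerance of the optimiser.
#' @return A [VarianceComponents-class] object.
#' @export
fitNullREML <- function(pheno, grm, covariates = NULL, reltol = 1e-10) {
  ctx <- .mmContext(pheno, grm)
  X <- cbind(rep(1, ctx$n), covariates)
  vy <- var(ctx$y)
  init <- log(rep(vy / 3, 3))
  fit <- optim(init, .remlNegLogLik, ctx = ctx, X = X, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = reltol))
  if (fit$convergence != 0) {
    stop("REML did not converge (optim code ", fit$convergence,
         ", ", fit$counts[1], " evaluations)")
  }
  s2 <- exp(fit$par)
  floorv <- vy * 1e-6
  if (any(s2 < floorv)) {
    warning("variance component estimate at lower boundary; clipped at ",
            signif(floorv, 3))
    s2 <- pmax(s2, floorv)
  }
  new("VarianceComponents", sigma2g = s2[1], sigma2pe = s2[2], sigma2e = s2[3],
      logLik = -fit$value, excludedChrom = grm@excludedChrom, converged = TRUE)
}

## batched GLS for animal-level design columns at fixed variance components.
## origin, allele: q x S matrices aligned with ctx$ids. Returns per-SNP
## estimates/SEs/p for both effects.
.glsScan <- function(ctx, vc, origin, allele) {
  s2e <- vc@sigma2e
  fac <- .innerFactor(ctx, vc@sigma2g, vc@sigma2pe, s2e)
  if (is.null(fac)) stop("variance components give a singular covariance")
  ya <- drop(rowsum(ctx$y, ctx$aIdx))
  yt <- drop(crossprod(ctx$U, ya)); ys <- drop(.innerSolve(fac, yt))
  ones <- rep(1, ctx$q)
  a0t <- drop(crossprod(ctx$U, ctx$m))       # U'(m * 1)
  a0s <- drop(.innerSolve(fac, a0t))
  Q11 <- ctx$n / s2e - sum(a0t * a0s) / s2e^2
  b1 <- sum(ya) / s2e - sum(a0t * ys) / s2e^2
  yVy <- sum(ctx$y^2) / s2e - sum(yt * ys) / s2e^2

  S <- ncol(origin)
  mO <- origin * ctx$m; mG <- allele * ctx$m
  Ot <- crossprod(ctx$U, mO); Gt <- crossprod(ctx$U, mG)
  Os <- .innerSolve(fac, Ot); Gs <- .innerSolve(fac, Gt)
  Q12 <- colSums(mO) / s2e - colSums(a0s * Ot) / s2e^2
  Q13 <- colSums(mG) / s2e - colSums(a0s * Gt) / s2e^2
  Q22 <- colSums(origin * mO) / s2e - colSums(Ot * Os) / s2e^2
  Q23 <- colSums(origin * mG) / s2e - colSums(Ot * Gs) / s2e^2
  Q33 <- colSums(allele * mG) / s2e - colSums(Gt * Gs) / s2e^2
  b2 <- colSums(origin * ya) / s2e - colSums(Os * yt) / s2e^2
  b3 <- colSums(allele * ya) / s2e - colSums(Gs * yt) / s2e^2

  out <- data.frame(origin_effect = NA_real_, origin_se = NA_real_,
                    origin_p = NA_real_, allele_effect = NA_real_,
                    allele_se = NA_real_, allele_p = NA_real_)[rep(1L, S), ]
  rownames(out) <- NULL
  varO <- apply(origin, 2L, var); varG <- apply(allele, 2L, var)
  for (s in seq_len(S)) {
    useO <- varO[s] > 0
    useG <- varG[s] > 0
    if (useO && useG) {
      r <- suppressWarnings(cor(origin[, s], allele[, s]))
      if (is.finite(r) && abs(r) > 1 - 1e-10) useG <- FALSE
    }
    sel <- c(TRUE, useO, useG)
    Q <- matrix(c(Q11, Q12[s], Q13[s],
                  Q12[s], Q22[s], Q23[s],
                  Q13[s], Q23[s], Q33[s]), 3, 3)[sel, sel, drop = FALSE]
    b <- c(b1, b2[s], b3[s])[sel]
    Qi <- tryCatch(solve(Q), error = function(e) NULL)
    if (is.null(Qi)) next
    beta <- drop(Qi %*% b)
    se <- sqrt(pmax(diag(Qi), 0))
    k <- 1L
    if (useO) {
      k <- k + 1L
      out$origin_effect[s] <- beta[k]; out$origin_se[s] <- se[k]
      out$origin_p[s] <- pchisq((beta[k] / se[k])^2, 1, lower.tail = FALSE)
    }
    if (useG) {
      k <- k + 1L
      out$allele_effect[s] <- beta[k]; out$allele_se[s] <- se[k]
      out$allele_p[s] <- pchisq((beta[k] / se[k])^2, 1, lower.tail = FALSE)
    }
  }
  attr(out, "yVy") <- yVy
  out
}

#' Test one SNP at fixed variance components
#'
#' Generalised-least-squares estimation of (mean, origin effect, allele
#' effect) with the covariance structure fixed at the supplied REML
#' estimates; Wald statistic \eqn{(\hat\beta/SE)^2} against \eqn{\chi^2_1}.
#' A design column that is constant (e.g. a SNP fixed for EUT origin in the
#' sample) or collinear with the other makes that effect not-estimable (NA);
#' when the two dosages are mutually collinear the origin effect, the
#' contrast of interest, is retained.
#'
#' @param pheno phenotype data.frame (\code{animal_id}, \code{record_id},
#'   \code{value}).
#' @param originDosage named per-animal EUT-origin dosage (0/1/2).
#' @param alleleDosage named per-animal allele dosage (0/1/2).
#' @param vc [VarianceComponents-class] fitted under the LOCO GRM for the
#'   SNP's chromosome.
#' @param grm the same [GRM-class] the components were fitted under.
#' @return one-row data.frame with origin/allele estimates, SEs and Wald p.
#' @export
testSnp <- function(pheno, originDosage, alleleDosage, vc, grm) {
  ctx <- .mmContext(pheno, grm)
  o <- originDosage[ctx$ids]; g <- alleleDosage[ctx$ids]
  if (any(is.na(o)) || any(is.na(g))) stop("dosage missing for phenotyped animals")
  .glsScan(ctx, vc, matrix(o, ncol = 1), matrix(g, ncol = 1))
}

#' Exact single-SNP mixed-model test (full REML refit)
#'
#' Re-estimates the variance components with the SNP's two dosage columns in
#' the fixed effects, then performs GLS at the refitted components. This is
#' the reference the two-stage (EMMAX-style) scan is checked against.
#'
#' @inheritParams testSnp
#' @return one-row data.frame as [testSnp()].
#' @export
testSnpExact <- function(pheno, originDosage, alleleDosage, grm) {
  ctx <- .mmContext(pheno, grm)
  o <- originDosage[ctx$ids]; g <- alleleDosage[ctx$ids]
  Xc <- cbind(origin = o[ctx$aIdx], allele = g[ctx$aIdx])
  vc <- fitNullREML(pheno, grm, covariates = Xc)
  .glsScan(ctx, vc, matrix(o, ncol = 1), matrix(g, ncol = 1))
}

#' Genome-wide dual-effect association scan
#'
#' For each chromosome: builds the leave-one-chromosome-out GRM, fits the
#' null REML once, then tests every SNP on that chromosome by GLS with both
#' effects estimated jointly. Returns two [ScanResult-class] objects, one
#' for residual allele effects and one for ancestral-origin effects, with
#' Storey q-values attached per scan.
#'
#' @param pheno phenotype data.frame.
#' @param panel [HaplotypePanel-class] of the phenotyped (or a superset of)
#'   animals.
#' @param ancestry aligned [AncestryMatrix-class].
#' @param qvalues attach Storey q-values (default TRUE).
#' @param ridge diagonal ridge for the LOCO GRMs.
#' @return named list of [ScanResult-class]: \code{allele}, \code{origin}.
#' @export
gwaScan <- function(pheno, panel, ancestry, qvalues = TRUE, ridge = 1e-6) {
  phenoIds <- unique(pheno$animal_id)
  panelA <- subsetAnimals(panel, phenoIds)
  ancA <- subsetAnimals(ancestry, phenoIds)
  dosAll <- alleleDosage(panelA)          # animals x SNPs
  dosOrig <- eutDosage(ancA)              # SNPs x animals
  chromOf <- panelA@chrom
  chromIds <- chroms(panelA)
  if (length(chromIds) < 2L) {
    stop("LOCO GRM needs at least two chromosomes")
  }
  rows <- vector("list", length(chromIds))
  for (ci in seq_along(chromIds)) {
    ch <- chromIds[ci]
    onC <- which(chromOf == ch)
    if (sum(chromOf != ch) < 2L) stop("too few SNPs outside chromosome ", ch)
    grmC <- buildGRM(dosAll, chrom = chromOf, excludeChrom = ch, ridge = ridge)
    vc <- fitNullREML(pheno, grmC)
    ctx <- .mmContext(pheno, grmC)
    O <- t(dosOrig[onC, ctx$ids, drop = FALSE])    # q animals x S SNPs
    Gm <- dosAll[ctx$ids, onC, drop = FALSE]
    res <- .glsScan(ctx, vc, origin = O, allele = Gm)
    rows[[ci]] <- cbind(data.frame(chrom = ch, pos = panelA@pos[onC],
                                   snp_id = panelA@snpID[onC]), res)
  }
  tab <- do.call(rbind, rows)
  mk <- function(kind) {
    t2 <- data.frame(chrom = tab$chrom, pos = tab$pos, snp_id = tab$snp_id,
                     effect = tab[[paste0(kind, "_effect")]],
                     se = tab[[paste0(kind, "_se")]],
                     p = tab[[paste0(kind, "_p")]])
    t2$neglog10p <- -log10(t2$p)
    sc <- ScanResult(t2, paste0("gwa_", kind))
    if (qvalues) sc <- attachQvalues(sc)
    sc
  }
  list(allele = mk("allele"), origin = mk("origin"))
}
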