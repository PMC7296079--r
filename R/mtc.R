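## Storey-Tibshirani q-values shared by all four scans, and the mapping from
## an FDR level to the -log10 p threshold line drawn on Manhattan plots.

#' Storey-Tibshirani q-values
#'
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0 m p_j / \mathrm{rank}(p_j)},
#' capped at 1. \eqn{\hat\pi_0} comes either from the natural-cubic-spline
#' smoother of \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))}
#' evaluated at the largest \eqn{\lambda} (the default), or is fixed by the
#' caller; with \eqn{\pi_0 = 1} the q-values reduce to Benjamini-Hochberg.
#'
#' @param p p-values in (0, 1].
#' @param lambda grid for the pi0 smoother.
#' @param pi0Method \code{"smoother"} or \code{"fixed"}.
#' @param pi0 fixed pi0 when \code{pi0Method = "fixed"}.
#' @return list: \code{q} (aligned with \code{p}), \code{pi0},
#'   \code{lambda}.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                    pi0Method = c("smoother", "fixed"), pi0 = 1) {
  pi0Method <- match.arg(pi0Method)
  if (!length(p)) stop("no p-values supplied")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (pi0Method == "smoother") {
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- smooth.spline(lambda, pi0l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("fixed pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  qs <- pmin(pi0 * m * p[o] / (m:1), 1)
  qs <- cummin(qs)
  q <- numeric(m)
  q[o] <- qs
  list(q = q, pi0 = pi0, lambda = lambda)
}

#' Attach q-values to a scan
#'
#' Runs [qvalues()] on the scan's defined p-values and adds the \code{q}
#' column (NA where p was NA).
#'
#' @param scan a [ScanResult-class].
#' @param ... passed to [qvalues()].
#' @return the scan with \code{q} attached and \code{pi0} recorded.
#' @export
attachQvalues <- function(scan, ...) {
  tab <- scan@table
  ok <- !is.na(tab$p)
  if (!any(ok)) stop("scan has no defined p-values")
  qs <- qvalues(tab$p[ok], ...)
  tab$q <- NA_real_
  tab$q[ok] <- qs$q
  ScanResult(tab, scan@scan, pi0 = qs$pi0)
}

#' FDR threshold as a -log10 p line
#'
#' The \eqn{-\log_{10}} p of the least-significant test whose q-value passes
#' the FDR level — the horizontal line a Manhattan plot draws for that FDR.
#'
#' @param qset output of [qvalues()] plus the p-values, or a
#'   [ScanResult-class] with q attached.
#' @param level FDR level.
#' @param p p-values (when \code{qset} is a [qvalues()] result).
#' @return \eqn{-\log_{10}} p of the largest passing p, or NA if no test
#'   passes.
#' @export
fdrThresholdLine <- function(qset, level, p = NULL) {
  if (is(qset, "ScanResult")) {
    tab <- qset@table
    p <- tab$p
    q <- tab$q
  } else {
    q <- qset$q
  }
  ok <- !is.na(p) & !is.na(q)
  pass <- ok & q <= level
  if (!any(pass)) return(NA_real_)
  -log10(max(p[pass]))
}
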