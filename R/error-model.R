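# Per-site error rates from Phred-scaled base-call and mapping qualities.

#' Mean of base-call and mapping quality for one allele class
#'
#' @param bq,mq Non-negative Phred-scaled mean base-call and mapping
#'   qualities.
#' @return `(bq + mq) / 2`, Phred units.
#' @export
allele_mean_quality <- function(bq, mq) {
  if (any(bq < 0, na.rm = TRUE) || any(mq < 0, na.rm = TRUE)) {
    stop("Phred qualities must be non-negative")
  }
  (bq + mq) / 2
}

#' Count-weighted site quality
#'
#' Weighted average of the four allele-class qualities (reference, dominant
#' alternative, two minor alleles), weighted by their read counts:
#' \deqn{Q = \frac{Q^R R + Q^M M + Q^{X_1} X_1 + Q^{X_2} X_2}{R + M + X_1 + X_2}.}
#' Classes with zero count contribute nothing, so their quality may be
#' missing (`NA`).
#'
#' @param n Numeric vector (or matrix, sites x 4) of class read counts in
#'   the order R, M, X1, X2.
#' @param q Matching vector/matrix of per-class Phred qualities.
#' @return Weighted mean quality per site; error if a site has no reads.
#' @export
site_weighted_quality <- function(n, q) {
  if (is.null(dim(n))) n <- matrix(n, nrow = 1L)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  stopifnot(ncol(n) == ncol(q), nrow(n) == nrow(q))
  K <- rowSums(n)
  if (any(K == 0)) stop("site with K = 0 reads has no defined quality")
  qq <- q
  qq[n == 0] <- 0 # zero-count classes are excluded from the weighted mean
  if (any(is.na(qq))) stop("missing quality for an allele class with reads")
  rowSums(n * qq) / K
}

#' Error probability from a Phred-scaled quality
#'
#' `e = 10^(-Q/10)`, clamped to `[e_min, e_max]`. A quality of 20
#' corresponds to an error rate of 0.01 (one miscalled base per 100 read).
#' The lower clamp keeps minor-allele log terms finite; the upper clamp
#' caps the rate below the point where the three wrong alleles would be
#' jointly likelier than the true one.
#'
#' @param q Phred-scaled quality (vectorized), must be non-negative.
#' @param e_min,e_max Clamp bounds, `0 < e_min < e_max < 1`.
#' @return Error probability per read.
#' @export
error_rate_from_quality <- function(q, e_min = 1e-10, e_max = 0.75) {
  if (any(q < 0)) stop("Phred quality must be non-negative")
  if (e_min <= 0 || e_max >= 1 || e_min >= e_max) {
    stop("clamp bounds must satisfy 0 < e_min < e_max < 1")
  }
  pmin(pmax(10^(-q / 10), e_min), e_max)
}
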