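# Log-space multinomial machinery for the two-group SNV model.
# Conventions used throughout:
#   * all internal likelihoods are natural logs; user-facing scores are log10
#   * 0 * log(0) == 0 (zero-count allele classes contribute nothing)

# x * log(y) with the 0*log(0) := 0 convention
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

# Elementwise log(exp(a) + exp(b)) that survives a, b far below log(.Machine$double.xmin)
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  ninf <- is.infinite(a) & a < 0 & is.infinite(b) & b < 0
  out[ninf] <- -Inf
  out
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  out <- a + log1p(-exp(b - a))
  out[b == a] <- -Inf
  out
}

#' Log multinomial coefficient for a site's allele counts
#'
#' Natural log of the number of read orderings compatible with the counts
#' `(R, M, X1, X2)` out of `K = R + M + X1 + X2` reads, computed via
#' log-gamma so that deep sequencing depths never overflow.
#'
#' @param K Integer vector, total reads per site.
#' @param R,M,X1,X2 Integer vectors: reference, dominant-alternative and the
#'   two minor-allele read counts. Must satisfy `K == R + M + X1 + X2`.
#' @return Numeric vector of natural-log coefficients.
#' @examples
#' log_multinomial_coef(2, 1, 1, 0, 0) # log(2)
#' @export
log_multinomial_coef <- function(K, R, M, X1, X2) {
  if (any(c(K, R, M, X1, X2) < 0)) {
    stop("allele counts must be non-negative")
  }
  if (any(K != R + M + X1 + X2)) {
    stop("count mismatch: K must equal R + M + X1 + X2")
  }
  lgamma(K + 1) - lgamma(R + 1) - lgamma(M + 1) - lgamma(X1 + 1) - lgamma(X2 + 1)
}

#' Null (no-variant) log-likelihood of a site's read counts
#'
#' Under the null hypothesis the site carries no alternative allele; every
#' non-reference read is a sequencing/mapping error, each error landing on
#' one of the three wrong bases with probability `e/3`. The counts are
#' multinomial, giving
#' \deqn{P(X \mid \theta = 0) = \binom{K}{R, M, X_1, X_2} (1-e)^R (e/3)^{K-R}.}
#'
#' @inheritParams log_multinomial_coef
#' @param e Per-read error probability, recycled across sites. `e = 0` is
#'   accepted with the limit convention: probability 1 when all reads are
#'   reference, probability 0 (`-Inf`) otherwise.
#' @return Natural-log probability, vectorized over sites.
#' @export
log_null_likelihood <- function(K, R, M, X1, X2, e) {
  log_multinomial_coef(K, R, M, X1, X2) + xlogy(R, 1 - e) + xlogy(K - R, e / 3)
}

#' Alternative log-likelihood at a fixed allele frequency
#'
#' Likelihood of the counts given the site is mutant with dominant
#' alternative allele frequency `theta`. A random read shows the reference
#' allele with probability \eqn{p_R = \theta e/3 + (1-\theta)(1-e)}, the
#' dominant alternative with \eqn{p_M = \theta(1-e) + (1-\theta)e/3}, and
#' each minor allele with \eqn{e/3}.
#'
#' @inheritParams log_null_likelihood
#' @param theta Allele frequency in `[0, 1]`, recycled across sites. At
#'   `theta = 0` this reduces exactly to [log_null_likelihood()].
#' @return Natural-log probability, vectorized over sites.
#' @export
log_alt_likelihood_at_theta <- function(K, R, M, X1, X2, e, theta) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  p_r <- theta * e / 3 + (1 - theta) * (1 - e)
  p_m <- theta * (1 - e) + (1 - theta) * e / 3
  log_multinomial_coef(K, R, M, X1, X2) +
    xlogy(R, p_r) + xlogy(M, p_m) + xlogy(X1 + X2, e / 3)
}

#' Alternative log-likelihood under an empirical allele-frequency distribution
#'
#' Approximates the marginal likelihood of the counts under the alternative
#' by an equal-weight atom set (the empirical distribution over a set of
#' suspected-mutant allele frequencies):
#' \deqn{P(X \mid \theta > 0) \approx \frac{1}{s} \sum_{l=1}^{s} P(X \mid \theta_l).}
#' The mixture is evaluated by log-sum-exp, so per-atom log-likelihoods of
#' order \eqn{-10^5} and below do not underflow. Duplicate atoms are
#' aggregated internally into weights; the result is identical to the plain
#' average over the multiset.
#'
#' @inheritParams log_null_likelihood
#' @param atoms Numeric vector of allele-frequency atoms in `(0, 1]`
#'   (duplicates allowed, each with weight `1/length(atoms)`).
#' @return Natural-log probability, vectorized over sites.
#' @export
log_alt_likelihood_empirical <- function(K, R, M, X1, X2, e, atoms) {
  s <- length(atoms)
  if (s == 0L) stop("empty atom set: at least one allele-frequency atom is required")
  n <- max(length(K), length(R), length(M), length(X1), length(X2), length(e))
  K <- rep_len(K, n); R <- rep_len(R, n); M <- rep_len(M, n)
  X1 <- rep_len(X1, n); X2 <- rep_len(X2, n); e <- rep_len(e, n)
  ua <- sort(unique(atoms))
  w <- tabulate(match(atoms, ua), nbins = length(ua)) / s

  lp_r <- log(outer(e / 3, ua) + outer(1 - e, 1 - ua))
  lp_m <- log(outer(1 - e, ua) + outer(e / 3, 1 - ua))
  t_r <- R * lp_r
  if (any(R == 0)) t_r[R == 0, ] <- 0
  t_m <- M * lp_m
  if (any(M == 0)) t_m[M == 0, ] <- 0
  lmat <- t_r + t_m +
    (log_multinomial_coef(K, R, M, X1, X2) + xlogy(X1 + X2, e / 3))

  mx <- apply(lmat, 1L, max)
  out <- mx + log(as.vector(exp(lmat - mx) %*% w))
  out[is.infinite(mx) & mx < 0] <- -Inf
  out
}

#' Local false discovery rate from null and alternative log-likelihoods
#'
#' The LFDR is the posterior probability that a site carries no variant:
#' \deqn{\psi = \frac{\pi_0 P_0}{\pi_0 P_0 + (1-\pi_0) P_1}.}
#' Computed entirely in log space (`log psi = a - logsumexp(a, b)` with
#' `a = log(pi0) + log_p0`, `b = log(1-pi0) + log_p1`), so posterior odds as
#' extreme as \eqn{10^{-1000}} are represented exactly on the log10 scale.
#' Exact at the boundaries `pi0 = 0` (psi 0) and `pi0 = 1` (psi 1).
#'
#' @param log_p0,log_p1 Natural-log likelihoods under the null and the
#'   alternative.
#' @param pi0 Prior proportion of non-mutant sites, in `[0, 1]`.
#' @return A data frame with columns `log10_psi` and `psi` (the latter
#'   underflows to 0 below about `1e-308`; `log10_psi` is authoritative).
#'   Sites where both likelihoods are `-Inf` get `NA` (undefined posterior).
#' @export
lfdr <- function(log_p0, log_p1, pi0) {
  if (any(pi0 < 0 | pi0 > 1)) stop("pi0 must lie in [0, 1]")
  a <- log(pi0) + log_p0
  b <- log1p(-pi0) + log_p1
  log_psi <- a - logsumexp2(a, b)
  log_psi[is.nan(log_psi)] <- NA_real_
  data.frame(log10_psi = log_psi / log(10), psi = exp(log_psi))
}

#' Local false discovery rate from a Bayes factor
#'
#' Re-expression of the LFDR through the null-vs-alternative Bayes factor
#' `BF = P0 / P1`: \eqn{\psi = \pi_0 BF / (\pi_0 BF + 1 - \pi_0)}, i.e.
#' \eqn{PO \cdot BF / (PO \cdot BF + 1)} with prior odds
#' \eqn{PO = \pi_0/(1-\pi_0)}. Identical to [lfdr()] with
#' `log_bf = log_p0 - log_p1`.
#'
#' @param log_bf Natural-log Bayes factor in favour of the null.
#' @param pi0 Prior proportion of non-mutant sites.
#' @return Same shape as [lfdr()].
#' @export
lfdr_from_bayes_factor <- function(log_bf, pi0) {
  lfdr(log_bf, 0, pi0)
}

#' Decision threshold implied by type-I/type-II losses
#'
#' With loss `l_I` for a false call (type I) and `l_II` for a missed
#' variant (type II), calling a variant has posterior expected loss
#' `l_I * psi` and not calling has `l_II * (1 - psi)`, so the Bayes rule
#' calls whenever `psi <= l_II / (l_I + l_II)`. Raising the type-I loss
#' therefore tightens the threshold, and `l_I = l_II` gives `tau = 0.5`.
#'
#' @param l_I,l_II Non-negative losses, not both zero.
#' @return The LFDR threshold `tau` minimizing posterior expected loss.
#' @export
loss_threshold <- function(l_I, l_II) {
  if (any(l_I < 0) || any(l_II < 0) || any(l_I + l_II <= 0)) {
    stop("losses must be non-negative with l_I + l_II > 0")
  }
  l_II / (l_I + l_II)
}

#' Bayes decision rule on LFDR scores
#'
#' Calls a variant (`1`) at every site whose LFDR does not exceed the
#' threshold; the comparison is performed on the log10 scale and the
#' boundary `psi == tau` is a call. This rule minimizes the aggregate
#' posterior expected loss over all sites.
#'
#' @param log10_psi Numeric vector of log10 LFDR scores.
#' @param tau LFDR threshold in `(0, 1]`. If `NULL`, derived from the
#'   losses via [loss_threshold()].
#' @param l_I,l_II Optional losses, used only when `tau` is `NULL`.
#' @return Integer vector of decisions (1 = variant), `NA` where the score
#'   is undefined.
#' @export
decide <- function(log10_psi, tau = NULL, l_I = NULL, l_II = NULL) {
  if (is.null(tau)) {
    if (is.null(l_I) || is.null(l_II)) {
      stop("either tau or both losses (l_I, l_II) must be supplied")
    }
    tau <- loss_threshold(l_I, l_II)
  }
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  as.integer(log10_psi <= log10(tau))
}
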