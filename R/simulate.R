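# Generative simulator for per-site allele-count tables with truth labels.
#
# Emulates the model's exact generative structure: a point mass of
# non-mutant sites (theta = 0) with probability pi0, a bimodal
# allele-frequency distribution at mutant sites (heterozygous mass near
# 0.5, homozygous-alternative mass near 1), and independent per-read
# errors that scatter uniformly over the three wrong bases.

# Beta shape parameters from a mean/sd pair (moment matching)
beta_shapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("sd too large for a Beta on (0,1) with this mean")
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Sample site allele frequencies and truth labels
#'
#' Each site is non-mutant (`theta = 0`) with probability `pi0`; otherwise
#' its dominant alternative allele frequency is drawn from the chosen
#' mixture. The default `"bimodal"` mixture places equal weight on a
#' heterozygous component (Beta matched to mean 0.5, sd 0.035) and a
#' homozygous-alternative component (Beta matched to mean 0.99, sd 0.007),
#' mirroring the concentration of germline allele frequencies around 0.5
#' and 1.
#'
#' @param p Number of sites.
#' @param pi0 Probability that a site is non-mutant.
#' @param g Mutant allele-frequency distribution: `"bimodal"`, `"uniform"`
#'   (Uniform(0, 1)), `"point"` (all at `point_af`), or `"atoms"` (sampled
#'   with replacement from `atoms`).
#' @param point_af Allele frequency used by `g = "point"`.
#' @param atoms Atom set used by `g = "atoms"`.
#' @param het_mean,het_sd,hom_mean,hom_sd,het_weight Bimodal mixture
#'   settings.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `theta` and `mutant` (logical).
#' @export
sample_theta <- function(p, pi0, g = c("bimodal", "uniform", "point", "atoms"),
                         point_af = 0.5, atoms = NULL,
                         het_mean = 0.5, het_sd = 0.035,
                         hom_mean = 0.99, hom_sd = 0.007, het_weight = 0.5,
                         seed = NULL) {
  g <- match.arg(g)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  mutant <- stats::runif(p) >= pi0
  theta <- numeric(p)
  nm <- sum(mutant)
  if (nm > 0) {
    theta[mutant] <- switch(
      g,
      bimodal = {
        het <- beta_shapes(het_mean, het_sd)
        hom <- beta_shapes(hom_mean, hom_sd)
        is_het <- stats::runif(nm) < het_weight
        v <- numeric(nm)
        v[is_het] <- stats::rbeta(sum(is_het), het[1], het[2])
        v[!is_het] <- stats::rbeta(sum(!is_het), hom[1], hom[2])
        v
      },
      uniform = stats::runif(nm),
      point = rep(point_af, nm),
      atoms = {
        if (is.null(atoms) || !length(atoms)) stop("g = \"atoms\" needs a non-empty 'atoms'")
        sample(atoms, nm, replace = TRUE)
      }
    )
  }
  data.frame(theta = theta, mutant = mutant)
}

#' Simulate a bam-readcount style table with truth labels
#'
#' Per site: the reference base is drawn uniformly from A/C/G/T and, for
#' mutant sites, an alternative base uniformly from the remaining three.
#' Read-class counts `(R, M, X1, X2)` are drawn from the four-category
#' multinomial with probabilities \eqn{p_R = \theta e/3 + (1-\theta)(1-e)},
#' \eqn{p_M = \theta(1-e) + (1-\theta)e/3}, \eqn{p_{X_1} = p_{X_2} = e/3}
#' (the multinomial is realized by sequential binomials, which is
#' distributionally identical). Every base class is emitted with
#' `BQ = MQ = -10 log10(e)`, so the quality-derived error model recovers
#' the simulated error rate exactly; an optional Gaussian perturbation of
#' the per-class qualities is available for robustness checks.
#'
#' @param p Number of sites.
#' @param pi0 Probability that a site is non-mutant (default 0.95).
#' @param depth Mean read depth (default 100).
#' @param error Per-read error probability (default 0.01; may be a
#'   length-`p` vector).
#' @param g,point_af,atoms,het_mean,het_sd,hom_mean,hom_sd,het_weight
#'   Passed to [sample_theta()].
#' @param depth_model `"fixed"` (every site at `depth`) or `"poisson"`
#'   (Poisson around `depth`, floored at 1).
#' @param chrom Chromosome label for the synthetic sites.
#' @param quality_noise Standard deviation of optional per-class quality
#'   jitter (default 0, i.e. exact qualities).
#' @param seed Optional RNG seed; the whole simulation is reproducible
#'   given the seed.
#' @return A list with `records` (a `readcounts` data frame, writable via
#'   [write_readcounts()]) and `truth` (chrom, pos, ref, alt — `NA` for
#'   non-mutant sites —, theta, mutant).
#' @export
simulate_readcounts <- function(p, pi0 = 0.95, depth = 100, error = 0.01,
                                g = "bimodal", point_af = 0.5, atoms = NULL,
                                het_mean = 0.5, het_sd = 0.035,
                                hom_mean = 0.99, hom_sd = 0.007, het_weight = 0.5,
                                depth_model = c("fixed", "poisson"),
                                chrom = "sim1", quality_noise = 0, seed = NULL) {
  depth_model <- match.arg(depth_model)
  if (!is.null(seed)) set.seed(seed)
  th <- sample_theta(p, pi0, g = g, point_af = point_af, atoms = atoms,
                     het_mean = het_mean, het_sd = het_sd,
                     hom_mean = hom_mean, hom_sd = hom_sd,
                     het_weight = het_weight)
  e <- rep_len(error, p)
  K <- switch(depth_model,
              fixed = rep_len(round(depth), p),
              poisson = pmax(1L, stats::rpois(p, depth)))

  ref_i <- sample.int(4L, p, replace = TRUE)
  alt_i <- vapply(ref_i, function(r) sample(setdiff(1:4, r), 1L), integer(1))

  p_r <- th$theta * e / 3 + (1 - th$theta) * (1 - e)
  p_m <- th$theta * (1 - e) + (1 - th$theta) * e / 3
  # sequential-binomial realization of the 4-category multinomial
  nR <- stats::rbinom(p, K, p_r)
  rem <- K - nR
  q_m <- ifelse(p_r >= 1, 0, pmin(1, p_m / (1 - p_r)))
  nM <- stats::rbinom(p, rem, q_m)
  rem <- rem - nM
  nX1 <- stats::rbinom(p, rem, 0.5)
  nX2 <- rem - nX1

  cnt <- matrix(0, p, 4L, dimnames = list(NULL, BASES))
  idx <- seq_len(p)
  cnt[cbind(idx, ref_i)] <- nR
  cnt[cbind(idx, alt_i)] <- cnt[cbind(idx, alt_i)] + nM
  # the two leftover bases receive the minor-allele counts in random order
  other <- t(vapply(idx, function(i) setdiff(1:4, c(ref_i[i], alt_i[i])), integer(2)))
  flip <- stats::runif(p) < 0.5
  o1 <- ifelse(flip, other[, 1], other[, 2])
  o2 <- ifelse(flip, other[, 2], other[, 1])
  cnt[cbind(idx, o1)] <- cnt[cbind(idx, o1)] + nX1
  cnt[cbind(idx, o2)] <- cnt[cbind(idx, o2)] + nX2

  q <- -10 * log10(pmax(e, 1e-100)) # e = 0 emits a saturated quality
  q <- pmin(q, 1000)
  qmat <- matrix(q, p, 4L)
  if (quality_noise > 0) {
    qmat <- pmax(qmat + matrix(stats::rnorm(p * 4L, 0, quality_noise), p, 4L), 0)
  }

  records <- data.frame(
    chrom = rep_len(chrom, p), pos = seq_len(p), ref = BASES[ref_i], depth = K,
    count_A = cnt[, "A"], count_C = cnt[, "C"], count_G = cnt[, "G"], count_T = cnt[, "T"],
    mq_A = qmat[, 1], mq_C = qmat[, 2], mq_G = qmat[, 3], mq_T = qmat[, 4],
    bq_A = qmat[, 1], bq_C = qmat[, 2], bq_G = qmat[, 3], bq_T = qmat[, 4],
    stringsAsFactors = FALSE
  )
  class(records) <- c("readcounts", "data.frame")

  truth <- data.frame(
    chrom = records$chrom, pos = records$pos, ref = records$ref,
    alt = ifelse(th$mutant, BASES[alt_i], NA_character_),
    theta = th$theta, mutant = th$mutant,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}
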