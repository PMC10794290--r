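# Log-space likelihoods, LFDR and the Bayes decision rule.

test_that("log multinomial coefficient counts read orderings", {
  expect_equal(log_multinomial_coef(2, 1, 1, 0, 0), log(2))
  expect_equal(log_multinomial_coef(7, 7, 0, 0, 0), 0)
  expect_equal(log_multinomial_coef(3, 1, 1, 1, 0), log(6))
  expect_error(log_multinomial_coef(5, 1, 1, 1, 1), "mismatch")
})

test_that("null likelihood matches closed forms and limit conventions", {
  expect_equal(log_null_likelihood(10, 10, 0, 0, 0, 0.01), 10 * log(0.99))
  expect_equal(log_null_likelihood(10, 10, 0, 0, 0, 0), 0) # error-free, all reference
  expect_identical(log_null_likelihood(10, 9, 1, 0, 0, 0), -Inf) # alt read impossible at e=0
})

test_that("alternative likelihood at fixed theta matches binomial arithmetic", {
  expect_equal(log_alt_likelihood_at_theta(2, 1, 1, 0, 0, 0, 0.5), log(0.5))
  expect_equal(log_alt_likelihood_at_theta(6, 6, 0, 0, 0, 0, 1), -Inf)
  expect_equal(log_alt_likelihood_at_theta(6, 0, 6, 0, 0, 0, 1), 0) # pure-alternative certainty
  # continuity: theta = 0 reduces exactly to the null likelihood
  set.seed(7)
  for (i in 1:10) {
    cc <- as.vector(stats::rmultinom(1, 20, c(0.7, 0.2, 0.06, 0.04)))
    e <- stats::runif(1, 0.001, 0.2)
    expect_equal(
      log_alt_likelihood_at_theta(20, cc[1], cc[2], cc[3], cc[4], e, 0),
      log_null_likelihood(20, cc[1], cc[2], cc[3], cc[4], e)
    )
  }
})

test_that("allele-class probabilities always sum to one", {
  grid <- expand.grid(theta = seq(0, 1, length.out = 100),
                      e = seq(0.001, 0.999, length.out = 100))
  p_r <- grid$theta * grid$e / 3 + (1 - grid$theta) * (1 - grid$e)
  p_m <- grid$theta * (1 - grid$e) + (1 - grid$theta) * grid$e / 3
  expect_true(all(abs(p_r + p_m + 2 * grid$e / 3 - 1) < 1e-12))
})

test_that("null likelihood is a proper distribution over compositions", {
  for (K in c(4, 8, 12)) {
    comp <- compositions4(K)
    tot <- sum(exp(log_null_likelihood(K, comp$R, comp$M, comp$X1, comp$X2, 0.05)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("empirical mixture likelihood reduces and averages correctly", {
  # single atom: identical to the fixed-theta likelihood
  expect_equal(log_alt_likelihood_empirical(10, 5, 5, 0, 0, 0.01, 0.5),
               log_alt_likelihood_at_theta(10, 5, 5, 0, 0, 0.01, 0.5))
  # two atoms: log of the plain linear-domain average
  lin <- oracle_alt_empirical(8, 5, 3, 0, 0, 0.02, c(0.3, 0.7))
  expect_equal(log_alt_likelihood_empirical(8, 5, 3, 0, 0, 0.02, c(0.3, 0.7)),
               log(lin), tolerance = 1e-12)
  # duplicated atoms leave the mean unchanged
  expect_equal(log_alt_likelihood_empirical(8, 5, 3, 0, 0, 0.02, rep(0.4, 5)),
               log_alt_likelihood_at_theta(8, 5, 3, 0, 0, 0.02, 0.4))
  expect_error(log_alt_likelihood_empirical(8, 5, 3, 0, 0, 0.02, numeric()),
               "empty atom")
})

test_that("log-space evaluation matches the linear oracle at modest depth", {
  atoms <- c(0.2, 0.5, 0.9)
  for (e in c(0.01, 0.1)) {
    for (K in c(5, 10)) {
      comp <- compositions4(K)
      for (r in seq_len(nrow(comp))) {
        cc <- comp[r, ]
        expect_equal(
          log_null_likelihood(K, cc$R, cc$M, cc$X1, cc$X2, e),
          log(oracle_null(K, cc$R, cc$M, cc$X1, cc$X2, e)),
          tolerance = 1e-10
        )
        expect_equal(
          log_alt_likelihood_empirical(K, cc$R, cc$M, cc$X1, cc$X2, e, atoms),
          log(oracle_alt_empirical(K, cc$R, cc$M, cc$X1, cc$X2, e, atoms)),
          tolerance = 1e-10
        )
      }
    }
  }
})

test_that("lfdr is exact at the prior boundaries and symmetric at equal evidence", {
  expect_equal(lfdr(-5, -50, 1)$psi, 1)
  expect_equal(lfdr(-5, -50, 0)$psi, 0)
  expect_equal(lfdr(-7.3, -7.3, 0.3)$psi, 0.3)
  expect_true(is.na(lfdr(-Inf, -Inf, 0.5)$psi)) # flagged undefined
})

test_that("lfdr survives a thousand-order-of-magnitude likelihood ratio", {
  res <- lfdr(-1000 * log(10), 0, 0.5)
  expect_equal(res$log10_psi, -1000, tolerance = 1e-6)
  expect_false(is.na(res$log10_psi))
})

test_that("Bayes-factor form is algebraically identical to the likelihood form", {
  expect_equal(lfdr_from_bayes_factor(0, 0.5)$psi, 0.5)
  expect_equal(lfdr_from_bayes_factor(3, 0)$psi, 0)
  set.seed(3)
  for (i in 1:20) {
    lp0 <- -stats::runif(1, 0, 500)
    lp1 <- -stats::runif(1, 0, 500)
    pi0 <- stats::runif(1)
    expect_lt(abs(lfdr_from_bayes_factor(lp0 - lp1, pi0)$log10_psi -
                    lfdr(lp0, lp1, pi0)$log10_psi), 1e-9)
  }
})

test_that("decision rule is boundary-inclusive and loss-derived", {
  expect_equal(decide(log10(0.5), l_I = 1, l_II = 1), 1L) # psi == tau calls
  expect_equal(decide(log10(0.6), l_I = 1, l_II = 1), 0L)
  # a high cost of missing a variant loosens the threshold ...
  expect_equal(loss_threshold(1, 9), 0.9)
  expect_equal(decide(log10(0.85), l_I = 1, l_II = 9), 1L)
  # ... and a high cost of a false call tightens it
  expect_equal(loss_threshold(9, 1), 0.1)
  expect_equal(decide(log10(0.85), l_I = 9, l_II = 1), 0L)
  expect_error(decide(log10(0.5)), "tau or both losses")
})

test_that("the threshold rule minimizes posterior expected loss", {
  # exhaustive check over all decision vectors for random psi and losses
  set.seed(21)
  for (case in 1:25) {
    p <- sample(2:10, 1)
    psi <- stats::runif(p)
    l1 <- stats::runif(1, 0.1, 5)
    l2 <- stats::runif(1, 0.1, 5)
    risk <- function(d) sum(d * l1 * psi + (1 - d) * l2 * (1 - psi))
    all_d <- as.matrix(expand.grid(rep(list(0:1), p)))
    best <- min(apply(all_d, 1, risk))
    rule <- decide(log10(psi), tau = loss_threshold(l1, l2))
    expect_equal(risk(rule), best, tolerance = 1e-12)
  }
})

test_that("psi is non-increasing in the alternative read count", {
  K <- 30
  M <- 0:K
  lp0 <- log_null_likelihood(K, K - M, M, 0, 0, 0.01)
  lp1 <- log_alt_likelihood_empirical(K, K - M, M, 0, 0, 0.01, 0.5)
  psi <- lfdr(lp0, lp1, 0.95)$log10_psi
  expect_true(all(diff(psi) <= 1e-12))
})
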