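# Iterative estimation of pi0 and the allele-frequency atoms (the caller).

test_that("pre-filter drops low-quality sites and computes the error rate", {
  rec <- make_records("chr1", 1:3, "A",
                      list(list(A = 40, C = 10, G = 0, T = 0),
                           list(A = 40, C = 10, G = 0, T = 0),
                           list(A = 40, C = 10, G = 0, T = 0)))
  rec[1, paste0("bq_", c("A", "C", "G", "T"))] <- 19 # weighted BQ below 20
  rec[2, paste0("mq_", c("A", "C", "G", "T"))] <- 29 # weighted MQ below 30
  rec[3, paste0("bq_", c("A", "C", "G", "T"))] <- 30
  rec[3, paste0("mq_", c("A", "C", "G", "T"))] <- 40
  sites <- prefilter_sites(rec, min_bq = 20, min_mq = 30)
  expect_equal(sites$pos, 3L)
  expect_equal(sites$q, 35)
  expect_equal(sites$e, 10^-3.5)
})

test_that("sites with no reads are dropped", {
  rec <- make_records("chr1", 1:2, "A",
                      list(list(A = 0, C = 0, G = 0, T = 0),
                           list(A = 5, C = 0, G = 0, T = 0)))
  sites <- prefilter_sites(rec, min_bq = 0, min_mq = 0)
  expect_equal(sites$pos, 2L)
})

test_that("empirical atoms are the observed non-zero allele frequencies", {
  sites <- data.frame(M = c(5, 0, 20), K = c(10, 20, 20))
  init <- initialize_atoms(sites, "empirical")
  expect_equal(sort(init$atoms), c(0.5, 1.0))
  expect_equal(init$index, c(1L, 3L))
  expect_error(initialize_atoms(data.frame(M = 0, K = 10), "empirical"),
               "uniform")
})

test_that("uniform atoms are seeded, reproducible, and near-uniform", {
  sites <- data.frame(M = 1, K = 2)
  a1 <- initialize_atoms(sites, "uniform", n_atoms = 1000, seed = 99)$atoms
  a2 <- initialize_atoms(sites, "uniform", n_atoms = 1000, seed = 99)$atoms
  expect_identical(a1, a2)
  expect_length(a1, 1000)
  # Kolmogorov distance to the uniform CDF at n = 1000
  ks <- max(abs(sort(a1) - (1:1000) / 1000))
  expect_lt(ks, 0.06)
})

test_that("strong alternative evidence drives psi down, none drives it up", {
  sites <- data.frame(K = c(100, 100), R = c(100, 50), M = c(0, 50),
                      X1 = 0, X2 = 0, e = 0.01)
  res <- site_lfdr(sites, pi0 = 0.99, atoms = 0.5)
  expect_gt(res$psi[1], 0.99)
  expect_lt(res$log10_psi[2], -50)
  # symmetric case: equal likelihoods and pi0 = 0.5 give psi = 0.5
  sym <- lfdr(-3, -3, 0.5)
  expect_equal(sym$psi, 0.5)
})

test_that("self-exclusion removes exactly the site's own atom term", {
  sites <- data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "C",
                      K = 10, R = c(5, 7, 2), M = c(5, 3, 8),
                      X1 = 0, X2 = 0, e = 0.01)
  atoms <- sites$M / sites$K
  res_excl <- site_lfdr(sites, 0.9, atoms, atom_index = 1:3, exclude_self = TRUE)
  for (i in 1:3) {
    loo <- site_lfdr(sites[i, ], 0.9, atoms[-i])
    expect_equal(res_excl$log10_psi[i], loo$log10_psi, tolerance = 1e-9)
  }
})

test_that("all-reference input yields no calls and pi0 = 1", {
  rec <- make_records("chr1", 1:50, "A",
                      rep(list(list(A = 30, C = 0, G = 0, T = 0)), 50))
  fit <- lfdr_call(rec, g_mode = "uniform", min_bq = 0, min_mq = 0, seed = 1)
  expect_equal(nrow(fit$calls), 0L)
  expect_equal(fit$pi0, 1)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
})

test_that("the caller recovers pi0 and the truth on simulated data", {
  sim <- simulate_readcounts(p = 4000, pi0 = 0.95, depth = 100, error = 0.01,
                             seed = 101)
  fit <- lfdr_call(sim$records, g_mode = "empirical", tau = 1e-20,
                   min_bq = 0, min_mq = 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi0 - mean(!sim$truth$mutant)), 0.01)
  ps <- precision_sensitivity(
    confusion_counts(fit$calls, sim$truth[sim$truth$mutant, ])
  )
  expect_gte(ps["precision"], 0.99)
  expect_gte(ps["sensitivity"], 0.95)
  # trajectory bookkeeping
  expect_equal(length(fit$pi0_trajectory), fit$iterations + 1L)
  expect_true(all(fit$pi0_trajectory >= 0 & fit$pi0_trajectory <= 1))
  expect_equal(length(fit$s_trajectory), fit$iterations)
})

test_that("identical inputs and seed give identical fits", {
  sim <- simulate_readcounts(p = 800, pi0 = 0.9, depth = 60, error = 0.01,
                             seed = 55)
  f1 <- lfdr_call(sim$records, g_mode = "uniform-empirical", min_bq = 0,
                  min_mq = 0, seed = 17)
  f2 <- lfdr_call(sim$records, g_mode = "uniform-empirical", min_bq = 0,
                  min_mq = 0, seed = 17)
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$pi0_trajectory, f2$pi0_trajectory)
})

test_that("call sets are nested in the threshold under fixed fitted parameters", {
  sim <- simulate_readcounts(p = 1000, pi0 = 0.9, depth = 40, error = 0.05,
                             seed = 31)
  fit <- lfdr_call(sim$records, min_bq = 0, min_mq = 0)
  taus <- c(1e-40, 1e-20, 1e-5, 0.5, 1)
  sets <- lapply(taus, function(t) which(decide(fit$sites$log10_psi, tau = t) == 1L))
  for (i in seq_along(taus)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("pi0 estimates concentrate around the truth as p grows", {
  est <- function(p, seed) {
    sim <- simulate_readcounts(p = p, pi0 = 0.95, depth = 100, error = 0.01,
                               seed = seed)
    lfdr_call(sim$records, min_bq = 0, min_mq = 0)$pi0
  }
  small <- vapply(1:3, function(s) est(1000, s), numeric(1))
  large <- vapply(1:3, function(s) est(8000, s + 10), numeric(1))
  expect_lt(abs(mean(small) - 0.95), 0.02)
  expect_lt(abs(mean(large) - 0.95), 0.01)
  expect_lte(stats::sd(large), stats::sd(small) + 0.005)
})

test_that("post-filters enforce allele-frequency and depth floors", {
  calls <- data.frame(K = c(1000, 9, 100), M = c(5, 5, 50))
  expect_equal(nrow(postfilter_calls(calls)), 1L) # AF 0.005 and K 9 removed
  expect_equal(postfilter_calls(calls)$K, 100)
  # every surviving call respects both floors by construction
  sim <- simulate_readcounts(p = 500, pi0 = 0.9, depth = 30, error = 0.02, seed = 8)
  fit <- lfdr_call(sim$records, min_bq = 0, min_mq = 0)
  if (nrow(fit$calls)) {
    expect_true(all(fit$calls$M / fit$calls$K >= 0.01))
    expect_true(all(fit$calls$K >= 10))
  }
})

test_that("fit methods print, summarize, predict and simulate coherently", {
  sim <- simulate_readcounts(p = 400, pi0 = 0.9, depth = 50, error = 0.01, seed = 4)
  fit <- lfdr_call(sim$records, min_bq = 0, min_mq = 0)
  expect_output(print(fit), "pi0 estimate")
  expect_output(print(summary(fit)), "trajectory")
  expect_named(coef(fit), "pi0")
  pr <- predict(fit, sim$records)
  expect_equal(pr$delta, fit$sites$delta)
  resim <- simulate(fit, nsim = 1, seed = 2)
  expect_s3_class(resim[[1]]$records, "readcounts")
  expect_equal(nrow(resim[[1]]$records), nrow(fit$sites))
})
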