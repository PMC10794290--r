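# Iterative empirical-Bayes LFDR variant caller.
#
# The procedure: (1) quality pre-filter and per-site error rates; (2) iterate
# score -> tentative calls -> update pi0 -> update allele-frequency atoms
# until pi0 stabilizes; (3) allele-frequency / depth post-filters.

#' Quality pre-filter and per-site error rates
#'
#' Drops sites whose count-weighted mean base-call quality falls below
#' `min_bq` or whose count-weighted mean mapping quality falls below
#' `min_mq`, and sites with no A/C/G/T reads. Retained sites are split
#' into allele classes via [select_alleles()] and annotated with the
#' per-site error rate `e = 10^(-Q/10)` where `Q` is the count-weighted
#' mean of the per-class qualities `(BQ + MQ)/2`.
#'
#' @param records A `readcounts` data frame or path to a count table.
#' @param min_bq,min_mq Minimum weighted mean base-call / mapping quality
#'   (Phred; defaults 20 and 30).
#' @param error_rate Optional global error rate; when supplied, every site
#'   receives this value instead of a quality-derived one.
#' @param e_min,e_max Clamp bounds passed to [error_rate_from_quality()].
#' @return Site table with columns of [select_alleles()] plus `bq`, `mq`,
#'   `q` (weighted qualities) and `e`.
#' @export
prefilter_sites <- function(records, min_bq = 20, min_mq = 30, error_rate = NULL,
                            e_min = 1e-10, e_max = 0.75) {
  records <- as_readcounts(records)
  cnt <- as.matrix(records[, paste0("count_", BASES)])
  bqm <- as.matrix(records[, paste0("bq_", BASES)])
  mqm <- as.matrix(records[, paste0("mq_", BASES)])
  bqm[cnt == 0 | is.na(bqm)] <- 0
  mqm[cnt == 0 | is.na(mqm)] <- 0
  K <- rowSums(cnt)
  wbq <- ifelse(K > 0, rowSums(cnt * bqm) / K, NA_real_)
  wmq <- ifelse(K > 0, rowSums(cnt * mqm) / K, NA_real_)
  keep <- K > 0 & wbq >= min_bq & wmq >= min_mq
  sites <- select_alleles(records[keep, , drop = FALSE])
  sites$bq <- wbq[keep]
  sites$mq <- wmq[keep]
  sites$q <- allele_mean_quality(sites$bq, sites$mq)
  sites$e <- if (is.null(error_rate)) {
    error_rate_from_quality(sites$q, e_min, e_max)
  } else {
    rep(error_rate, nrow(sites))
  }
  rownames(sites) <- NULL
  sites
}

#' Initial allele-frequency atom set
#'
#' In `"empirical"` mode the atoms are the observed alternative allele
#' frequencies `M/K` at every site with at least one dominant-alternative
#' read. In `"uniform"` and `"uniform-empirical"` modes they are `n_atoms`
#' seeded draws from Uniform(0, 1).
#'
#' @param sites Site table from [prefilter_sites()].
#' @param g_mode One of `"empirical"`, `"uniform-empirical"`, `"uniform"`.
#' @param n_atoms Number of uniform atoms (default 1000).
#' @param seed Optional RNG seed for the uniform draws.
#' @return List with `atoms` (numeric vector) and `index` (row indices of
#'   the contributing sites, or `NULL` for uniform draws).
#' @export
initialize_atoms <- function(sites, g_mode = c("empirical", "uniform-empirical", "uniform"),
                             n_atoms = 1000L, seed = NULL) {
  g_mode <- match.arg(g_mode)
  if (g_mode == "empirical") {
    idx <- which(sites$M > 0)
    if (length(idx) == 0L) {
      stop("empirical mode needs at least one site with M > 0; ",
           "use g_mode = \"uniform\" for data without alternative reads")
    }
    list(atoms = sites$M[idx] / sites$K[idx], index = idx)
  } else {
    if (!is.null(seed)) set.seed(seed)
    list(atoms = stats::runif(n_atoms), index = NULL)
  }
}

#' LFDR scores for a set of sites under fixed model parameters
#'
#' One scoring pass: per-site null and empirical-alternative
#' log-likelihoods (each site using its own error rate) combined into the
#' posterior null probability at the given `pi0`.
#'
#' @param sites Site table from [prefilter_sites()].
#' @param pi0 Proportion of non-mutant sites.
#' @param atoms Allele-frequency atom set.
#' @param atom_index Optional row indices of `sites` that contributed the
#'   atoms (needed for `exclude_self`).
#' @param exclude_self If `TRUE`, a site contributing its own allele
#'   frequency to the atom set is scored against the remaining `s - 1`
#'   atoms (its own term is removed in log space). Requires at least two
#'   atoms.
#' @return Data frame with `log10_psi` and `psi` (see [lfdr()]).
#' @export
site_lfdr <- function(sites, pi0, atoms, atom_index = NULL, exclude_self = FALSE) {
  lp0 <- log_null_likelihood(sites$K, sites$R, sites$M, sites$X1, sites$X2, sites$e)
  lp1 <- log_alt_likelihood_empirical(sites$K, sites$R, sites$M, sites$X1, sites$X2,
                                      sites$e, atoms)
  if (exclude_self && !is.null(atom_index) && length(atom_index)) {
    s <- length(atoms)
    if (s < 2L) stop("exclude_self needs at least two atoms")
    i <- atom_index
    own <- log_alt_likelihood_at_theta(sites$K[i], sites$R[i], sites$M[i],
                                       sites$X1[i], sites$X2[i], sites$e[i],
                                       sites$M[i] / sites$K[i])
    lp1[i] <- logdiffexp(lp1[i] + log(s), own) - log(s - 1)
  }
  lfdr(lp0, lp1, pi0)
}

#' Allele-frequency and depth post-filters
#'
#' Retains calls with alternative allele frequency `M/K >= aft` and depth
#' `K >= dpt`.
#'
#' @param calls Data frame of calls carrying `K` and `M` columns.
#' @param aft Allele-frequency threshold (default 0.01).
#' @param dpt Read-depth threshold (default 10).
#' @return The retained subset of `calls`.
#' @export
postfilter_calls <- function(calls, aft = 0.01, dpt = 10) {
  calls[calls$K >= dpt & calls$M / pmax(calls$K, 1) >= aft, , drop = FALSE]
}

#' Empirical Bayes LFDR variant calling
#'
#' Fits the two-group model to a per-site allele-count table and calls
#' germline SNVs. The proportion of non-mutant sites `pi0` and the
#' empirical allele-frequency distribution at mutant sites (an equal-weight
#' atom set) are estimated iteratively: each pass scores every site
#' ([site_lfdr()]), takes the sites at or below the LFDR threshold as
#' tentative variants, re-estimates `pi0` as one minus the called
#' fraction, and (except in `"uniform"` mode) re-estimates the atoms from
#' the tentative variants' allele frequencies. Iteration stops when
#' consecutive `pi0` estimates differ by less than `epsilon`. Final calls
#' are the tentative calls that also pass the allele-frequency and depth
#' post-filters.
#'
#' @param records A `readcounts` data frame (from [parse_readcounts()] or
#'   [simulate_readcounts()]) or a path to a bam-readcount style table.
#' @param g_mode Estimation mode for the alternative allele-frequency
#'   distribution: `"empirical"` (atoms start at all observed non-zero
#'   allele frequencies and are refined each pass), `"uniform-empirical"`
#'   (atoms start as uniform draws, then refined), or `"uniform"` (uniform
#'   draws, never refined).
#' @param tau LFDR call threshold in `(0, 1]` (default `1e-20`). Takes
#'   precedence over the losses.
#' @param l_I,l_II Optional type-I/type-II losses; used to derive `tau`
#'   via [loss_threshold()] when `tau` is `NULL`.
#' @param epsilon Convergence tolerance on `pi0` (default 0.001).
#' @param n_uniform_atoms Number of uniform atoms `N` (default 1000).
#' @param min_bq,min_mq Pre-filter quality thresholds (defaults 20, 30).
#' @param aft,dpt Post-filter allele-frequency and depth thresholds
#'   (defaults 0.01, 10).
#' @param max_iter Iteration cap (default 100).
#' @param error_rate Optional global per-read error rate (e.g. 0.01)
#'   replacing the quality-derived per-site rates.
#' @param pi0_init Initial `pi0`; default is the fraction of sites with no
#'   dominant-alternative read.
#' @param filter_first If `TRUE`, apply the allele-frequency/depth filters
#'   before estimation, so `pi0` refers to the filtered site set.
#' @param exclude_self Remove a site's own allele frequency from the atom
#'   set when scoring that site (default `FALSE`).
#' @param seed RNG seed for the uniform atom draws.
#' @return An object of class `lfdr_call` with components `sites` (all
#'   assayed sites with `log10_psi`, `psi`, `delta`), `calls` (the called
#'   subset after post-filters), `pi0` (final estimate), `pi0_trajectory`
#'   (iteration 0 = initial value), `s_trajectory`, `iterations`,
#'   `converged`, `atoms`, and the configuration.
#' @seealso [prioritize()] for re-scoring an external caller's variants,
#'   [simulate_readcounts()] for generating synthetic input with truth
#'   labels, [write_calls_vcf()] for VCF export.
#' @examples
#' sim <- simulate_readcounts(p = 500, pi0 = 0.9, depth = 60, error = 0.01,
#'                            seed = 7)
#' fit <- lfdr_call(sim$records, min_bq = 0, min_mq = 0)
#' fit
#' coef(fit)
#' @export
lfdr_call <- function(records,
                      g_mode = c("empirical", "uniform-empirical", "uniform"),
                      tau = 1e-20, l_I = NULL, l_II = NULL,
                      epsilon = 0.001, n_uniform_atoms = 1000L,
                      min_bq = 20, min_mq = 30, aft = 0.01, dpt = 10,
                      max_iter = 100L, error_rate = NULL, pi0_init = NULL,
                      filter_first = FALSE, exclude_self = FALSE, seed = NULL) {
  g_mode <- match.arg(g_mode)
  if (is.null(tau)) tau <- loss_threshold(l_I, l_II)
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  if (epsilon <= 0) stop("epsilon must be positive")

  sites <- prefilter_sites(records, min_bq = min_bq, min_mq = min_mq,
                           error_rate = error_rate)
  if (filter_first) sites <- postfilter_calls(sites, aft = aft, dpt = dpt)
  p <- nrow(sites)
  if (p == 0L) stop("no sites retained after pre-filtering")

  if (is.null(pi0_init)) pi0_init <- mean(sites$M == 0)
  init <- initialize_atoms(sites, g_mode, n_atoms = n_uniform_atoms, seed = seed)
  atoms <- init$atoms
  atom_index <- init$index

  pi0 <- pi0_init
  pi0_traj <- pi0_init
  s_traj <- integer()
  converged <- FALSE
  res <- NULL
  called <- integer()
  iter <- 0L

  for (j in seq_len(max_iter)) {
    iter <- j
    res <- site_lfdr(sites, pi0, atoms, atom_index = atom_index,
                     exclude_self = exclude_self)
    called <- which(!is.na(res$log10_psi) & res$log10_psi <= log10(tau))
    pi0_new <- 1 - length(called) / p
    if (g_mode != "uniform") {
      idx <- called[sites$M[called] > 0]
      if (length(idx)) { # an empty tentative set keeps the previous atoms
        atoms <- sites$M[idx] / sites$K[idx]
        atom_index <- idx
      }
    }
    pi0_traj <- c(pi0_traj, pi0_new)
    s_traj <- c(s_traj, length(atoms))
    if (abs(pi0_new - pi0) < epsilon) {
      pi0 <- pi0_new
      converged <- TRUE
      break
    }
    pi0 <- pi0_new
  }
  if (!converged) {
    warning(sprintf("pi0 did not converge within %d iterations", max_iter))
  }

  sites$log10_psi <- res$log10_psi
  sites$psi <- res$psi
  sites$delta <- 0L
  sites$delta[called] <- 1L
  calls <- postfilter_calls(sites[called, , drop = FALSE], aft = aft, dpt = dpt)
  rownames(calls) <- NULL

  structure(list(
    sites = sites, calls = calls, pi0 = pi0,
    pi0_trajectory = pi0_traj, s_trajectory = s_traj,
    iterations = iter, converged = converged,
    atoms = atoms,
    config = list(g_mode = g_mode, tau = tau, epsilon = epsilon,
                  n_uniform_atoms = n_uniform_atoms, min_bq = min_bq,
                  min_mq = min_mq, aft = aft, dpt = dpt, max_iter = max_iter,
                  error_rate = error_rate, pi0_init = pi0_init,
                  filter_first = filter_first, exclude_self = exclude_self,
                  seed = seed)
  ), class = "lfdr_call")
}

#' Called variants from a fit
#'
#' @param object An `lfdr_call` or `lfdr_priority` object.
#' @return Data frame of called (or ranked) variants.
#' @export
variant_calls <- function(object) {
  if (inherits(object, "lfdr_call") || inherits(object, "lfdr_priority")) {
    return(object$calls)
  }
  stop("no variant calls in object of class ", paste(class(object), collapse = "/"))
}

#' @export
print.lfdr_call <- function(x, ...) {
  cat("Empirical Bayes LFDR SNV calls\n")
  cat(sprintf("  sites assayed:  %d (g mode: %s, LFDR threshold: %g)\n",
              nrow(x$sites), x$config$g_mode, x$config$tau))
  cat(sprintf("  pi0 estimate:   %.5f (%d iteration%s, %s)\n",
              x$pi0, x$iterations, if (x$iterations == 1L) "" else "s",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  AF atoms:       %d\n", length(x$atoms)))
  cat(sprintf("  variants called:%5d (AF >= %g, depth >= %g)\n",
              nrow(x$calls), x$config$aft, x$config$dpt))
  invisible(x)
}

#' @export
coef.lfdr_call <- function(object, ...) {
  c(pi0 = object$pi0)
}

#' @export
summary.lfdr_call <- function(object, ...) {
  traj <- data.frame(
    iteration = seq_along(object$pi0_trajectory) - 1L,
    pi0 = object$pi0_trajectory,
    s = c(NA_integer_, object$s_trajectory)
  )
  out <- list(
    fit = object,
    trajectory = traj,
    call_af = if (nrow(object$calls)) summary(object$calls$M / object$calls$K) else NULL,
    log10_psi_range = range(object$sites$log10_psi[is.finite(object$sites$log10_psi)])
  )
  class(out) <- "summary.lfdr_call"
  out
}

#' @export
print.summary.lfdr_call <- function(x, ...) {
  print(x$fit)
  cat("\npi0 trajectory (iteration 0 = initial value):\n")
  print(x$trajectory, row.names = FALSE)
  if (!is.null(x$call_af)) {
    cat("\nalternative allele frequency of calls:\n")
    print(x$call_af)
  }
  cat(sprintf("\nlog10 LFDR range over finite scores: [%.3g, %.3g]\n",
              x$log10_psi_range[1], x$log10_psi_range[2]))
  invisible(x)
}

#' Diagnostic plots for an LFDR fit
#'
#' Panel 1: histogram of per-site log10 LFDR (scores below `floor` are
#' collapsed into the leftmost bin). Panel 2: histogram of the alternative
#' allele frequencies of the called variants, with the fitted atom set as
#' a rug.
#'
#' @param x An `lfdr_call` object.
#' @param which Which panel(s) to draw.
#' @param floor Display floor for log10 LFDR.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.lfdr_call <- function(x, which = 1:2, floor = -50, ...) {
  if (1 %in% which) {
    v <- pmax(x$sites$log10_psi, floor)
    v <- v[!is.na(v)]
    graphics::hist(v, breaks = 40, main = "log10 LFDR across sites",
                   xlab = expression(log[10] ~ psi), ...)
    graphics::abline(v = log10(x$config$tau), lty = 2)
  }
  if (2 %in% which && nrow(x$calls)) {
    graphics::hist(x$calls$M / x$calls$K, breaks = seq(0, 1, by = 0.02),
                   main = "Allele frequency of called variants",
                   xlab = "M / K", ...)
    graphics::rug(x$atoms)
  }
  invisible(x)
}

#' Score new sites with a fitted model
#'
#' Applies the fitted `(pi0, atoms)` and the fit's pre-filter settings to
#' a new count table, without re-estimating anything.
#'
#' @param object An `lfdr_call` fit.
#' @param newdata A `readcounts` data frame or count-table path.
#' @param ... Unused.
#' @return Site table with `log10_psi`, `psi` and `delta` columns.
#' @export
predict.lfdr_call <- function(object, newdata, ...) {
  cfg <- object$config
  sites <- prefilter_sites(newdata, min_bq = cfg$min_bq, min_mq = cfg$min_mq,
                           error_rate = cfg$error_rate)
  res <- site_lfdr(sites, object$pi0, object$atoms)
  sites$log10_psi <- res$log10_psi
  sites$psi <- res$psi
  sites$delta <- decide(res$log10_psi, tau = cfg$tau)
  sites
}

#' Simulate count tables from a fitted model
#'
#' Draws new datasets from the fitted two-group model: each site is
#' non-mutant with probability `pi0`, otherwise its allele frequency is
#' drawn from the fitted atom set; counts are multinomial at the median
#' fitted error rate and depth.
#'
#' @param object An `lfdr_call` fit.
#' @param nsim Number of datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` simulations (each as in
#'   [simulate_readcounts()]).
#' @export
simulate.lfdr_call <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  depth <- stats::median(object$sites$K)
  err <- stats::median(object$sites$e)
  lapply(seq_len(nsim), function(i) {
    simulate_readcounts(p = nrow(object$sites), pi0 = object$pi0,
                        depth = depth, error = err,
                        g = "atoms", atoms = object$atoms)
  })
}
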