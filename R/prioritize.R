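# Single-pass LFDR re-scoring of an external caller's variant list.

#' Prioritize an external caller's variants by LFDR
#'
#' Re-scores a list of SNVs called by any other variant caller and ranks
#' them from most to least probable variant. Unlike the iterative caller,
#' this is a single estimate-then-score pass: `pi0` is estimated as the
#' fraction of assayed sites the external caller did *not* call,
#' `(p - n_called)/p`, and the allele-frequency atom set as the empirical
#' distribution `M/K` at the called sites with `M > 0`. Each call is then
#' scored by [site_lfdr()] with its own quality-derived error rate.
#'
#' Calls are matched to the count table by chromosome and position;
#' unmatched calls are reported and skipped. The caller's ALT allele is
#' trusted: `M` is the read count of that allele (a disagreement with the
#' dominant alternative in the counts is reported), `R` the reference
#' count, and the remaining two base counts become `X1 >= X2`.
#'
#' @param records A `readcounts` data frame or count-table path covering
#'   the assayed sites.
#' @param calls Data frame of external calls with columns `chrom`, `pos`,
#'   `ref`, `alt` (e.g. from [read_external_calls()]).
#' @param min_bq,min_mq,error_rate Pre-filter / error-model settings, as
#'   in [lfdr_call()].
#' @return An object of class `lfdr_priority`: `calls` (the matched calls
#'   with counts, `e`, `log10_psi`, `psi` and `rank`, sorted by ascending
#'   `log10_psi` with chrom/pos tie-break), `pi0`, `atoms`, `n_assayed`,
#'   `n_unmatched`.
#' @seealso [threshold_calls()] to cut the ranking at an LFDR threshold.
#' @export
prioritize <- function(records, calls, min_bq = 20, min_mq = 30,
                       error_rate = NULL) {
  sites <- prefilter_sites(records, min_bq = min_bq, min_mq = min_mq,
                           error_rate = error_rate)
  p <- nrow(sites)
  if (p == 0L) stop("no sites retained after pre-filtering")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(calls))) {
    stop("'calls' must have columns chrom, pos, ref, alt")
  }

  key_site <- paste(sites$chrom, sites$pos)
  m <- match(paste(calls$chrom, calls$pos), key_site)
  unmatched <- sum(is.na(m))
  if (unmatched > 0) {
    message(unmatched, " external call(s) had no count record and were skipped")
  }
  calls <- calls[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  if (nrow(calls) == 0L) stop("no external call matched an assayed site")

  n_called_sites <- length(unique(m))
  pi0 <- (p - n_called_sites) / p

  # counts oriented around the external caller's ALT allele
  cnt_cols <- paste0("count_", BASES)
  s <- sites[m, , drop = FALSE]
  rec <- as_readcounts(records)
  rec_m <- rec[match(paste(s$chrom, s$pos), paste(rec$chrom, rec$pos)), , drop = FALSE]
  cntm <- as.matrix(rec_m[, cnt_cols])
  colnames(cntm) <- BASES
  alt <- toupper(calls$alt)
  if (!all(alt %in% BASES)) stop("external calls must have single-base ACGT ALT alleles")
  n <- nrow(calls)
  M <- cntm[cbind(seq_len(n), match(alt, BASES))]
  R <- cntm[cbind(seq_len(n), match(s$ref, BASES))]
  rest <- vapply(seq_len(n), function(i) {
    sort(cntm[i, setdiff(BASES, c(s$ref[i], alt[i]))], decreasing = TRUE)
  }, numeric(2))
  mismatch <- sum(alt != s$alt & s$M > 0)
  if (mismatch > 0) {
    message(mismatch, " call(s) have an ALT allele differing from the dominant ",
            "alternative in the counts; scored with the caller's ALT count as M")
  }

  ranked <- data.frame(
    chrom = calls$chrom, pos = calls$pos, ref = s$ref, alt = alt,
    K = R + M + rest[1, ] + rest[2, ], R = R, M = M,
    X1 = rest[1, ], X2 = rest[2, ], e = s$e,
    stringsAsFactors = FALSE
  )
  af_pos <- ranked$M > 0
  if (!any(af_pos)) stop("no matched call has alternative reads; cannot estimate g")
  atoms <- ranked$M[af_pos] / ranked$K[af_pos]

  res <- site_lfdr(ranked, pi0, atoms)
  ranked$log10_psi <- res$log10_psi
  ranked$psi <- res$psi
  o <- order(ranked$log10_psi, ranked$chrom, ranked$pos)
  ranked <- ranked[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL

  structure(list(calls = ranked, pi0 = pi0, atoms = atoms,
                 n_assayed = p, n_unmatched = unmatched),
            class = "lfdr_priority")
}

#' @export
print.lfdr_priority <- function(x, ...) {
  cat("LFDR prioritization of external variant calls\n")
  cat(sprintf("  sites assayed: %d, calls scored: %d (%d unmatched)\n",
              x$n_assayed, nrow(x$calls), x$n_unmatched))
  cat(sprintf("  pi0 (reference fraction per caller): %.5f; AF atoms: %d\n",
              x$pi0, length(x$atoms)))
  cat(sprintf("  log10 LFDR range: [%.3g, %.3g]\n",
              min(x$calls$log10_psi), max(x$calls$log10_psi)))
  invisible(x)
}

#' @export
as.data.frame.lfdr_priority <- function(x, ...) x$calls

#' Threshold a ranking (or call table) at an LFDR cutoff
#'
#' Retains the calls with `psi <= tau`. The output is always a subset of
#' the input — thresholding can only remove calls, so sensitivity against
#' any truth set can never increase. Original ranks are preserved.
#'
#' @param x An `lfdr_priority` object or a data frame with a `log10_psi`
#'   column.
#' @param tau LFDR threshold in `[0, 1]` (`tau = 1` keeps everything,
#'   `tau = 0` keeps only exact-zero LFDRs).
#' @return Same class as `x`, restricted to the retained calls.
#' @export
threshold_calls <- function(x, tau) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  cutoff <- if (tau == 0) -Inf else log10(tau)
  if (inherits(x, "lfdr_priority")) {
    keep <- if (tau == 0) x$calls$psi == 0 else x$calls$log10_psi <= cutoff
    x$calls <- x$calls[keep & !is.na(keep), , drop = FALSE]
    return(x)
  }
  keep <- if (tau == 0) 10^x$log10_psi == 0 else x$log10_psi <= cutoff
  x[keep & !is.na(keep), , drop = FALSE]
}
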