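# Independent linear-domain oracles for the multinomial two-group model.
# Deliberately naive (factorials and plain arithmetic, no log space): they
# are only trusted at small K where nothing underflows.

oracle_null <- function(K, R, M, X1, X2, e) {
  factorial(K) / (factorial(R) * factorial(M) * factorial(X1) * factorial(X2)) *
    (1 - e)^R * (e / 3)^(K - R)
}

oracle_alt_theta <- function(K, R, M, X1, X2, e, theta) {
  p_r <- theta * e / 3 + (1 - theta) * (1 - e)
  p_m <- theta * (1 - e) + (1 - theta) * e / 3
  factorial(K) / (factorial(R) * factorial(M) * factorial(X1) * factorial(X2)) *
    p_r^R * p_m^M * (e / 3)^(X1 + X2)
}

oracle_alt_empirical <- function(K, R, M, X1, X2, e, atoms) {
  mean(vapply(atoms, function(th) oracle_alt_theta(K, R, M, X1, X2, e, th),
              numeric(1)))
}

oracle_lfdr <- function(K, R, M, X1, X2, e, atoms, pi0) {
  p0 <- oracle_null(K, R, M, X1, X2, e)
  p1 <- oracle_alt_empirical(K, R, M, X1, X2, e, atoms)
  pi0 * p0 / (pi0 * p0 + (1 - pi0) * p1)
}

# All compositions (R, M, X1, X2) of K into four ordered non-negative parts
compositions4 <- function(K) {
  out <- expand.grid(R = 0:K, M = 0:K, X1 = 0:K)
  out <- out[out$R + out$M + out$X1 <= K, , drop = FALSE]
  out$X2 <- K - out$R - out$M - out$X1
  out
}

# Minimal readcounts table builder for hand-crafted sites
make_records <- function(chrom, pos, ref, counts, mq = 60, bq = 30) {
  n <- length(pos)
  cnt <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) cnt[i, names(counts[[i]])] <- unlist(counts[[i]])
  mqm <- matrix(rep_len(mq, n * 4), n, 4)
  bqm <- matrix(rep_len(bq, n * 4), n, 4)
  out <- data.frame(
    chrom = rep_len(chrom, n), pos = pos, ref = ref, depth = rowSums(cnt),
    count_A = cnt[, 1], count_C = cnt[, 2], count_G = cnt[, 3], count_T = cnt[, 4],
    mq_A = mqm[, 1], mq_C = mqm[, 2], mq_G = mqm[, 3], mq_T = mqm[, 4],
    bq_A = bqm[, 1], bq_C = bqm[, 2], bq_G = bqm[, 3], bq_T = bqm[, 4],
    stringsAsFactors = FALSE
  )
  class(out) <- c("readcounts", "data.frame")
  out
}
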