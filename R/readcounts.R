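# Reading and shaping bam-readcount style per-site allele count tables.
# Coordinates are 1-based and fully closed on every interface.

BASES <- c("A", "C", "G", "T")

#' Parse a bam-readcount style count table
#'
#' Reads the tab-delimited per-position output dialect of bam-readcount:
#' four lead fields (chromosome, 1-based position, reference base, depth)
#' followed by one colon-separated field per base. Within each per-base
#' field only the first four elements are consumed — base, count, mean
#' mapping quality, mean base-call quality — so extra trailing statistics
#' from newer versions are ignored. Fields for non-ACGT "bases" (e.g. `=`
#' or indel records) are skipped. Sites whose reference base is not one of
#' A/C/G/T (e.g. `N`) are dropped with a warning.
#'
#' @param file Path to a count table. Ignored when `text` is given.
#' @param text Optional character vector of lines (mainly for testing).
#' @return A `readcounts` data frame, one row per input line (input order
#'   preserved) with columns `chrom`, `pos`, `ref`, `depth` and, for each
#'   base `B` in A,C,G,T: `count_B`, `mq_B`, `bq_B`.
#' @export
parse_readcounts <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) {
    return(empty_readcounts())
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)

  chrom <- character(n)
  pos <- integer(n)
  ref <- character(n)
  depth <- numeric(n)
  cnt <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
  mq <- matrix(NA_real_, n, 4L, dimnames = list(NULL, BASES))
  bq <- matrix(NA_real_, n, 4L, dimnames = list(NULL, BASES))

  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4L) {
      stop(sprintf("line %d: expected at least 4 tab-separated fields, got %d",
                   i, length(tk)))
    }
    chrom[i] <- tk[1L]
    p <- suppressWarnings(as.integer(tk[2L]))
    d <- suppressWarnings(as.numeric(tk[4L]))
    if (is.na(p) || p < 1L) stop(sprintf("line %d: bad position field '%s'", i, tk[2L]))
    if (is.na(d)) stop(sprintf("line %d: bad depth field '%s'", i, tk[4L]))
    pos[i] <- p
    ref[i] <- toupper(tk[3L])
    depth[i] <- d
    for (fld in tk[-(1:4)]) {
      el <- strsplit(fld, ":", fixed = TRUE)[[1L]]
      b <- toupper(el[1L])
      if (!(b %in% BASES)) next # '=', indels, N pile-ups: not modelled
      if (length(el) < 4L) {
        stop(sprintf("line %d: per-base field '%s' has fewer than 4 elements", i, fld))
      }
      v <- suppressWarnings(as.numeric(el[2:4]))
      if (any(is.na(v))) {
        stop(sprintf("line %d: non-numeric count/quality in field '%s'", i, fld))
      }
      cnt[i, b] <- v[1L]
      mq[i, b] <- v[2L]
      bq[i, b] <- v[3L]
    }
  }

  keep <- ref %in% BASES
  if (!all(keep)) {
    warning(sprintf("dropped %d site(s) with non-ACGT reference base", sum(!keep)))
  }
  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, depth = depth,
    count_A = cnt[, "A"], count_C = cnt[, "C"], count_G = cnt[, "G"], count_T = cnt[, "T"],
    mq_A = mq[, "A"], mq_C = mq[, "C"], mq_G = mq[, "G"], mq_T = mq[, "T"],
    bq_A = bq[, "A"], bq_C = bq[, "C"], bq_G = bq[, "G"], bq_T = bq[, "T"],
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("readcounts", "data.frame")
  out
}

empty_readcounts <- function() {
  out <- data.frame(
    chrom = character(), pos = integer(), ref = character(), depth = numeric(),
    count_A = numeric(), count_C = numeric(), count_G = numeric(), count_T = numeric(),
    mq_A = numeric(), mq_C = numeric(), mq_G = numeric(), mq_T = numeric(),
    bq_A = numeric(), bq_C = numeric(), bq_G = numeric(), bq_T = numeric(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("readcounts", "data.frame")
  out
}

#' Write a count table in the bam-readcount dialect
#'
#' Inverse of [parse_readcounts()]: emits one tab-delimited line per site
#' with per-base `base:count:meanMQ:meanBQ` fields (plus a leading `=`
#' field and trailing placeholder elements, mimicking the native dialect).
#'
#' @param x A `readcounts` data frame.
#' @param file Output path (or connection).
#' @return `file`, invisibly.
#' @export
write_readcounts <- function(x, file) {
  fmt <- function(v) {
    v[is.na(v)] <- 0
    format(v, digits = 15, trim = TRUE, scientific = FALSE)
  }
  base_fields <- lapply(BASES, function(b) {
    sprintf("%s:%s:%s:%s:0:0", b,
            fmt(x[[paste0("count_", b)]]),
            fmt(x[[paste0("mq_", b)]]),
            fmt(x[[paste0("bq_", b)]]))
  })
  lines <- do.call(paste, c(
    list(x$chrom, x$pos, x$ref, fmt(x$depth), "=:0:0:0:0:0"),
    base_fields, sep = "\t"
  ))
  writeLines(lines, file)
  invisible(file)
}

#' Split per-base counts into reference/dominant/minor allele classes
#'
#' For every site, `R` is the reference-base count, `M` the largest count
#' among the three non-reference bases (the dominant alternative), and
#' `X1 >= X2` the remaining two. Ties for the dominant allele are broken
#' by higher mean class quality `(BQ + MQ)/2`, then by alphabetical base
#' order, so the assignment is deterministic. The dominant alternative
#' base is reported even when its count is zero.
#'
#' @param x A `readcounts` data frame (see [parse_readcounts()]).
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`, `K`,
#'   `R`, `M`, `X1`, `X2`; `K = R + M + X1 + X2` counts only A/C/G/T reads.
#' @export
select_alleles <- function(x) {
  n <- nrow(x)
  cnt <- as.matrix(x[, paste0("count_", BASES)])
  mqm <- as.matrix(x[, paste0("mq_", BASES)])
  bqm <- as.matrix(x[, paste0("bq_", BASES)])
  qual <- (ifelse(is.na(bqm), 0, bqm) + ifelse(is.na(mqm), 0, mqm)) / 2
  colnames(cnt) <- colnames(qual) <- BASES

  ref_idx <- match(x$ref, BASES)
  alt <- character(n)
  M <- X1 <- X2 <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(1:4, ref_idx[i])
    o <- j[order(-cnt[i, j], -qual[i, j], j)]
    alt[i] <- BASES[o[1L]]
    M[i] <- cnt[i, o[1L]]
    X1[i] <- cnt[i, o[2L]]
    X2[i] <- cnt[i, o[3L]]
  }
  R <- cnt[cbind(seq_len(n), ref_idx)]
  data.frame(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = alt,
    K = R + M + X1 + X2, R = R, M = M, X1 = X1, X2 = X2,
    stringsAsFactors = FALSE
  )
}

# Coerce a path or data frame to a readcounts table
as_readcounts <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    return(parse_readcounts(records))
  }
  if (!is.data.frame(records) || !all(c("chrom", "pos", "ref", "count_A") %in% names(records))) {
    stop("'records' must be a readcounts data frame or a path to a count table")
  }
  records
}
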