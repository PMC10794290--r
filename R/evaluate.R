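# Evaluation of a call set against a truth list of known variants.

site_key <- function(x, use_alt) {
  if (use_alt) paste(x$chrom, x$pos, toupper(x$alt)) else paste(x$chrom, x$pos)
}

#' Confusion counts of a call set against a truth set
#'
#' `TP` is the number of calls present in the truth set, `FP` the number
#' absent from it, and `FN` the number of truth variants not called. When
#' `assayed` is given, the truth set is first restricted to assayed
#' positions, so `FN` counts only missable variants. Matching uses
#' chromosome, position and (by default) the alternative allele; set
#' `match_alt = FALSE` for position-only matching (reported as a message,
#' since it is a relaxation).
#'
#' @param calls Data frame of calls with `chrom`, `pos` and (for allele
#'   matching) `alt`.
#' @param truth Data frame of known variants, same columns.
#' @param assayed Optional data frame of assayed sites (`chrom`, `pos`)
#'   restricting the truth set.
#' @param match_alt Require the alternative allele to agree (default
#'   `TRUE` when both tables carry an `alt` column).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(calls, truth, assayed = NULL, match_alt = NULL) {
  if (is.null(match_alt)) {
    match_alt <- !is.null(calls$alt) && !is.null(truth$alt)
  }
  if (!match_alt) message("matching by position only (alt allele ignored)")
  if (!is.null(assayed)) {
    truth <- truth[paste(truth$chrom, truth$pos) %in% paste(assayed$chrom, assayed$pos), ,
                   drop = FALSE]
  }
  ck <- unique(site_key(calls, match_alt))
  tk <- unique(site_key(truth, match_alt))
  out <- list(TP = sum(ck %in% tk), FP = sum(!ck %in% tk), FN = sum(!tk %in% ck))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP = %d, FP = %d, FN = %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision and sensitivity from confusion counts
#'
#' `Prec = TP/(TP + FP)` and `Sens = TP/(TP + FN)`. A zero denominator
#' yields an explicit `NA` (undefined), never a silent zero.
#'
#' @param x A `confusion_counts` object (or list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `c(precision, sensitivity)`.
#' @export
precision_sensitivity <- function(x) {
  prec <- if (x$TP + x$FP == 0) NA_real_ else x$TP / (x$TP + x$FP)
  sens <- if (x$TP + x$FN == 0) NA_real_ else x$TP / (x$TP + x$FN)
  c(precision = prec, sensitivity = sens)
}
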