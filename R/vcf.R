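# VCF input (via vcfR) and output of LFDR-scored calls.
# Coordinates are 1-based, as in VCF and the count tables.

#' Read SNV calls from an external caller's VCF
#'
#' Consumes biallelic SNV records from a VCF 4.x file; multiallelic
#' records are split into one call per ALT allele, and non-SNV records
#' (indels, symbolic alleles) are skipped with a reported count. If the
#' INFO field carries `AF`, `L10LFDR` or `RANK` keys, they are returned as
#' columns (useful for round-tripping files written by
#' [write_calls_vcf()]).
#'
#' @param file Path to a VCF file (plain or bgzipped).
#' @param source Label recorded in the `source` column (defaults to the
#'   file name).
#' @return Data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `af`, `l10lfdr`, `rank`, `source`.
#' @export
read_external_calls <- function(file, source = basename(file)) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), l10lfdr = numeric(),
                      rank = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  info_val <- function(key) {
    out <- tryCatch(vcfR::extract.info(v, element = key),
                    error = function(e) rep(NA_character_, n))
    if (is.null(out)) rep(NA_character_, n) else out
  }
  af_raw <- info_val("AF")
  l10_raw <- info_val("L10LFDR")
  rank_raw <- info_val("RANK")

  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  afs <- strsplit(ifelse(is.na(af_raw), "", af_raw), ",", fixed = TRUE)
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ref <- toupper(fix[i, "REF"])
    for (j in seq_along(alts[[i]])) {
      alt <- toupper(alts[[i]][j])
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !(ref %in% BASES) || !(alt %in% BASES) || alt == ref) {
        skipped <- skipped + 1L
        next
      }
      af <- suppressWarnings(as.numeric(
        if (length(afs[[i]]) >= j) afs[[i]][j] else NA_character_))
      rows[[i]] <- rbind(rows[[i]], data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, af = af,
        l10lfdr = suppressWarnings(as.numeric(l10_raw[i])),
        rank = suppressWarnings(as.integer(rank_raw[i])),
        stringsAsFactors = FALSE
      ))
    }
  }
  if (skipped > 0) message(skipped, " non-SNV ALT allele(s) skipped")
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), l10lfdr = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  }
  out$source <- rep_len(source, nrow(out))
  rownames(out) <- NULL
  out
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.finite(x), trimws(formatC(x, digits = digits, format = "g")), ".")
}

#' Write LFDR-scored calls to a VCF 4.2 file
#'
#' Emits one record per call with INFO keys `DP` (total reads `K`), `AD`
#' (reference and alternative read counts), `AF` (`M/K`), `LFDR` (the
#' posterior null probability, which underflows to 0 below about
#' `1e-308`) and `L10LFDR` (log10 LFDR — the authoritative score, exact
#' far below the linear floating-point range). Prioritized calls also get
#' `RANK`. Fit metadata (`pi0`, estimation mode, threshold) is recorded in
#' the header. Records are sorted by chromosome, then position.
#'
#' @param x An `lfdr_call` fit, an `lfdr_priority` ranking, or a data
#'   frame of calls with columns `chrom`, `pos`, `ref`, `alt`, `K`, `R`,
#'   `M`, `log10_psi`, `psi`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_calls_vcf <- function(x, file) {
  meta <- character()
  ranked <- FALSE
  if (inherits(x, "lfdr_call")) {
    meta <- c(sprintf("##lfdrsnv_pi0=%.6g", x$pi0),
              sprintf("##lfdrsnv_g_mode=%s", x$config$g_mode),
              sprintf("##lfdrsnv_tau=%g", x$config$tau))
    calls <- x$calls
  } else if (inherits(x, "lfdr_priority")) {
    meta <- sprintf("##lfdrsnv_pi0=%.6g", x$pi0)
    calls <- x$calls
    ranked <- TRUE
  } else {
    calls <- x
    ranked <- !is.null(calls$rank)
  }

  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=lfdrsnv %s", as.character(utils::packageVersion("lfdrsnv"))),
    meta,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total A/C/G/T read depth (K)\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Reference and dominant alternative read counts (R,M)\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency M/K\">",
    "##INFO=<ID=LFDR,Number=1,Type=Float,Description=\"Local false discovery rate (posterior null probability); 0 when below float range\">",
    "##INFO=<ID=L10LFDR,Number=1,Type=Float,Description=\"log10 LFDR (authoritative score)\">",
    if (ranked) "##INFO=<ID=RANK,Number=1,Type=Integer,Description=\"Priority rank, 1 = most probable variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )

  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    calls <- calls[o, , drop = FALSE]
    # LFDR is clamped to the 32-bit float range of the VCF Float type;
    # L10LFDR carries the full score
    psi_txt <- ifelse(calls$psi < 1e-38, "0", fmt_num(calls$psi))
    info <- sprintf("DP=%d;AD=%d,%d;AF=%s;LFDR=%s;L10LFDR=%s",
                    as.integer(calls$K), as.integer(calls$R), as.integer(calls$M),
                    fmt_num(calls$M / calls$K), psi_txt, fmt_num(calls$log10_psi))
    if (ranked) info <- sprintf("%s;RANK=%d", info, as.integer(calls$rank))
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    calls$chrom, as.integer(calls$pos), calls$ref, calls$alt, info)
  } else {
    recs <- character()
  }
  writeLines(c(hdr, recs), file)
  invisible(file)
}
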