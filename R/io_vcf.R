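## VCF-backed exchange of per-line call records. The call tables carry
## read support (K of N), RMS mapping quality and the caller count in
## INFO; rejected calls can carry the rejecting rule in FILTER.

#' Write per-line variant calls as VCF
#'
#' One VCF per call table (typically one line, or the ancestor). K, N,
#' RMS mapping quality and caller count travel in INFO; when a
#' `reject_reason` column is present it becomes the FILTER tag (PASS
#' otherwise).
#'
#' @param calls Tibble with `chrom, pos, ref, alt, K, N` and optionally
#'   `rms_mq, n_callers, reject_reason`.
#' @param path Output path (`.vcf`; gzipped when the extension is `.gz`).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  calls <- as_tibble(calls) |> arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=K,Number=1,Type=Integer,Description=\"Reads supporting the variant\">",
    "##INFO=<ID=N,Number=1,Type=Integer,Description=\"Total quality reads at site\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=NC,Number=1,Type=Integer,Description=\"Number of independent callers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  filt <- if ("reject_reason" %in% names(calls)) {
    if_else(is.na(calls$reject_reason), "PASS", calls$reject_reason)
  } else rep("PASS", nrow(calls))
  info <- sprintf("K=%d;N=%d;MQ=%.2f;NC=%d",
                  as.integer(calls$K), as.integer(calls$N),
                  calls$rms_mq %||% rep(NA_real_, nrow(calls)),
                  as.integer(calls$n_callers %||% rep(NA_integer_, nrow(calls))))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt, filt, info)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a per-line call VCF written by [write_calls_vcf()]
#'
#' @param path VCF path (plain or gzipped).
#' @param line Line identifier attached to every record.
#' @return Call tibble with `line, chrom, pos, ref, alt, variant_type, K,
#'   N, rms_mq, n_callers, filter`.
#' @export
read_calls_vcf <- function(path, line = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v, getINFO = FALSE)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = as.integer(length(fx) > 0), ncol = 7)
  if (nrow(fx) == 0L) {
    return(tibble(line = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(),
                  variant_type = character(), K = integer(), N = integer(),
                  rms_mq = numeric(), n_callers = integer(),
                  filter = character()))
  }
  tibble(
    line = line, chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
    ref = fx[, "REF"], alt = fx[, "ALT"],
    variant_type = variant_type_of(fx[, "REF"], fx[, "ALT"]),
    K = as.integer(vcfR::extract.info(v, "K")),
    N = as.integer(vcfR::extract.info(v, "N")),
    rms_mq = as.numeric(vcfR::extract.info(v, "MQ")),
    n_callers = as.integer(vcfR::extract.info(v, "NC")),
    filter = fx[, "FILTER"]
  )
}
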