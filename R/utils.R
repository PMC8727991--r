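## shared small helpers; nothing here is exported

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' Thin vectorised wrapper used for triplet collapsing and strand symmetry
#' checks; `N` is preserved.
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("AAT", "GATC"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

## Deterministic 31-bit sub-seed derived from a parent seed and a key path.
## A single global seed drives hierarchical per-line / per-stage streams so
## that subsets of a simulation are reproducible in isolation.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% 2147483629
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_bases <- function(x, arg = deparse(substitute(x))) {
  bad <- !x %in% DNA_BASES
  if (any(bad)) {
    abort(sprintf("`%s` contains non-ACGT values: %s", arg,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

## substring of a per-chromosome sequence kept as a single character scalar
seq_sub <- function(seqstr, start, end) {
  substr(seqstr, start, end)
}
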