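## Triplet sequence-complexity statistic.
##
## For a window a of length n, count each of the 64 possible triplets over
## the l = n - 2 overlapping positions (c_t), and score
##
##   S(a) = sum_t c_t (c_t - 1) / (2 (l - 1)).
##
## S counts pairs of identical triplets, scaled by (l - 1): it is 0 exactly
## when all triplets are distinct and is maximised by homopolymers, i.e.
## larger S means *more* repetitive sequence. Because "low complexity" is
## the field's usual phrasing for repetitive DNA, the normalised complement
##   1 - sum_t c_t (c_t - 1) / (l (l - 1))
## is reported alongside raw S so that directional statements about lower
## complexity near indels can be tested on a statistic that decreases with
## repetitiveness; raw S is always retained.

#' Triplet sequence complexity of windows
#'
#' @param windows Character vector (or `DNAStringSet`) of sequence windows,
#'   each of length >= 3. Windows containing N are flagged and get `NA`
#'   statistics.
#' @return Tibble with one row per window: `n` (window length), `l`
#'   (overlapping triplets, `n - 2`), `S` (raw statistic), `S_complement`
#'   (normalised, in `[0, 1]`, decreasing with repetitiveness) and `flagged`.
#' @export
#' @examples
#' sequence_complexity("AAAAAA") # S = 2
sequence_complexity <- function(windows) {
  if (is(windows, "DNAStringSet")) windows <- as.character(windows)
  if (is(windows, "DNAString")) windows <- as.character(windows)
  windows <- toupper(windows)
  n <- nchar(windows)
  if (any(n < 3L)) abort("complexity windows must be at least 3 bp long")
  has_n <- stringr::str_detect(windows, "[^ACGT]")
  l <- n - 2L
  S <- rep(NA_real_, length(windows))
  Sc <- rep(NA_real_, length(windows))
  ok <- !has_n
  if (any(ok)) {
    cts <- Biostrings::trinucleotideFrequency(
      Biostrings::DNAStringSet(windows[ok]))
    pairs <- rowSums(cts * (cts - 1))
    S[ok] <- if_else(l[ok] > 1L, pairs / (2 * (l[ok] - 1)), 0)
    Sc[ok] <- if_else(l[ok] > 1L, 1 - pairs / (l[ok] * (l[ok] - 1)), 1)
  }
  tibble(n = n, l = l, S = S, S_complement = Sc, flagged = has_n)
}

#' Per-site window statistics (complexity and GC)
#'
#' Computes the triplet complexity statistic and the G+C fraction of a
#' window centred on each site (default width 41 bp, i.e. 20 bp each side).
#' Windows are truncated at contig edges; windows shorter than `min_width`
#' after truncation are flagged and get `NA` statistics, as do windows
#' containing N.
#'
#' @param genome An `ma_genome`.
#' @param sites Data frame with `chrom`, `pos`.
#' @param width Window width in bp (odd; default 41).
#' @param min_width Minimum post-truncation width (default 21).
#' @return Tibble with `chrom, pos, width, S, S_complement, gc, truncated,
#'   flagged`.
#' @export
window_stats <- function(genome, sites, width = 41L, min_width = 21L) {
  stopifnot(inherits(genome, "ma_genome"), width %% 2L == 1L)
  sites <- as_tibble(sites)
  half <- (width - 1L) %/% 2L
  len <- genome$chrom_lengths[sites$chrom]
  start <- pmax(1L, sites$pos - half)
  end <- pmin(unname(len), sites$pos + half)
  win <- substr(genome$seq[sites$chrom], start, end)
  w <- end - start + 1L
  truncated <- w < width
  short <- w < min_width
  cx <- sequence_complexity(if_else(short, strrep("A", 3L), win))
  gcv <- Biostrings::letterFrequency(Biostrings::DNAStringSet(win),
                                     letters = "GC", as.prob = TRUE)[, 1]
  flagged <- short | cx$flagged
  tibble(
    chrom = sites$chrom, pos = sites$pos, width = w,
    S = if_else(flagged, NA_real_, cx$S),
    S_complement = if_else(flagged, NA_real_, cx$S_complement),
    gc = if_else(flagged & short, NA_real_, unname(gcv)),
    truncated = truncated, flagged = flagged
  )
}
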