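# Independent oracles used across test files. These deliberately take the
# slow, obvious route so they share no code path with the implementation.

# Brute-force tandem-repeat enumerator: for every start and unit length,
# count whole copies by direct string comparison; keep left-maximal,
# primitive-motif runs meeting the copy thresholds.
brute_force_repeats <- function(s, min_copies = c(6L, 4L, 4L, 3L, 3L, 3L)) {
  s <- toupper(s)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  rows <- list()
  for (p in 1:6) {
    for (start in seq_len(max(0L, n - p * min_copies[p] + 1L))) {
      unit <- paste(ch[start:(start + p - 1L)], collapse = "")
      if (grepl("[^ACGT]", unit)) next
      # primitive motif?
      prim <- TRUE
      if (p > 1L) {
        for (d in seq_len(p - 1L)) {
          if (p %% d == 0L &&
              unit == strrep(substr(unit, 1, d), p %/% d)) prim <- FALSE
        }
      }
      if (!prim) next
      # left-maximal in the period sense
      if (start > 1L && start + p - 1L <= n &&
          ch[start - 1L] == ch[start + p - 1L] &&
          !grepl("[^ACGT]", ch[start - 1L])) next
      copies <- 1L
      while (start + (copies + 1L) * p - 1L <= n) {
        nxt <- paste(ch[(start + copies * p):(start + (copies + 1L) * p - 1L)],
                     collapse = "")
        if (nxt != unit) break
        copies <- copies + 1L
      }
      if (copies < min_copies[p]) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = start + p * copies - 1L,
        unit_length = p, copy_number = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_length = integer(), copy_number = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# O(l^2) complexity oracle: count pairs of identical overlapping triplets
# directly, then scale by 2(l-1).
brute_force_complexity <- function(window) {
  n <- nchar(window)
  l <- n - 2L
  tri <- substring(window, 1:l, 3:n)
  pairs <- 0L
  for (i in seq_len(l - 1L)) {
    for (j in (i + 1L):l) if (tri[i] == tri[j]) pairs <- pairs + 1L
  }
  pairs / (l - 1L)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
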