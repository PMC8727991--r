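## Microsatellite / homopolymer catalog.
##
## Perfect tandem runs with unit lengths 1-6 bp. Inclusion thresholds follow
## the common microsatellite-extraction convention: homopolymers need >= 6 bp,
## di- and tri-nucleotide repeats >= 4 copies of the motif, tetra- to
## hexa-nucleotide repeats >= 3 copies. Imperfect repeats enter the catalog
## only through the maximal perfect sub-runs that an interruption leaves
## behind, each judged against the same thresholds.

REPEAT_MIN_COPIES <- c(6L, 4L, 4L, 3L, 3L, 3L)

## smallest rotation of a motif, used as its canonical form
canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(m)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1L, i - 1L))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

## a motif is primitive iff it is not a repetition of a shorter unit
is_primitive <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L &&
          m == strrep(substr(m, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

repeat_base_class <- function(motif) {
  letters <- strsplit(motif, "")
  vapply(letters, function(x) {
    if (all(x %in% c("A", "T"))) "AT"
    else if (all(x %in% c("G", "C"))) "GC"
    else "mixed"
  }, character(1))
}

#' Dinucleotide motif family
#'
#' Collapses a dinucleotide motif over rotation and strand into the four
#' conventional families `AT/TA`, `AC/GT`, `AG/CT`, `CG/GC`.
#'
#' @param motif Character vector of 2-bp motifs.
#' @return Character vector of family labels.
#' @export
dinucleotide_family <- function(motif) {
  map <- c(AC = "AC/GT", CA = "AC/GT", GT = "AC/GT", TG = "AC/GT",
           AG = "AG/CT", GA = "AG/CT", CT = "AG/CT", TC = "AG/CT",
           AT = "AT/TA", TA = "AT/TA", CG = "CG/GC", GC = "CG/GC")
  out <- unname(map[motif])
  if (anyNA(out)) abort("dinucleotide_family() expects 2-bp heterogeneous motifs")
  out
}

detect_repeats_chr <- function(s, chrom = NA_character_,
                               min_copies = REPEAT_MIN_COPIES) {
  n <- nchar(s)
  raw <- charToRaw(s)
  ok <- raw == as.raw(65L) | raw == as.raw(67L) | raw == as.raw(71L) | raw == as.raw(84L)
  out <- list()
  for (p in 1:6) {
    if (n < p * min_copies[p]) next
    ## m[i]: position i matches position i+p and both are unambiguous bases
    m <- raw[seq_len(n - p)] == raw[(p + 1L):n]
    m <- m & ok[seq_len(n - p)] & ok[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + p >= p * min_copies[p])
    for (k in hit) {
      reg_start <- starts[k]
      reg_len <- r$lengths[k] + p
      copies <- reg_len %/% p
      if (copies < min_copies[p]) next
      motif <- substr(s, reg_start, reg_start + p - 1L)
      if (!is_primitive(motif)) next
      out[[length(out) + 1L]] <- c(reg_start, reg_start + p * copies - 1L, p, copies)
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  motif = character(), unit_length = integer(),
                  copy_number = integer(), base_class = character()))
  }
  mat <- do.call(rbind, out)
  motif_raw <- substr(rep(s, nrow(mat)), mat[, 1], mat[, 1] + mat[, 3] - 1L)
  tibble(
    chrom = chrom,
    start = as.integer(mat[, 1]), end = as.integer(mat[, 2]),
    motif = canonical_rotation(motif_raw),
    unit_length = as.integer(mat[, 3]),
    copy_number = as.integer(mat[, 4]),
    base_class = repeat_base_class(motif_raw)
  ) |> arrange(.data$start, .data$unit_length)
}

#' Detect perfect tandem repeats
#'
#' Scans for maximal perfect runs of 1-6 bp units. A run qualifies if it
#' reaches 6 bp (homopolymers), 4 copies (di-/tri-nucleotide) or 3 copies
#' (tetra- to hexa-nucleotide units). Motifs are reported as their
#' lexicographically smallest rotation; a run is attributed to its smallest
#' period, so poly-A is a homopolymer, never an (AA)n dinucleotide. An N (or
#' any interruption) splits a candidate into independently judged perfect
#' sub-runs; a trailing partial unit is not part of the catalogued interval.
#'
#' @param x A character vector of sequences, a `DNAString`/`DNAStringSet`,
#'   or an `ma_genome` (all chromosomes scanned).
#' @param min_copies Integer vector of length 6: minimum copy number per
#'   unit length.
#' @return Tibble with `chrom, start, end, motif, unit_length, copy_number,
#'   base_class` (1-based closed coordinates).
#' @export
detect_repeats <- function(x, min_copies = REPEAT_MIN_COPIES) {
  stopifnot(length(min_copies) == 6L, all(min_copies >= 2L | seq_len(6) == 1L))
  if (inherits(x, "ma_genome")) {
    return(bind_rows(lapply(names(x$seq), function(nm) {
      detect_repeats_chr(x$seq[[nm]], chrom = nm, min_copies = min_copies)
    })))
  }
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (is(x, "DNAString")) x <- as.character(x)
  nms <- names(x) %||% as.character(seq_along(x))
  bind_rows(lapply(seq_along(x), function(i) {
    detect_repeats_chr(toupper(x[[i]]), chrom = nms[i], min_copies = min_copies)
  }))
}

#' Split an imperfect repeat region into qualifying perfect sub-runs
#'
#' An imperfect repeat contributes to the catalog only if its interruptions
#' leave at least one maximal perfect sub-run meeting the copy-number
#' thresholds; each sub-run is evaluated independently.
#'
#' @param region Character scalar, the candidate region sequence.
#' @inheritParams detect_repeats
#' @return Tibble of qualifying sub-runs, coordinates relative to `region`.
#' @export
split_imperfect <- function(region, min_copies = REPEAT_MIN_COPIES) {
  stopifnot(is.character(region), length(region) == 1L)
  detect_repeats_chr(toupper(region), chrom = "region", min_copies = min_copies)
}

#' Associate variants with the repeat catalog
#'
#' A variant is `in_repeat` when its affected bases intersect a catalogued
#' run, `adjacent` when it lies within `flank` bp of a run boundary, and
#' `complex` otherwise. Deletions are matched by their deleted span,
#' insertions by the two bases framing the insertion point; ties go to the
#' longest overlapping run.
#'
#' @param variants Tibble with `chrom, pos, ref, alt` (VCF-style anchored
#'   indels) or just `chrom, pos` for point queries.
#' @param catalog Repeat catalog from [detect_repeats()].
#' @param flank Adjacency window in bp (default 1).
#' @return `variants` with `repeat_status, run_motif, run_unit_length,
#'   run_length, run_base_class` appended (`run_length` in bp).
#' @export
map_variant_to_repeat <- function(variants, catalog, flank = 1L) {
  variants <- as_tibble(variants)
  n <- nrow(variants)
  has_alleles <- all(c("ref", "alt") %in% names(variants))
  if (has_alleles) {
    rl <- nchar(variants$ref); al <- nchar(variants$alt)
    vstart <- if_else(rl > al, variants$pos + 1L, variants$pos)          # deletion: deleted span
    vend <- if_else(rl > al, variants$pos + rl - 1L,
                    if_else(al > rl, variants$pos + 1L, variants$pos))   # insertion: framing bases
  } else {
    vstart <- variants$pos; vend <- variants$pos
  }
  status <- rep("complex", n)
  run_cols <- tibble(run_motif = rep(NA_character_, n),
                     run_unit_length = rep(NA_integer_, n),
                     run_length = rep(NA_integer_, n),
                     run_base_class = rep(NA_character_, n))
  if (n == 0L || nrow(catalog) == 0L) {
    return(bind_cols(variants, tibble(repeat_status = status), run_cols))
  }
  qry <- GenomicRanges::GRanges(variants$chrom, IRanges::IRanges(vstart, vend))
  runs <- GenomicRanges::GRanges(catalog$chrom, IRanges::IRanges(catalog$start, catalog$end))
  run_bp <- catalog$end - catalog$start + 1L

  pick <- function(hits) {
    if (!length(hits)) return(NULL)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ord <- order(qh, -run_bp[sh])
    keep <- !duplicated(qh[ord])
    list(q = qh[ord][keep], s = sh[ord][keep])
  }
  near <- pick(GenomicRanges::findOverlaps(qry, runs, maxgap = flank))
  inr <- pick(GenomicRanges::findOverlaps(qry, runs))
  if (!is.null(near)) {
    status[near$q] <- "adjacent"
    run_cols$run_motif[near$q] <- catalog$motif[near$s]
    run_cols$run_unit_length[near$q] <- catalog$unit_length[near$s]
    run_cols$run_length[near$q] <- run_bp[near$s]
    run_cols$run_base_class[near$q] <- catalog$base_class[near$s]
  }
  if (!is.null(inr)) {
    status[inr$q] <- "in_repeat"
    run_cols$run_motif[inr$q] <- catalog$motif[inr$s]
    run_cols$run_unit_length[inr$q] <- catalog$unit_length[inr$s]
    run_cols$run_length[inr$q] <- run_bp[inr$s]
    run_cols$run_base_class[inr$q] <- catalog$base_class[inr$s]
  }
  bind_cols(variants, tibble(repeat_status = status), run_cols)
}
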