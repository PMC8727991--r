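## Mutation-rate estimation and spectrum statistics.
##
## Rates are per site per generation: mu = F / (G * B), with F the mutation
## count in a line, G that line's generations of mutation accumulation, and
## B the callable bases of the genome or genomic subdivision. Experiment
## rates average the line-specific rates; 95% CIs use the t distribution
## over lines.

#' Per-site per-generation mutation rate
#'
#' @param F_var Mutation count.
#' @param G Generations.
#' @param B Callable bases in the queried partition.
#' @return `F_var / (G * B)`, vectorised.
#' @export
mutation_rate <- function(F_var, G, B) {
  stopifnot(all(F_var >= 0), all(G >= 1), all(B >= 1))
  F_var / (G * B)
}

#' Per-line mutation rates, optionally partitioned
#'
#' Counts records per line (and per partition group), fills explicit zeros
#' for lines or groups with no mutations, and converts to rates with each
#' line's own generation number and the partition's callable-base
#' denominator.
#'
#' @param records Mutation records with a `line` column (one row per
#'   accepted mutation).
#' @param lines Tibble `line, generations` for every sequenced line
#'   (zero-mutation lines included).
#' @param B Callable bases: a single number, or a tibble of group columns
#'   plus `bases` when `by` is given.
#' @param by Optional character vector of record columns to partition by.
#' @return Tibble `line, generations, [by], n, bases, rate`.
#' @export
line_rates <- function(records, lines, B, by = NULL) {
  records <- as_tibble(records)
  lines <- as_tibble(lines)
  stopifnot(all(c("line", "generations") %in% names(lines)))
  if (is.null(by)) {
    Btab <- tibble(bases = as.numeric(B))
    grid <- lines
    cnt <- records |> count(.data$line)
  } else {
    stopifnot(is.data.frame(B), all(c(by, "bases") %in% names(B)))
    Btab <- as_tibble(B)
    if (any(Btab$bases <= 0)) {
      skip <- Btab |> filter(.data$bases <= 0)
      warn(sprintf("skipping %d partition(s) with zero callable bases", nrow(skip)))
      Btab <- Btab |> filter(.data$bases > 0)
    }
    grid <- tidyr::crossing(lines, Btab |> select(dplyr::all_of(by)))
    cnt <- records |> count(across(dplyr::all_of(c("line", by))))
  }
  out <- grid |>
    left_join(cnt, by = intersect(names(grid), names(cnt))) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  out <- if (is.null(by)) dplyr::cross_join(out, Btab) else left_join(out, Btab, by = by)
  out |> mutate(rate = .data$n / (.data$generations * .data$bases))
}

#' Average per-line rates with t-based 95% CI
#'
#' @param rates Output of [line_rates()].
#' @param by Grouping columns carried through (defaults to every column
#'   other than line-level ones).
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `mean_rate, sd_rate, sem, ci_half, n_lines` per group.
#' @export
rate_summary <- function(rates, by = NULL, conf = 0.95) {
  rates <- as_tibble(rates)
  by <- by %||% setdiff(names(rates), c("line", "generations", "n", "bases", "rate"))
  rates |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(
      mean_rate = mean(.data$rate),
      sd_rate = sd(.data$rate),
      sem = sd(.data$rate) / sqrt(dplyr::n()),
      ci_half = if (dplyr::n() > 1) {
        qt(1 - (1 - conf) / 2, dplyr::n() - 1) * sd(.data$rate) / sqrt(dplyr::n())
      } else NA_real_,
      n_lines = dplyr::n(),
      .groups = "drop")
}

#' Fold change of rates against a reference spectrum
#'
#' `fold = mean rate / reference rate`. When per-line reference rates are
#' supplied a Welch two-sample t-test on the line-specific rates is run per
#' group; a zero reference leaves the fold undefined and flagged.
#'
#' @param rates Per-line rates from [line_rates()].
#' @param reference Either a tibble of group columns plus `ref_rate`
#'   (means), or per-line reference rates with columns `line, [by], rate`.
#' @param by Optional grouping columns shared by both tables.
#' @return Tibble with `mean_rate, ref_rate, fold` (and `t, p_value` when a
#'   per-line reference was given) per group.
#' @export
fold_change <- function(rates, reference, by = NULL) {
  rates <- as_tibble(rates)
  reference <- as_tibble(reference)
  per_line_ref <- all(c("line", "rate") %in% names(reference))
  smry <- rate_summary(rates, by = by %||% character()) |>
    select(dplyr::all_of(by %||% character()), "mean_rate", "n_lines")
  if (per_line_ref) {
    ref_smry <- rate_summary(reference, by = by %||% character()) |>
      select(dplyr::all_of(by %||% character()), ref_rate = "mean_rate")
  } else {
    ref_smry <- reference |> rename(ref_rate = dplyr::any_of(c("ref_rate", "rate")))
  }
  out <- if (length(by %||% character())) {
    left_join(smry, ref_smry, by = by)
  } else {
    dplyr::cross_join(smry, ref_smry)
  }
  out <- out |>
    mutate(fold = if_else(.data$ref_rate > 0, .data$mean_rate / .data$ref_rate, NA_real_),
           fold_defined = .data$ref_rate > 0)
  if (per_line_ref) {
    groups <- if (length(by %||% character())) {
      out |> select(dplyr::all_of(by))
    } else tibble(.rows = 1)
    tests <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
      x <- rates; y <- reference
      if (length(by %||% character())) {
        for (cl in by) {
          x <- x |> filter(.data[[cl]] == out[[cl]][i])
          y <- y |> filter(.data[[cl]] == out[[cl]][i])
        }
      }
      tt <- tryCatch(t.test(x$rate, y$rate), error = function(e) NULL)
      tibble(t = tt$statistic %||% NA_real_, p_value = tt$p.value %||% NA_real_)
    })
    out <- bind_cols(out, tests)
  }
  out
}

#' Transition/transversion ratio
#'
#' @param records Mutation records with `substitution_class` (and `line`
#'   for per-line mode), or a class-count table with columns
#'   `substitution_class, n`.
#' @param per_line If `TRUE`, return the mean of line-specific ratios
#'   (lines without transversions are dropped with a warning) instead of
#'   the pooled ratio.
#' @return A single number; `NA` (with a warning) when no transversions.
#' @export
tstv_ratio <- function(records, per_line = FALSE) {
  records <- as_tibble(records)
  is_counts <- "n" %in% names(records) && !"line" %in% names(records)
  if (per_line && is_counts) abort("per-line mode needs per-mutation records")
  ratio_of <- function(cls, w) {
    ts <- sum(w[cls %in% TRANSITION_CLASSES])
    tv <- sum(w[!cls %in% TRANSITION_CLASSES])
    if (tv == 0) NA_real_ else ts / tv
  }
  recs <- records |> filter(!is.na(.data$substitution_class))
  if (!per_line) {
    w <- if (is_counts) recs$n else rep(1, nrow(recs))
    r <- ratio_of(recs$substitution_class, w)
    if (is.na(r)) warn("no transversions; Ts/Tv undefined")
    return(r)
  }
  per <- recs |>
    group_by(.data$line) |>
    summarise(r = ratio_of(.data$substitution_class, rep(1, dplyr::n())),
              .groups = "drop")
  if (anyNA(per$r)) warn("lines without transversions dropped from per-line Ts/Tv")
  mean(per$r, na.rm = TRUE)
}

#' AT-ward bias of GC-changing substitutions
#'
#' Fraction of GC-content-changing substitutions that increase A+T content.
#' The raw fraction is `N_toAT / (N_toAT + N_toGC)` (classes `G/C->A/T` and
#' `G/C->T/A` versus `A/T->G/C` and `A/T->C/G`); the composition-normalised
#' version divides each count by the fraction of the genome offering that
#' kind of site:
#' `(N_toAT/f_GC) / (N_toAT/f_GC + N_toGC/f_AT)`. With uniform composition
#' (`f_GC = 0.5`) the normalised value reduces exactly to the raw fraction.
#'
#' @param records Mutation records or class counts (as in [tstv_ratio()]).
#' @param gc_fraction Genomic G+C fraction (`NULL` for raw only).
#' @return Tibble with `n_to_at, n_to_gc, raw, normalized`.
#' @export
at_bias <- function(records, gc_fraction = NULL) {
  records <- as_tibble(records)
  is_counts <- "n" %in% names(records)
  cls <- records$substitution_class
  w <- if (is_counts) records$n else rep(1, nrow(records))
  n_to_at <- sum(w[cls %in% c("G/C->A/T", "G/C->T/A")])
  n_to_gc <- sum(w[cls %in% c("A/T->G/C", "A/T->C/G")])
  raw <- if (n_to_at + n_to_gc > 0) n_to_at / (n_to_at + n_to_gc) else NA_real_
  norm <- NA_real_
  if (!is.null(gc_fraction)) {
    if (gc_fraction <= 0 || gc_fraction >= 1) {
      abort("gc_fraction must be strictly inside (0, 1)")
    }
    a <- n_to_at / gc_fraction
    b <- n_to_gc / (1 - gc_fraction)
    norm <- if (a + b > 0) a / (a + b) else NA_real_
  }
  tibble(n_to_at = n_to_at, n_to_gc = n_to_gc, raw = raw, normalized = norm)
}

#' Indel size accounting
#'
#' Signed-size bookkeeping over indel records: size histogram by type,
#' 1-bp fractions, deletion:insertion ratio, and the net base-pair change
#' (negative = genome shrinkage), overall and per line.
#'
#' @param records Mutation records with `indel_size` (negative deletions),
#'   optionally `line`.
#' @return List with `totals` (one-row tibble), `size_histogram` and
#'   `per_line` tibbles.
#' @export
indel_summary <- function(records) {
  records <- as_tibble(records) |> filter(!is.na(.data$indel_size))
  del <- records |> filter(.data$indel_size < 0)
  ins <- records |> filter(.data$indel_size > 0)
  totals <- tibble(
    n_indels = nrow(records),
    n_del = nrow(del), n_ins = nrow(ins),
    n_del_1bp = sum(del$indel_size == -1L),
    n_ins_1bp = sum(ins$indel_size == 1L),
    frac_del_1bp = if (nrow(del)) mean(del$indel_size == -1L) else NA_real_,
    frac_ins_1bp = if (nrow(ins)) mean(ins$indel_size == 1L) else NA_real_,
    del_ins_ratio = if (nrow(ins)) nrow(del) / nrow(ins) else NA_real_,
    deletion_fraction = if (nrow(records)) nrow(del) / nrow(records) else NA_real_,
    net_bp = sum(records$indel_size),
    net_bp_1bp = sum(records$indel_size[abs(records$indel_size) == 1L])
  )
  hist <- records |>
    mutate(type = if_else(.data$indel_size < 0, "deletion", "insertion"),
           size = abs(.data$indel_size)) |>
    count(.data$type, .data$size)
  per_line <- if ("line" %in% names(records)) {
    records |>
      group_by(.data$line) |>
      summarise(n_del = sum(.data$indel_size < 0),
                n_ins = sum(.data$indel_size > 0),
                net_bp = sum(.data$indel_size), .groups = "drop")
  } else tibble()
  list(totals = totals, size_histogram = hist, per_line = per_line)
}

#' Heteroplasmy-weighted mitochondrial mutation rate
#'
#' Each mitochondrial variant contributes its intracellular frequency
#' (fraction of quality reads carrying it); a multi-bp deletion is one
#' event at its frequency. Line rates are `sum(f) / (L_mt * G)` and the
#' overall rate averages across all lines, including lines without
#' mutations; the rate is therefore linear in the frequencies.
#'
#' @param variants Tibble `line, frequency` (`0 < f <= 1`), one row per
#'   heteroplasmic variant; may be empty.
#' @param lines Tibble `line, generations` for every sequenced line.
#' @param L_mt Mitochondrial callable length in bp (default 13794, the
#'   C. elegans mtDNA length; override with a callable-site count when
#'   available).
#' @return List with `per_line` rates and the one-row `summary`
#'   (`mean_rate, ci_half, n_lines`).
#' @export
mito_rate <- function(variants, lines, L_mt = 13794) {
  variants <- as_tibble(variants)
  lines <- as_tibble(lines)
  stopifnot(L_mt > 0)
  if (nrow(variants) && (any(variants$frequency <= 0) || any(variants$frequency > 1))) {
    abort("heteroplasmy frequencies must lie in (0, 1]")
  }
  fsum <- if (nrow(variants)) {
    variants |> group_by(.data$line) |> summarise(f = sum(.data$frequency), .groups = "drop")
  } else tibble(line = character(), f = numeric())
  per_line <- lines |>
    left_join(fsum, by = "line") |>
    mutate(f = dplyr::coalesce(.data$f, 0),
           rate = .data$f / (L_mt * .data$generations))
  smry <- per_line |>
    summarise(mean_rate = mean(.data$rate),
              ci_half = if (dplyr::n() > 1)
                qt(0.975, dplyr::n() - 1) * sd(.data$rate) / sqrt(dplyr::n()) else NA_real_,
              n_lines = dplyr::n())
  list(per_line = per_line, summary = smry)
}

#' Compare per-line rates between genomic partitions
#'
#' Runs an analysis of variance on line-specific rates across partition
#' levels, plus a paired t-test for the two-level case (each line
#' contributes one rate per level, so pairing is within line). With fewer
#' than two lines only the descriptive summary is returned.
#'
#' @param rates Per-line rates from [line_rates()] with one partition
#'   column.
#' @param partition Name of the partition column.
#' @param paired Use a paired t-test (requires exactly two levels).
#' @return List with `summary` (per-level [rate_summary()]), `anova`
#'   tibble, and `t_test` tibble (two-level case).
#' @export
partition_compare <- function(rates, partition, paired = FALSE) {
  rates <- as_tibble(rates)
  stopifnot(partition %in% names(rates))
  smry <- rate_summary(rates, by = partition)
  n_lines <- dplyr::n_distinct(rates$line)
  if (n_lines < 2) {
    return(list(summary = smry, anova = tibble(), t_test = tibble()))
  }
  lv <- unique(rates[[partition]])
  av <- aov(rate ~ part, data = tibble(rate = rates$rate,
                                       part = factor(rates[[partition]])))
  avs <- summary(av)[[1]]
  anova_tbl <- tibble(term = partition,
                      df = avs$Df[1], statistic = avs$`F value`[1],
                      p_value = avs$`Pr(>F)`[1])
  ttab <- tibble()
  if (length(lv) == 2) {
    wide <- rates |>
      select("line", dplyr::all_of(partition), "rate") |>
      tidyr::pivot_wider(names_from = dplyr::all_of(partition), values_from = "rate")
    tt <- t.test(wide[[lv[1]]], wide[[lv[2]]], paired = paired)
    ttab <- tibble(comparison = paste(lv, collapse = " vs "),
                   paired = paired,
                   mean_difference = mean(wide[[lv[1]]] - wide[[lv[2]]], na.rm = TRUE),
                   t = unname(tt$statistic), p_value = tt$p.value)
  }
  list(summary = smry, anova = anova_tbl, t_test = ttab)
}
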