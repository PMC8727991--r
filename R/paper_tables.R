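## Published summary tables of the MMR-impaired outcrossing MA study,
## transcribed once as in-code fixtures, plus the recomputation of every
## derived statistic from them. The transcription is validated against its
## own internal sums on every load so silent drift is impossible.

#' Published reference tables of the MMR-impaired MA experiment
#'
#' Returns the printed summary tables of the study this pipeline
#' re-implements: per-class mutation rates with fold changes versus
#' wildtype selfing MA lines (`table1`, units 1e-7 /site/generation;
#' copy-number rows per gene per generation), the complex/repeat partition
#' of the six substitution classes (`table2`), the five heteroplasmic
#' mitochondrial variants (`table3`), and scalar `constants` (line count,
#' mean generations, indel size tallies, genomic G+C, mtDNA length).
#' Internal consistency (row sums, partition totals, fold arithmetic) is
#' re-checked on every call.
#'
#' @return List of tibbles `table1`, `table2`, `table3` and the named list
#'   `constants`.
#' @export
ma_reference_tables <- function() {
  table1 <- tibble(
    class = c("snp", "indel", "deletion", "insertion", "mito",
              "cnv_gain", "cnv_loss"),
    wt = c(0.0184, 0.0068, 0.0051, 0.0018, 1.05, 26.40, 11.90),
    knockdown = c(0.42, 2.23, 1.47, 0.76, 2.18, 10.70, 3.95),
    printed_fold = c(22.93, 327.94, 288.24, 422.22, 2.08, 0.41, 0.33)
  )
  table2 <- tibble(
    substitution_class = SUBSTITUTION_CLASSES,
    total = c(886, 545, 403, 768, 494, 29),
    complex = c(832, 98, 367, 708, 472, 27),
    repeat_seq = c(54, 447, 36, 60, 22, 2)
  )
  table3 <- tibble(
    line = c("16", "16", "38", "34", "4"),
    generation = c(33, 33, 43, 43, 44),
    position = c("721", "6361-7394", "8872", "11722", "11722"),
    mutation = c("T->C", "1034 bp del", "C->T", "(T)8->(T)9", "(T)8->(T)9"),
    effect = c("nonsynonymous", "frameshift", "nonsynonymous",
               "frameshift", "frameshift"),
    frequency = c(0.937, 0.817, 0.034, 0.040, 0.049)
  )
  constants <- list(
    n_lines = 19L, mean_generations = 40.3,
    n_snps = 3125L, n_indels = 10861L,
    n_del = 7180L, n_ins = 3681L,
    n_del_1bp = 6960L, n_ins_1bp = 3513L,
    net_loss_gt1bp = 381L,
    genome_gc = 0.36, mito_length = 13794L
  )
  ## checksum: the transcription must satisfy the printed row/column sums
  stopifnot(
    sum(table2$total) == constants$n_snps,
    sum(table2$complex) == 2504L,
    sum(table2$repeat_seq) == 621L,
    all(table2$total == table2$complex + table2$repeat_seq),
    constants$n_del + constants$n_ins == constants$n_indels,
    all(abs(table1$printed_fold - table1$knockdown / table1$wt) /
          table1$printed_fold < 0.02),
    nrow(table3) == 5L, all(table3$frequency > 0 & table3$frequency <= 1)
  )
  list(table1 = table1, table2 = table2, table3 = table3,
       constants = constants)
}

table2_records <- function(table2, count_col) {
  tibble(substitution_class = rep(table2$substitution_class,
                                  table2[[count_col]]))
}

#' Recompute the study's derived statistics from the printed tables
#'
#' Runs the package's spectrum/rate operations on the table fixtures
#' alone: pooled Ts/Tv, the share of repeat-located substitutions that are
#' A/T->T/A, the repeat-association fraction of A/T->T/A, the
#' composition-normalised AT-ward bias, indel net-loss accounting, the
#' combined nuclear rate, insertion/deletion/substitution fold changes,
#' and the heteroplasmy-weighted mitochondrial rate. No derived number is
#' hand-entered; everything flows from the fixture counts and rates.
#'
#' @param tables Output of [ma_reference_tables()].
#' @return Named list of derived statistics (an `ma_results` bundle).
#' @export
recompute_results <- function(tables = ma_reference_tables()) {
  t1 <- tables$table1; t2 <- tables$table2; t3 <- tables$table3
  k <- tables$constants
  counts <- t2 |> select("substitution_class", n = "total")

  tstv <- tstv_ratio(counts)
  rep_counts <- t2 |> select("substitution_class", n = "repeat_seq")
  at_ta_share_of_repeat <-
    rep_counts$n[rep_counts$substitution_class == "A/T->T/A"] / sum(rep_counts$n)
  at_ta_repeat_assoc <-
    t2$repeat_seq[t2$substitution_class == "A/T->T/A"] /
    t2$total[t2$substitution_class == "A/T->T/A"]
  bias <- at_bias(counts, gc_fraction = k$genome_gc)

  one_bp <- tibble(indel_size = c(rep(-1L, k$n_del_1bp), rep(1L, k$n_ins_1bp)))
  acc <- indel_summary(one_bp)$totals
  net_1bp <- acc$net_bp
  net_total <- net_1bp - k$net_loss_gt1bp
  frac_del_1bp <- k$n_del_1bp / k$n_del
  frac_ins_1bp <- k$n_ins_1bp / k$n_ins

  rate_of <- function(cl) t1$knockdown[t1$class == cl] * 1e-7
  wt_of <- function(cl) t1$wt[t1$class == cl] * 1e-7
  combined_rate <- rate_of("snp") + rate_of("indel")
  folds <- setNames(
    (t1$knockdown / t1$wt)[match(c("snp", "indel", "deletion", "insertion"),
                                 t1$class)],
    c("snp", "indel", "deletion", "insertion"))

  carrier_g <- t3 |> distinct(.data$line, .data$generation)
  mito_lines <- bind_rows(
    carrier_g |> rename(generations = "generation"),
    tibble(line = sprintf("z%02d", seq_len(k$n_lines - nrow(carrier_g))),
           generations = k$mean_generations))
  mt <- mito_rate(t3 |> select("line", "frequency"), mito_lines,
                  L_mt = k$mito_length)

  list(
    tstv_pooled = tstv,
    at_ta_share_of_repeat_substitutions = at_ta_share_of_repeat,
    at_ta_repeat_association = at_ta_repeat_assoc,
    at_bias_raw = bias$raw,
    at_bias_normalized = bias$normalized,
    net_loss_1bp = -net_1bp,
    net_loss_total = -net_total,
    net_loss_per_genome = -net_total / k$n_lines,
    frac_del_1bp = frac_del_1bp,
    frac_ins_1bp = frac_ins_1bp,
    combined_nuclear_rate = combined_rate,
    fold_snp = unname(folds["snp"]),
    fold_indel = unname(folds["indel"]),
    fold_deletion = unname(folds["deletion"]),
    fold_insertion = unname(folds["insertion"]),
    mito_rate = mt$summary$mean_rate,
    mito_rate_ci_half = mt$summary$ci_half
  )
}

#' Summarise a pipeline run as a results bundle
#'
#' Aggregates classified mutation records of one experiment (real or
#' simulated) into the same shape as the published-table recomputation:
#' per-class rates, Ts/Tv, AT bias, repeat shares and indel accounting.
#' Empty runs produce a bundle of zeros with a note rather than an error.
#'
#' @param records Classified mutation records.
#' @param lines Tibble `line, generations`.
#' @param genome The analysed `ma_genome` (for B and base composition).
#' @return Named list (an `ma_results` bundle).
#' @export
experiment_report <- function(records, lines, genome) {
  records <- as_tibble(records)
  B <- callable_bases(genome)
  gc_frac <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(genome$seq), letters = c("G", "C"))) /
    sum(genome$chrom_lengths)
  snps <- records |> filter(.data$variant_type == "snp")
  indels <- records |> filter(.data$variant_type != "snp")
  if (nrow(records) == 0L) {
    return(list(note = "no mutations", n_snps = 0, n_indels = 0,
                snp_rate = 0, indel_rate = 0, tstv_pooled = NA_real_,
                at_bias_normalized = NA_real_, net_loss_total = 0))
  }
  snp_rt <- rate_summary(line_rates(snps, lines, B), by = character())
  ind_rt <- rate_summary(line_rates(indels, lines, B), by = character())
  class_rt <- rate_summary(line_rates(snps, lines,
                                      tidyr::crossing(substitution_class = SUBSTITUTION_CLASSES,
                                                      bases = B),
                                      by = "substitution_class"),
                           by = "substitution_class")
  acc <- indel_summary(indels)$totals
  bias <- at_bias(snps, gc_fraction = gc_frac)
  list(
    n_snps = nrow(snps), n_indels = nrow(indels),
    snp_rate = snp_rt$mean_rate, snp_rate_ci_half = snp_rt$ci_half,
    indel_rate = ind_rt$mean_rate, indel_rate_ci_half = ind_rt$ci_half,
    combined_rate = snp_rt$mean_rate + ind_rt$mean_rate,
    class_rates = class_rt |> select("substitution_class", "mean_rate", "ci_half"),
    tstv_pooled = if (nrow(snps)) tstv_ratio(snps) else NA_real_,
    at_bias_raw = bias$raw, at_bias_normalized = bias$normalized,
    deletion_fraction = acc$deletion_fraction,
    frac_del_1bp = acc$frac_del_1bp, frac_ins_1bp = acc$frac_ins_1bp,
    net_loss_total = -acc$net_bp
  )
}

#' Render a results bundle as human-readable text plus machine JSON
#'
#' Field names are stable and ordered; numbers carry explicit units in the
#' text rendering. Rendering the same bundle twice yields byte-identical
#' JSON.
#'
#' @param results Named list, e.g. from [recompute_results()] or
#'   [experiment_report()].
#' @param json_path Optional path; the JSON is written there when given.
#' @return The JSON string, invisibly; the text summary is printed.
#' @export
render_report <- function(results, json_path = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  ord <- results[order(names(results))]
  js <- jsonlite::toJSON(ord, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  if (!is.null(json_path)) writeLines(js, json_path)
  for (nm in names(ord)) {
    v <- ord[[nm]]
    if (is.numeric(v) && length(v) == 1L) {
      cat(sprintf("%-40s %s\n", nm, format(v, digits = 6)))
    } else if (is.character(v) && length(v) == 1L) {
      cat(sprintf("%-40s %s\n", nm, v))
    }
  }
  invisible(as.character(js))
}
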