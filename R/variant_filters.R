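## Candidate-call acceptance pipeline.
##
## Stage 1, hard thresholds: root-mean-square mapping quality (30 for SNPs,
## 40 for indels), minimum supporting reads (3 / 5), >= 80% of high-quality
## calls at the position supporting the variant, independent calls from at
## least two callers, and zero supporting evidence in the ancestral control.
##
## Stage 2, cross-line verification: for each surviving variant position the
## supporting reads are summed over every sequenced line (carriers and
## non-carriers) and divided by the total reads there, giving the chance P
## that any single read calls the variant by noise alone. Each carrier call
## is then scored with the binomial point mass C(N,K) P^K (1-P)^(N-K), and a
## Holm-Bonferroni step-down over all candidate variants decides retention:
## a significant (small) probability means the observed support is
## inconsistent with shared noise, so the variant is kept.

#' Hard-filter configuration
#'
#' @param min_rms_mq_snp,min_rms_mq_indel Minimum RMS mapping quality.
#' @param min_reads_snp,min_reads_indel Minimum supporting reads K.
#' @param min_support_fraction Minimum K/N at the variant position.
#' @param min_callers Minimum number of independent callers.
#' @param alpha Significance level for the Holm-Bonferroni step.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_rms_mq_snp = 30, min_rms_mq_indel = 40,
                          min_reads_snp = 3L, min_reads_indel = 5L,
                          min_support_fraction = 0.80, min_callers = 2L,
                          alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, min_support_fraction >= 0,
            min_reads_snp >= 0, min_reads_indel >= 0)
  structure(list(min_rms_mq_snp = min_rms_mq_snp,
                 min_rms_mq_indel = min_rms_mq_indel,
                 min_reads_snp = min_reads_snp,
                 min_reads_indel = min_reads_indel,
                 min_support_fraction = min_support_fraction,
                 min_callers = min_callers, alpha = alpha),
            class = "filter_config")
}

variant_type_of <- function(ref, alt) {
  dplyr::case_when(nchar(ref) == nchar(alt) & nchar(ref) == 1L ~ "snp",
                   nchar(alt) > nchar(ref) ~ "insertion",
                   nchar(ref) > nchar(alt) ~ "deletion",
                   TRUE ~ "other")
}

#' Apply hard threshold filters to candidate calls
#'
#' A call survives iff it passes the mapping-quality, read-count,
#' support-fraction and caller-count thresholds and has no supporting read
#' in the ancestral control at the same position and allele (ancestral
#' presence, even at low quality or coverage, removes the candidate). The
#' first failing rule, in a fixed order, is recorded as the rejection
#' reason.
#'
#' @param calls Tibble of candidate calls with `line, chrom, pos, ref, alt,
#'   K, N, rms_mq, n_callers` (a `variant_type` column is derived from
#'   ref/alt if absent).
#' @param ancestor_calls Tibble of ancestral-control records with `chrom,
#'   pos, alt, K` (K > 0 marks ancestral support).
#' @param config A [filter_config()].
#' @return The calls with `pass` (logical) and `reject_reason` (`NA` when
#'   passed) appended; the per-rule rejection count table is attached as
#'   attribute `"rejection_log"` (also via [hard_filter_log()]).
#' @export
apply_hard_filters <- function(calls, ancestor_calls = NULL,
                               config = filter_config()) {
  calls <- as_tibble(calls)
  if (!"variant_type" %in% names(calls)) {
    calls$variant_type <- variant_type_of(calls$ref, calls$alt)
  }
  if (any(abs(nchar(calls$alt) - nchar(calls$ref)) > 100L)) {
    abort("indels longer than 100 bp are outside the model's scope")
  }
  is_snp <- calls$variant_type == "snp"
  min_mq <- if_else(is_snp, config$min_rms_mq_snp, config$min_rms_mq_indel)
  min_k <- if_else(is_snp, as.numeric(config$min_reads_snp),
                   as.numeric(config$min_reads_indel))

  in_ancestor <- rep(FALSE, nrow(calls))
  if (!is.null(ancestor_calls) && nrow(ancestor_calls) > 0) {
    anc <- as_tibble(ancestor_calls) |>
      filter(.data$K > 0) |>
      distinct(.data$chrom, .data$pos, .data$alt) |>
      mutate(.anc = TRUE)
    in_ancestor <- (calls |>
                      left_join(anc, by = c("chrom", "pos", "alt")) |>
                      pull(".anc")) %in% TRUE
  }

  reason <- dplyr::case_when(
    calls$N == 0L ~ "no_coverage",
    in_ancestor ~ "present_in_ancestor",
    calls$rms_mq < min_mq ~ if_else(is_snp, "min_rms_mq_snp", "min_rms_mq_indel"),
    calls$K < min_k ~ if_else(is_snp, "min_reads_snp", "min_reads_indel"),
    calls$K / calls$N < config$min_support_fraction ~ "support_fraction",
    calls$n_callers < config$min_callers ~ "min_callers",
    TRUE ~ NA_character_
  )
  out <- calls |> mutate(pass = is.na(reason), reject_reason = reason)
  attr(out, "rejection_log") <- out |>
    filter(!.data$pass) |>
    count(.data$reject_reason, name = "n_rejected") |>
    arrange(dplyr::desc(.data$n_rejected))
  out
}

#' Per-rule rejection counts from a hard-filtered call set
#' @param filtered Output of [apply_hard_filters()].
#' @return Tibble `reject_reason`, `n_rejected`.
#' @export
hard_filter_log <- function(filtered) {
  attr(filtered, "rejection_log") %||%
    (filtered |> filter(!.data$pass) |> count(.data$reject_reason, name = "n_rejected"))
}

#' Cross-line error-rate estimate at variant positions
#'
#' For each variant position, the probability that any given read calls the
#' variant by chance is estimated as P = (sum of supporting reads K over all
#' sequenced lines, carriers and non-carriers alike) / (sum of total reads N
#' there).
#'
#' @param coverage Tibble with `chrom, pos, line, K, N` covering every
#'   sequenced line at each variant position (include `alt` to resolve
#'   multi-allelic positions).
#' @return Tibble with one row per position (`chrom, pos[, alt]`) and
#'   columns `sum_K, sum_N, P, n_lines`; positions where no line has
#'   coverage get `P = NA` and `defined = FALSE`.
#' @export
cross_line_error_rate <- function(coverage) {
  coverage <- as_tibble(coverage)
  keys <- intersect(c("chrom", "pos", "alt"), names(coverage))
  coverage |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(sum_K = sum(.data$K), sum_N = sum(.data$N),
              n_lines = dplyr::n_distinct(.data$line), .groups = "drop") |>
    mutate(defined = .data$sum_N > 0,
           P = if_else(.data$defined, .data$sum_K / .data$sum_N, NA_real_))
}

#' Binomial point probability of observed variant support
#'
#' The verification statistic: the binomial mass
#' `choose(N, K) * P^K * (1 - P)^(N - K)`, evaluated in log space so it is
#' stable for read depths up to 1e5. `upper_tail = TRUE` instead returns the
#' conventional upper-tail probability `P(X >= K)`; reports flag which mode
#' was used.
#'
#' @param K Supporting reads in the line (0 <= K <= N).
#' @param N Total quality reads at the position in the line.
#' @param P Per-read chance of calling the variant by noise.
#' @param upper_tail Return `P(X >= K)` instead of the point mass.
#' @return Numeric vector of probabilities.
#' @export
binomial_point_probability <- function(K, N, P, upper_tail = FALSE) {
  if (any(P < 0 | P > 1, na.rm = TRUE)) abort("P must lie in [0, 1]")
  if (any(K < 0 | K > N, na.rm = TRUE)) abort("K must lie in [0, N]")
  if (upper_tail) {
    return(stats::pbinom(K - 1, N, P, lower.tail = FALSE))
  }
  lp <- lchoose(N, K) +
    if_else(K == 0, 0, K * log(P)) +
    if_else(N - K == 0, 0, (N - K) * log1p(-P))
  ## log rules break at the P = 0 / P = 1 boundaries; handle exactly
  lp[P == 0 & K > 0] <- -Inf
  lp[P == 1 & K < N] <- -Inf
  lp[P == 0 & K == 0] <- 0
  lp[P == 1 & K == N] <- 0
  exp(lp)
}

#' Holm-Bonferroni step-down retention
#'
#' Sorts the probabilities ascending and rejects the null (shared noise) for
#' each of the first i with `p_(i) < alpha / (m - i + 1)`; the procedure
#' stops at the first failure. Ties keep their stable original order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param alpha Significance level.
#' @return Logical vector, `TRUE` where the null is rejected (variant
#'   retained), in the original order.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) return(logical(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("pvalues must be finite and in [0, 1]")
  }
  ord <- order(pvalues)
  sig_sorted <- pvalues[ord] < alpha / (m - seq_len(m) + 1)
  if (any(!sig_sorted)) {
    stop_at <- which(!sig_sorted)[1]
    sig_sorted[stop_at:m] <- FALSE
  }
  out <- logical(m)
  out[ord] <- sig_sorted
  out
}

#' Consensus filter: cross-line binomial verification
#'
#' Composes the full acceptance pipeline on hard-filter survivors: estimates
#' the per-position noise probability P across all sequenced lines, scores
#' every carrier call with the binomial point probability (or upper tail),
#' and applies the Holm-Bonferroni step-down experiment-wide. Calls whose
#' evidence is inconsistent with shared noise (significant) are retained.
#' Calls at positions with undefined P (no coverage anywhere) are moved to
#' a quarantine table, never silently dropped.
#'
#' @param calls Candidate calls (see [apply_hard_filters()]); if hard
#'   filters have not been applied yet (`pass` column absent) they are
#'   applied first.
#' @param coverage Per-line read support at candidate positions for all
#'   sequenced lines (`chrom, pos, alt, line, K, N`).
#' @param ancestor_calls Ancestral-control records, forwarded to the hard
#'   filters when those still need to run.
#' @param config A [filter_config()].
#' @param upper_tail Use the upper-tail probability instead of the point
#'   mass (flagged in the output).
#' @return Tibble of retained calls with `P, p_value, significant`
#'   appended; attributes `"quarantine"` (undefined-P calls) and
#'   `"p_mode"`.
#' @export
consensus_filter <- function(calls, coverage, ancestor_calls = NULL,
                             config = filter_config(), upper_tail = FALSE) {
  calls <- as_tibble(calls)
  if (!"pass" %in% names(calls)) {
    calls <- apply_hard_filters(calls, ancestor_calls, config)
  }
  surv <- calls |> filter(.data$pass)
  er <- cross_line_error_rate(coverage)
  keys <- intersect(c("chrom", "pos", "alt"), names(er))
  surv <- left_join(surv, er |> select(dplyr::all_of(keys), "P", "defined"),
                    by = keys)
  surv$defined <- surv$defined %in% TRUE
  quarantine <- surv |> filter(!.data$defined)
  surv <- surv |> filter(.data$defined)
  surv$p_value <- binomial_point_probability(surv$K, surv$N, surv$P,
                                             upper_tail = upper_tail)
  surv$significant <- holm_bonferroni(surv$p_value, alpha = config$alpha)
  out <- surv |> filter(.data$significant) |> select(-"defined")
  attr(out, "quarantine") <- quarantine |> select(-"defined")
  attr(out, "p_mode") <- if (upper_tail) "upper_tail" else "point_mass"
  out
}
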