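## Read-support simulation.
##
## Every candidate site (true-variant sites plus systematic noise sites)
## receives, in every line, a total read depth N ~ Poisson(depth) and a
## supporting-read count K ~ Binomial(N, 1 - e) for carriers or
## Binomial(N, e) otherwise. Noise sites emulate recurrent sequencing /
## alignment artifacts: the same spurious allele receives error-level
## support in every line and in the unmutated ancestral control, which is
## exactly the signature the cross-line binomial verification is built to
## remove. The ancestral control carries no support for true variants
## beyond this noise model.

#' Sequencing / calling model for the simulator
#'
#' @param mean_depth Mean quality read depth per line.
#' @param ancestor_depth Mean depth of the ancestral control.
#' @param error_rate Per-read probability `e` of mis-calling (0 <= e < 0.5).
#' @param caller_prob Per-caller detection probability for a true variant
#'   (of `n_callers` independent callers).
#' @param n_callers Number of variant callers emulated.
#' @param noise_caller_prob Per-caller probability of co-calling a noise
#'   site.
#' @param mq_mean,mq_sd RMS mapping-quality distribution at candidate
#'   sites.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(mean_depth = 30, ancestor_depth = 30,
                           error_rate = 0.01, caller_prob = 0.98,
                           n_callers = 3L, noise_caller_prob = 0.4,
                           mq_mean = 55, mq_sd = 3) {
  stopifnot(mean_depth >= 1, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, ancestor_depth = ancestor_depth,
                 error_rate = error_rate, caller_prob = caller_prob,
                 n_callers = n_callers, noise_caller_prob = noise_caller_prob,
                 mq_mean = mq_mean, mq_sd = mq_sd),
            class = "coverage_model")
}

random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Simulate per-line read evidence for an MA experiment
#'
#' @param truth Ground-truth mutations from [simulate_ma_lines()].
#' @param genome The `ma_genome` the truth was planted in.
#' @param experiment The [experiment_config()] (supplies lines and seed).
#' @param coverage A [coverage_model()].
#' @param n_noise_sites Number of systematic noise sites to scatter over
#'   callable positions.
#' @return List with `calls` (candidate records: every carrier call plus
#'   one record per line per noise site; columns `line, chrom, pos, ref,
#'   alt, variant_type, K, N, rms_mq, n_callers, truth_site`), `coverage`
#'   (K and N for every line at every candidate site, for the cross-line
#'   error rate) and `ancestor` (ancestral-control records).
#' @export
simulate_read_evidence <- function(truth, genome, experiment,
                                   coverage = coverage_model(),
                                   n_noise_sites = 0L) {
  stopifnot(inherits(coverage, "coverage_model"))
  lines <- experiment$lines
  e <- coverage$error_rate
  with_seed(derive_seed(experiment$seed, "reads"), {
    true_sites <- truth |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$variant_type) |>
      mutate(truth_site = TRUE)
    noise_sites <- tibble()
    if (n_noise_sites > 0L) {
      pools <- site_pools(genome)
      ns <- bind_rows(draw_pool_sites(pools$AT,
                                      round(n_noise_sites * pools$AT$total /
                                              (pools$AT$total + pools$GC$total))),
                      draw_pool_sites(pools$GC,
                                      n_noise_sites -
                                        round(n_noise_sites * pools$AT$total /
                                                (pools$AT$total + pools$GC$total)))) |>
        distinct(.data$chrom, .data$pos) |>
        anti_join(true_sites, by = c("chrom", "pos"))
      ref <- base_at(genome, ns$chrom, ns$pos)
      noise_sites <- ns |>
        mutate(ref = ref, alt = random_alt(ref), variant_type = "snp",
               truth_site = FALSE)
    }
    sites <- bind_rows(true_sites, noise_sites) |>
      mutate(site_id = row_number())
    carrier <- truth |>
      inner_join(sites |> select("chrom", "pos", "ref", "alt", "site_id"),
                 by = c("chrom", "pos", "ref", "alt")) |>
      select("line", "site_id") |>
      mutate(is_carrier = TRUE)

    grid <- tidyr::crossing(lines |> select("line"), sites) |>
      left_join(carrier, by = c("line", "site_id")) |>
      mutate(is_carrier = .data$is_carrier %in% TRUE)
    m <- nrow(grid)
    grid$N <- rpois(m, coverage$mean_depth)
    grid$K <- rbinom(m, grid$N, if_else(grid$is_carrier, 1 - e, e))
    grid$rms_mq <- pmax(0, rnorm(m, coverage$mq_mean, coverage$mq_sd))
    grid$n_callers <- rbinom(m, coverage$n_callers,
                             if_else(grid$is_carrier, coverage$caller_prob,
                                     coverage$noise_caller_prob))

    cov_tbl <- grid |>
      select("line", "chrom", "pos", "alt", "K", "N")
    calls <- grid |>
      filter(.data$is_carrier | !.data$truth_site) |>
      select("line", "chrom", "pos", "ref", "alt", "variant_type",
             "K", "N", "rms_mq", "n_callers", "truth_site")

    n_anc <- nrow(sites)
    anc_N <- rpois(n_anc, coverage$ancestor_depth)
    anc_K <- rbinom(n_anc, anc_N, if_else(sites$truth_site, 0, e))
    ancestor <- sites |>
      mutate(line = "ancestor", N = anc_N, K = anc_K) |>
      select("line", "chrom", "pos", "ref", "alt", "K", "N")
    list(calls = calls, coverage = cov_tbl, ancestor = ancestor)
  })
}
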