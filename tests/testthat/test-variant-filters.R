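mk_call <- function(..., line = "L01", chrom = "I", rms_mq = 50, n_callers = 3L) {
  tibble::tibble(line = line, chrom = chrom, rms_mq = rms_mq,
                 n_callers = n_callers, ...)
}

test_that("hard filters enforce every threshold with named rejection reasons", {
  calls <- dplyr::bind_rows(
    mk_call(pos = 10L, ref = "A", alt = "G", K = 3L, N = 3L, rms_mq = 35),   # boundary pass
    mk_call(pos = 20L, ref = "A", alt = "AT", K = 4L, N = 5L, rms_mq = 45),  # indel needs 5 reads
    mk_call(pos = 30L, ref = "C", alt = "T", K = 8L, N = 11L),               # 0.727 < 0.80
    mk_call(pos = 40L, ref = "G", alt = "T", K = 5L, N = 5L, n_callers = 1L),
    mk_call(pos = 50L, ref = "T", alt = "A", K = 0L, N = 0L),
    mk_call(pos = 60L, ref = "A", alt = "C", K = 10L, N = 10L),              # in ancestor
    mk_call(pos = 70L, ref = "A", alt = "AT", K = 6L, N = 7L, rms_mq = 39)   # indel MQ 40
  )
  anc <- tibble::tibble(chrom = "I", pos = 60L, alt = "C", K = 2L, N = 28L)
  out <- apply_hard_filters(calls, anc, filter_config())
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reject_reason,
               c(NA, "min_reads_indel", "support_fraction", "min_callers",
                 "no_coverage", "present_in_ancestor", "min_rms_mq_indel"))
  log <- hard_filter_log(out)
  expect_equal(sum(log$n_rejected), 6L)
})

test_that("ancestral records with zero supporting reads do not remove calls", {
  calls <- mk_call(pos = 10L, ref = "A", alt = "G", K = 25L, N = 26L)
  anc0 <- tibble::tibble(chrom = "I", pos = 10L, alt = "G", K = 0L, N = 30L)
  expect_true(apply_hard_filters(calls, anc0)$pass)
})

test_that("cross-line error rate sums reads over carriers and non-carriers", {
  cov <- tibble::tibble(chrom = "I", pos = 5L, alt = "T",
                        line = sprintf("L%02d", 1:20),
                        K = c(30L, rep(0L, 19)), N = rep(30L, 20))
  er <- cross_line_error_rate(cov)
  expect_equal(er$P, 30 / 600)
  expect_equal(cross_line_error_rate(dplyr::mutate(cov, K = 0L))$P, 0)
  one <- tibble::tibble(chrom = "I", pos = 5L, alt = "T", line = "L01",
                        K = 12L, N = 12L)
  expect_equal(cross_line_error_rate(one)$P, 1)
  und <- cross_line_error_rate(dplyr::mutate(cov, K = 0L, N = 0L))
  expect_false(und$defined)
  expect_true(is.na(und$P))
})

test_that("binomial point probability matches closed forms and stays exact in log space", {
  expect_equal(binomial_point_probability(1, 2, 0.5), 0.5)
  expect_equal(binomial_point_probability(0, 10, 0.1), 0.9^10)
  expect_equal(binomial_point_probability(5, 5, 0.01), 1e-10)
  # log-space route agrees with the direct product to 12 significant digits
  withr::with_seed(3, {
    for (i in 1:200) {
      N <- sample(1:30, 1); K <- sample(0:N, 1); P <- runif(1)
      direct <- choose(N, K) * P^K * (1 - P)^(N - K)
      expect_equal(binomial_point_probability(K, N, P), direct,
                   tolerance = 1e-12)
      expect_equal(binomial_point_probability(K, N, P), dbinom(K, N, P),
                   tolerance = 1e-12)
    }
  })
  # stable at depths far beyond double-precision factorials
  big <- binomial_point_probability(99000, 1e5, 0.99)
  expect_true(is.finite(big) && big > 0)
  # boundary probabilities
  expect_equal(binomial_point_probability(0, 10, 0), 1)
  expect_equal(binomial_point_probability(10, 10, 1), 1)
  expect_equal(binomial_point_probability(3, 10, 0), 0)
  expect_error(binomial_point_probability(1, 2, 1.5), "0, 1")
  # optional conventional upper tail
  expect_equal(binomial_point_probability(3, 10, 0.2, upper_tail = TRUE),
               pbinom(2, 10, 0.2, lower.tail = FALSE))
})

test_that("Holm-Bonferroni step-down follows the hand-worked examples", {
  expect_equal(holm_bonferroni(c(0.001, 0.02, 0.04), 0.05), c(TRUE, TRUE, TRUE))
  expect_equal(holm_bonferroni(0.5, 0.05), FALSE)
  expect_equal(holm_bonferroni(c(0.03, 0.03), 0.05), c(FALSE, FALSE))
  expect_equal(holm_bonferroni(numeric(0)), logical(0))
  # the step-down stops at the first failure even if later p would pass
  expect_equal(holm_bonferroni(c(0.04, 0.020, 0.001), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(holm_bonferroni(c(0.0001, 0.03, 0.04), 0.05),
               c(TRUE, FALSE, FALSE))
  # agrees with the standard adjusted-p implementation on generic values
  withr::with_seed(8, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))^2
      expect_equal(holm_bonferroni(p, 0.05), p.adjust(p, "holm") <= 0.05)
    }
  })
})

test_that("consensus filter keeps isolated true variants and drops shared artifacts", {
  lines <- sprintf("L%02d", 1:20)
  # one planted fixed variant in L01; all other lines clean
  cov_true <- tibble::tibble(chrom = "I", pos = 100L, alt = "T", line = lines,
                             K = c(30L, rep(0L, 19)), N = 30L)
  # systematic artifact: roughly half the reads in every line support it
  withr::with_seed(21, {
    cov_art <- tibble::tibble(chrom = "I", pos = 200L, alt = "G", line = lines,
                              K = rbinom(20, 30, 0.5), N = 30L)
  })
  calls <- dplyr::bind_rows(
    mk_call(pos = 100L, ref = "A", alt = "T", K = 30L, N = 30L),
    tibble::tibble(line = lines, chrom = "I", pos = 200L, ref = "A", alt = "G",
                   K = cov_art$K, N = 30L, rms_mq = 50, n_callers = 3L))
  out <- consensus_filter(calls, dplyr::bind_rows(cov_true, cov_art))
  expect_equal(nrow(dplyr::filter(out, pos == 100L)), 1L)
  expect_equal(nrow(dplyr::filter(out, pos == 200L)), 0L)

  # zero candidates in, zero out
  empty <- consensus_filter(calls[0, ], cov_true)
  expect_equal(nrow(empty), 0L)

  # undefined P goes to quarantine, never silently dropped
  qcalls <- mk_call(pos = 300L, ref = "A", alt = "C", K = 10L, N = 10L)
  qcov <- tibble::tibble(chrom = "I", pos = 300L, alt = "C", line = lines,
                         K = 0L, N = 0L)
  qcalls$K <- 10L; qcalls$N <- 10L
  qout <- consensus_filter(qcalls, qcov)
  expect_equal(nrow(qout), 0L)
  expect_equal(nrow(attr(qout, "quarantine")), 1L)
})

test_that("hard and consensus filters commute on the accepted set", {
  sim <- simulate_experiment(
    spec = genome_spec(chromosomes = tibble::tibble(name = "I", length = 5e4)),
    spectrum = spectrum_config(class_rates = rep(2e-6, 6),
                               ins_rate = 1e-6, del_rate = 2e-6),
    experiment = small_experiment(n_lines = 4L, seed = 31L),
    n_noise_sites = 500L)
  cfg <- filter_config()
  # route 1: hard filters explicitly, then consensus
  hard <- apply_hard_filters(sim$evidence$calls, sim$evidence$ancestor, cfg)
  a1 <- consensus_filter(hard, sim$evidence$coverage, config = cfg)
  # route 2: consensus runs the hard filters internally
  a2 <- consensus_filter(sim$evidence$calls, sim$evidence$coverage,
                         ancestor_calls = sim$evidence$ancestor, config = cfg)
  key <- function(x) dplyr::arrange(dplyr::select(x, line, chrom, pos, alt),
                                    line, chrom, pos)
  expect_equal(key(a1), key(a2))
  expect_gt(nrow(a1), 0)
})

test_that("filter calibration: high sensitivity, almost no retained noise", {
  sim <- simulate_experiment(
    spec = genome_spec(chromosomes = tibble::tibble(name = "I", length = 1e5)),
    spectrum = spectrum_config(class_rates = rep(2e-6, 6),
                               ins_rate = 1e-6, del_rate = 2e-6),
    experiment = small_experiment(n_lines = 6L, seed = 17L),
    coverage = coverage_model(mean_depth = 30, error_rate = 0.01),
    n_noise_sites = 3000L)
  out <- run_acceptance_pipeline(sim, coding = FALSE)
  truth_keys <- dplyr::distinct(sim$truth, line, chrom, pos)
  kept_true <- nrow(dplyr::semi_join(truth_keys,
                                     dplyr::filter(out$accepted, truth_site),
                                     by = c("line", "chrom", "pos")))
  expect_gte(kept_true / nrow(truth_keys), 0.99)
  n_noise_sites <- nrow(dplyr::distinct(
    dplyr::filter(sim$evidence$calls, !truth_site), chrom, pos))
  noise_kept <- nrow(dplyr::distinct(
    dplyr::filter(out$accepted, !truth_site), chrom, pos))
  expect_lte(noise_kept / n_noise_sites, 0.01)
})
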