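test_that("planted repeats are present verbatim and builds are seed-deterministic", {
  spec <- genome_spec(chromosomes = tibble::tibble(name = "I", length = 4e4))
  ref <- build_reference(spec, seed = 5)
  pr <- ref$planted_repeats
  expect_gt(nrow(pr), 0)
  for (i in seq_len(nrow(pr))) {
    got <- substr(ref$genome$seq[[pr$chrom[i]]], pr$start[i], pr$end[i])
    want <- substr(strrep(pr$motif[i], ceiling(pr$length_bp[i] / pr$unit_length[i])),
                   1, pr$length_bp[i])
    expect_equal(got, want)
  }
  # every planted run reappears in the detected catalog
  cat <- detect_repeats(ref$genome)
  hit <- dplyr::semi_join(pr, cat, by = c("chrom", "start"))
  expect_equal(nrow(hit), nrow(pr))
  # byte-identical FASTA under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- build_reference(spec, seed = 9, dir = d1)
  b2 <- build_reference(spec, seed = 9, dir = d2)
  expect_identical(readLines(b1$files$fasta), readLines(b2$files$fasta))
  b3 <- build_reference(spec, seed = 10)
  expect_false(identical(b1$genome$seq, b3$genome$seq))
})

test_that("background G+C content concentrates around the target", {
  spec <- genome_spec(chromosomes = tibble::tibble(name = "I", length = 3e5),
                      gc = 0.36)
  ref <- build_reference(spec, seed = 12)
  gc <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(ref$genome$seq), letters = c("G", "C")))
  expect_lt(abs(gc / sum(ref$genome$chrom_lengths) - 0.36), 0.02)
})

test_that("planted mutation counts follow the Poisson expectation", {
  spec <- genome_spec(chromosomes = tibble::tibble(name = "I", length = 1e5),
                      hp_per_length_at = 2L, hp_per_length_gc = 1L,
                      dinuc_per_cell = 1L)
  ref <- build_reference(spec, seed = 2)
  # substitution rate 1e-5/site/gen in total, G = 10, 20 lines
  spect <- spectrum_config(class_rates = rep(1e-5 / 6, 6),
                           ins_rate = 0, del_rate = 0,
                           hp_rate_at = 0, hp_rate_gc = 0,
                           dinuc_rates = tibble::tibble(
                             family = c("AT/TA", "AC/GT", "AG/CT", "CG/GC"),
                             ins_rate = 0, del_rate = 0))
  exper <- experiment_config(n_lines = 20L, generations = 10L, seed = 4L)
  truth <- simulate_ma_lines(ref$genome, spect, exper)
  counts <- dplyr::count(truth, line)
  expected <- 1e-5 * callable_bases(ref$genome) * 10
  se <- sqrt(expected / 20)
  expect_lt(abs(mean(counts$n) - expected), 3 * se)
  # same seed reproduces the identical truth set
  truth2 <- simulate_ma_lines(ref$genome, spect, exper)
  expect_identical(truth, truth2)
})

test_that("all-zero rates produce an empty truth set", {
  ref <- build_reference(
    genome_spec(chromosomes = tibble::tibble(name = "I", length = 2e4)), seed = 2)
  spect <- spectrum_config(class_rates = rep(0, 6), ins_rate = 0, del_rate = 0,
                           hp_rate_at = 0, hp_rate_gc = 0,
                           dinuc_rates = tibble::tibble(
                             family = c("AT/TA", "AC/GT", "AG/CT", "CG/GC"),
                             ins_rate = 0, del_rate = 0))
  truth <- simulate_ma_lines(ref$genome, spect, small_experiment())
  expect_equal(nrow(truth), 0L)
})

test_that("the configured deletion bias is realised in the planted indels", {
  ref <- build_reference(
    genome_spec(chromosomes = tibble::tibble(name = "I", length = 1e5)), seed = 6)
  spect <- spectrum_config(class_rates = rep(0, 6),
                           ins_rate = 1e-5, del_rate = 2e-5,
                           deletion_fraction = 2 / 3,
                           hp_rate_at = 0, hp_rate_gc = 0,
                           dinuc_rates = tibble::tibble(
                             family = c("AT/TA", "AC/GT", "AG/CT", "CG/GC"),
                             ins_rate = 0, del_rate = 0))
  exper <- experiment_config(n_lines = 20L, generations = 40L, seed = 8L)
  truth <- simulate_ma_lines(ref$genome, spect, exper)
  expect_gt(nrow(truth), 1500)
  frac_del <- mean(truth$indel_size < 0)
  expect_lt(abs(frac_del - 2 / 3), 0.03)
})

test_that("context multipliers enrich substitutions at the keyed triplet", {
  ref <- build_reference(
    genome_spec(chromosomes = tibble::tibble(name = "I", length = 1e5)), seed = 13)
  base <- spectrum_config(class_rates = c(0, 2e-5, 0, 0, 0, 0),
                          ins_rate = 0, del_rate = 0,
                          hp_rate_at = 0, hp_rate_gc = 0)
  boosted <- base
  boosted$context_multipliers <- c("AAT/ATT" = 25)
  exper <- experiment_config(n_lines = 6L, generations = 10L, seed = 14L)
  share_aat <- function(sp) {
    truth <- simulate_ma_lines(ref$genome, sp, exper)
    ctx <- collapse_context(ref$genome, truth[, c("chrom", "pos")])
    mean(ctx == "AAT/ATT", na.rm = TRUE)
  }
  expect_gt(share_aat(boosted), 3 * share_aat(base))
})

test_that("read evidence follows the coverage and error model", {
  ref <- build_reference(
    genome_spec(chromosomes = tibble::tibble(name = "I", length = 5e4)), seed = 3)
  exper <- small_experiment(n_lines = 2L, seed = 23L)
  spect <- spectrum_config(class_rates = rep(2e-6, 6), ins_rate = 0, del_rate = 0,
                           hp_rate_at = 0, hp_rate_gc = 0)
  truth <- simulate_ma_lines(ref$genome, spect, exper)
  # no-error limit: every carrier call has K = N
  ev0 <- simulate_read_evidence(truth, ref$genome, exper,
                                coverage = coverage_model(error_rate = 0))
  carriers <- dplyr::filter(ev0$calls, truth_site)
  expect_true(all(carriers$K == carriers$N))
  # with e = 0.01 the mean noise support fraction is e
  ev <- simulate_read_evidence(truth, ref$genome, exper,
                               coverage = coverage_model(error_rate = 0.01),
                               n_noise_sites = 5000L)
  noise <- dplyr::filter(ev$calls, !truth_site, N > 0)
  expect_gt(nrow(noise), 9000)
  expect_lt(abs(mean(noise$K / noise$N) - 0.01), 0.002)
  # ancestral control has no true-variant support beyond noise
  anc_true <- dplyr::semi_join(ev$ancestor, truth, by = c("chrom", "pos"))
  expect_true(all(anc_true$K == 0))
  # identical call table under the same seed
  ev2 <- simulate_read_evidence(truth, ref$genome, exper,
                                coverage = coverage_model(error_rate = 0.01),
                                n_noise_sites = 5000L)
  expect_identical(ev$calls, ev2$calls)
})
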