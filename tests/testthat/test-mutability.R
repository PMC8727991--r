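# Shared small genome for the feature / training-set tests
mut_ref <- build_reference(
  genome_spec(chromosomes = tibble::tibble(name = c("I", "X"),
                                           length = c(8e4, 4e4))),
  seed = 51)
mut_catalog <- detect_repeats(mut_ref$genome)

test_that("training-set assembly keeps the bookkeeping and is deterministic", {
  muts <- tibble::tibble(chrom = rep("I", 50), pos = seq(1000L, 50000L, by = 1000L))
  tr <- build_training_set(mut_ref$genome, muts, n_random = 1000L, seed = 3L,
                           catalog = mut_catalog)
  expect_equal(nrow(tr), 1050L)
  expect_equal(sum(tr$response), 50L)
  tr2 <- build_training_set(mut_ref$genome, muts, n_random = 1000L, seed = 3L,
                            catalog = mut_catalog)
  expect_identical(tr, tr2)
  # random sites never collide with mutation sites
  expect_equal(nrow(dplyr::inner_join(dplyr::filter(tr, response == 0),
                                      muts, by = c("chrom", "pos"))), 0L)
  # mean GC over random sites tracks the genomic GC
  gc_genome <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(mut_ref$genome$seq), letters = c("G", "C"))) /
    sum(mut_ref$genome$chrom_lengths)
  expect_lt(abs(mean(tr$gc[tr$response == 0], na.rm = TRUE) - gc_genome), 0.01)
})

test_that("an overwhelming penalty drives every odds ratio to 1", {
  withr::with_seed(5, {
    x <- cbind(a = rnorm(500), b = rnorm(500), c = as.numeric(runif(500) < 0.3))
    y <- rbinom(500, 1, plogis(-1 + x[, "a"]))
  })
  m <- fit_penalized_logistic(x, y = y, lambda = 1e6)
  expect_true(all(abs(m$coefficients) < 1e-6))
  ors <- odds_ratios(m)
  expect_true(all(abs(ors$odds_ratio - 1) < 1e-5))
})

test_that("odds ratios are e^c and tidy/glance expose the fit", {
  m <- structure(list(coefficients = c(zero = 0, two = log(2)),
                      intercept = -3, lambda = 1e-4, alpha = 0.01,
                      n_mutated = 10, n_random = 100, dev_ratio = 0.5,
                      null_deviance = 100, schema = c("zero", "two")),
                 class = "mutability_model")
  ors <- odds_ratios(m)
  expect_equal(ors$odds_ratio[ors$predictor == "zero"], 1.0)
  expect_equal(ors$odds_ratio[ors$predictor == "two"], 2.0)
  expect_identical(tidy(m), ors)
  expect_equal(glance(m)$lambda, 1e-4)
})

test_that("planted coefficients are recovered and predictions are calibrated and monotone", {
  withr::with_seed(77, {
    n <- 30000L
    x <- cbind(repeat_seq = as.numeric(runif(n) < 0.08),
               gc = pmin(pmax(rnorm(n, 0.36, 0.08), 0), 1),
               complexity = rexp(n, 2))
    eta <- -3.4 + 1.5 * x[, "repeat_seq"] - 1.0 * x[, "gc"] +
      0.3 * x[, "complexity"]
    y <- rbinom(n, 1, plogis(eta))
  })
  m <- fit_penalized_logistic(x, y = y, lambda = 6.83e-5)
  expect_gt(m$coefficients[["repeat_seq"]], 1.0)
  expect_lt(m$coefficients[["repeat_seq"]], 2.0)
  # calibration: mean prediction equals class prevalence
  p <- predict_mutability(m, x)
  expect_equal(mean(p), mean(y), tolerance = 0.02)
  # monotone in a positive-coefficient predictor, other features fixed
  x0 <- cbind(repeat_seq = c(0, 1), gc = 0.36, complexity = 0.5)
  p01 <- predict_mutability(m, x0)
  expect_gt(p01[2], p01[1])
  # all-zero features give the intercept through the logistic link
  pz <- predict_mutability(m, cbind(repeat_seq = 0, gc = 0, complexity = 0))
  expect_equal(pz, plogis(m$intercept), tolerance = 1e-8)
})

test_that("a permuted response is shrunk to the null by cross-validated lambda", {
  withr::with_seed(78, {
    n <- 20000L
    x <- cbind(repeat_seq = as.numeric(runif(n) < 0.08),
               gc = rnorm(n, 0.36, 0.08), complexity = rexp(n, 2))
    y <- rbinom(n, 1, plogis(-3.4 + 1.5 * x[, "repeat_seq"]))
    yperm <- sample(y)
  })
  m0 <- fit_penalized_logistic(x, y = yperm, nfolds = 5L, seed = 9L)
  expect_true(all(abs(m0$coefficients) < 0.1))
  expect_lt(m0$dev_ratio, 0.005)
})

test_that("dropping the penalty reproduces unpenalized logistic estimates", {
  withr::with_seed(80, {
    n <- 20000L
    x <- cbind(a = rnorm(n), b = as.numeric(runif(n) < 0.3))
    y <- rbinom(n, 1, plogis(-2 + 0.8 * x[, "a"] - 0.5 * x[, "b"]))
  })
  m <- fit_penalized_logistic(x, y = y, lambda = 0)
  g <- glm(y ~ x, family = binomial())
  expect_equal(unname(m$coefficients),
               unname(coef(g)[-1]), tolerance = 0.01)
})

test_that("a three-predictor refit explains nearly as much as the full feature set", {
  # mutations planted from {repeat, gc, complexity} only: extra predictors
  # cannot add real signal, so deviance ratios should sit within 5 points
  withr::with_seed(81, {
    sites <- dplyr::bind_rows(lapply(names(mut_ref$genome$seq), function(nm) {
      tibble::tibble(chrom = nm,
                     pos = sort(sample(21:(mut_ref$genome$chrom_lengths[[nm]] - 21L),
                                       15000L)))
    }))
  })
  f <- site_features(mut_ref$genome, sites, catalog = mut_catalog)
  ok <- stats::complete.cases(f[, c("gc", "complexity")])
  f <- f[ok, ]
  withr::with_seed(82, {
    eta <- -3.3 + 1.5 * f$repeat_seq - 1.2 * f$gc + 0.4 * f$complexity
    y <- rbinom(nrow(f), 1, plogis(eta))
  })
  small <- fit_penalized_logistic(
    cbind(repeat_seq = as.numeric(f$repeat_seq), gc = f$gc,
          complexity = f$complexity), y = y, lambda = 6.83e-5)
  full <- fit_penalized_logistic(dplyr::bind_cols(
    f |> dplyr::select(-chrom, -pos), tibble::tibble(response = y)),
    lambda = 6.83e-5)
  expect_lt(abs(full$dev_ratio - small$dev_ratio), 0.05)
  expect_gt(small$dev_ratio, 0)
})

test_that("bin calibration yields the default 8 bins and sane regressions", {
  withr::with_seed(90, {
    p <- runif(20000, 0, 0.12)
    # perfectly calibrated predictions: bin rate tracks the midpoint
    m <- runif(20000) < p
    bins <- bin_rates(p, m, G = 1)
    # degenerate case: every mutation in the top bin, none elsewhere
    topm <- p > 0.105
    top <- bin_rates(p, topm, G = 1)
  })
  expect_equal(nrow(bins$bins), 8L)
  expect_equal(sum(bins$bins$SNP_b), sum(m))
  expect_gt(bins$regression$r, 0.95)
  expect_equal(bins$regression$slope, 1, tolerance = 0.1)
  expect_true(all(diff(top$bins$rate) >= 0))
  expect_gt(top$regression$slope, 0)
  # null: mutations independent of prediction give a flat profile
  withr::with_seed(91, {
    m0 <- runif(20000) < 0.02
    b0 <- bin_rates(p, m0, G = 1)
  })
  expect_lt(abs(b0$regression$slope), 0.05)
  expect_identical(tidy(b0), b0$bins)
  expect_s3_class(autoplot(b0), "ggplot")
})
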