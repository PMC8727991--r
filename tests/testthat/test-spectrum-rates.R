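tbls <- ma_reference_tables()

test_that("substitution classes collapse over strand with correct transitions", {
  expect_equal(classify_substitution("A", "G")$substitution_class, "A/T->G/C")
  expect_true(classify_substitution("A", "G")$is_transition)
  expect_equal(classify_substitution("C", "A")$substitution_class, "G/C->T/A")
  expect_false(classify_substitution("C", "A")$is_transition)
  expect_equal(classify_substitution(c("T", "A"), c("A", "T"))$substitution_class,
               rep("A/T->T/A", 2))
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"))
  # exhaustive: every (ref, alt) pair and its reverse complement share a class
  for (r in c("A", "C", "G", "T")) {
    for (a in setdiff(c("A", "C", "G", "T"), r)) {
      fwd <- classify_substitution(r, a)
      rc <- classify_substitution(revcomp(r), revcomp(a))
      expect_identical(fwd, rc)
    }
  }
})

test_that("triplet context collapse is a 32-key bijection with reverse complement", {
  all_tri <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                               c("A","C","G","T")), 1, paste, collapse = "")
  keys <- collapse_triplet(all_tri)
  expect_equal(length(unique(keys)), 32L)
  expect_identical(collapse_triplet(all_tri), collapse_triplet(revcomp(all_tri)))
  # brute-force pairing oracle: each key covers exactly its triplet and rc
  for (k in unique(keys)) {
    members <- all_tri[keys == k]
    expect_setequal(members, unique(c(members, revcomp(members))))
    expect_equal(length(members), 2L)
  }
  expect_equal(collapse_triplet("AAT"), "AAT/ATT")
  # focal A in 5'-AAT-3' mutating A->T matches focal T in 5'-ATT-3' T->A
  g <- mamutspec:::new_ma_genome(c(I = "GGAATGG", II = "GGATTGG"),
                                 mito_name = NULL, x_names = character())
  expect_equal(collapse_context(g, tibble::tibble(chrom = c("I", "II"),
                                                  pos = c(4L, 4L))),
               rep("AAT/ATT", 2))
  # flank off the contig end yields NA
  expect_true(is.na(collapse_context(g, tibble::tibble(chrom = "I", pos = 1L))))
})

test_that("coding effects follow codon translation and frame arithmetic", {
  g <- make_codon_genome()   # 10 GGA (Gly) codons at 11..40
  v <- tibble::tibble(chrom = "I",
                      pos = c(13L, 12L, 20L, 20L, 5L),
                      ref = c("A", "G", "G", "GACG", "A"),
                      alt = c("G", "T", "GT", "G", "T"))
  eff <- classify_coding_effect(v, g)
  # GGA -> GGG stays glycine; GTA is valine; +1 bp shifts frame; -3 in frame
  expect_equal(eff, c("synonymous", "nonsynonymous", "frameshift",
                      "in-frame-indel", "noncoding"))
})

test_that("synonymous site counting matches code-table enumeration", {
  g <- make_codon_genome()
  s <- synonymous_site_counts(g)
  # GGN is fully synonymous at position 3: each GGA codon has 1 syn site
  expect_equal(s$syn_sites, 10)
  expect_equal(s$syn_sites + s$nonsyn_sites, 3 * s$n_codons)
  # ATG (Met) has no synonymous sites; enumerate directly from the code table
  syn_tab <- mamutspec:::codon_syn_fraction_table()
  expect_equal(unname(syn_tab[["ATG"]]), 0)
  expect_equal(unname(syn_tab[["GGG"]]), 1)
})

test_that("rate arithmetic, averaging and confidence intervals are exact", {
  expect_equal(mutation_rate(2, 40, 1e6), 5e-8)
  lines <- tibble::tibble(line = c("a", "b", "c"), generations = c(10, 20, 40))
  recs <- tibble::tibble(line = c("a", "a", "b"))
  lr <- line_rates(recs, lines, B = 1e5)
  expect_equal(lr$n, c(2L, 1L, 0L))
  expect_equal(lr$rate, c(2 / (10 * 1e5), 1 / (20 * 1e5), 0))
  # identical per-line counts and generations give a zero CI half-width
  same <- line_rates(tibble::tibble(line = rep(c("a", "b"), each = 3)),
                     tibble::tibble(line = c("a", "b"), generations = c(10, 10)),
                     B = 1e4)
  expect_equal(rate_summary(same)$ci_half, 0)
})

test_that("fold changes reproduce the published table arithmetic", {
  expect_equal(2.23e-7 / 6.8e-10, 327.94, tolerance = 1e-4)
  r <- tibble::tibble(line = c("a", "b"), generations = c(1, 1),
                      rate = c(2.2e-7, 2.26e-7))
  fc <- fold_change(r, tibble::tibble(ref_rate = 6.8e-10))
  expect_equal(fc$fold, 2.23e-7 / 6.8e-10, tolerance = 1e-12)
  fc2 <- fold_change(r, tibble::tibble(ref_rate = mean(r$rate)))
  expect_equal(fc2$fold, 1.0)
  fc0 <- fold_change(r, tibble::tibble(ref_rate = 0))
  expect_true(is.na(fc0$fold) && !fc0$fold_defined)
  # per-line reference triggers a Welch t-test
  ref <- tibble::tibble(line = c("x", "y", "z"), generations = 1,
                        rate = c(1e-9, 2e-9, 1.5e-9))
  fct <- fold_change(r, ref)
  expect_true(is.finite(fct$t) && fct$p_value < 0.05)
})

test_that("Ts/Tv handles pooled counts, per-line means and degenerate input", {
  counts <- dplyr::select(tbls$table2, substitution_class, n = total)
  expect_equal(tstv_ratio(counts), (886 + 768) / (545 + 403 + 494 + 29))
  expect_equal(round(tstv_ratio(counts), 2), 1.12)
  eq <- tibble::tibble(substitution_class = c("A/T->G/C", "A/T->T/A"), n = c(7, 7))
  expect_equal(tstv_ratio(eq), 1.0)
  # per-line and pooled differ when line sizes are unequal
  recs <- tibble::tibble(
    line = c(rep("a", 4), rep("b", 30)),
    substitution_class = c(rep("A/T->G/C", 3), "A/T->T/A",
                           rep("A/T->G/C", 10), rep("G/C->T/A", 20)))
  pooled <- tstv_ratio(recs)
  per_line <- tstv_ratio(recs, per_line = TRUE)
  expect_equal(pooled, 13 / 21)
  expect_equal(per_line, mean(c(3 / 1, 10 / 20)))
  expect_warning(out <- tstv_ratio(tibble::tibble(
    substitution_class = "A/T->G/C", n = 3)), "undefined")
  expect_true(is.na(out))
})

test_that("AT bias normalisation reproduces the published fraction", {
  counts <- dplyr::select(tbls$table2, substitution_class, n = total)
  b <- at_bias(counts, gc_fraction = 0.36)
  expect_equal(round(b$normalized, 2), 0.64)
  # uniform composition reduces exactly to the raw count fraction
  b50 <- at_bias(counts, gc_fraction = 0.5)
  expect_equal(b50$normalized, b50$raw)
  sym <- tibble::tibble(substitution_class = c("G/C->A/T", "A/T->G/C"), n = c(5, 5))
  expect_equal(at_bias(sym, gc_fraction = 0.5)$normalized, 0.5)
  only <- tibble::tibble(substitution_class = "G/C->A/T", n = 9)
  expect_equal(at_bias(only, gc_fraction = 0.36)$normalized, 1.0)
  expect_error(at_bias(counts, gc_fraction = 1), "inside")
})

test_that("indel accounting reproduces the published net-loss numbers", {
  recs <- tibble::tibble(indel_size = c(rep(-1L, 6960), rep(1L, 3513)))
  tot <- indel_summary(recs)$totals
  expect_equal(tot$net_bp, -3447)
  expect_equal(tot$n_del, 6960)
  empty <- indel_summary(tibble::tibble(indel_size = integer()))$totals
  expect_equal(empty$net_bp, 0)
  expect_equal(empty$n_indels, 0)
})

test_that("mitochondrial rates are heteroplasmy-weighted, averaged over all lines", {
  # single line, one fixed variant
  one <- mito_rate(tibble::tibble(line = "a", frequency = 1),
                   tibble::tibble(line = "a", generations = 10), L_mt = 1e4)
  expect_equal(one$summary$mean_rate, 1e-5)
  # no variants at all
  zero <- mito_rate(tibble::tibble(line = character(), frequency = numeric()),
                    tibble::tibble(line = c("a", "b"), generations = c(10, 20)),
                    L_mt = 1e4)
  expect_equal(zero$summary$mean_rate, 0)
  # linearity in the heteroplasmy frequencies
  vars <- tibble::tibble(line = c("a", "a", "b"), frequency = c(0.4, 0.2, 0.1))
  lines <- tibble::tibble(line = c("a", "b", "c"), generations = c(10, 20, 30))
  full <- mito_rate(vars, lines, L_mt = 1e4)$summary$mean_rate
  half <- mito_rate(dplyr::mutate(vars, frequency = frequency / 2),
                    lines, L_mt = 1e4)$summary$mean_rate
  expect_equal(full, 2 * half)
  expect_error(mito_rate(tibble::tibble(line = "a", frequency = 1.2),
                         lines, L_mt = 1e4), "frequencies")
})

test_that("partition comparison runs ANOVA and paired t-tests on per-line rates", {
  withr::with_seed(31, {
    lines <- sprintf("L%02d", 1:20)
    rates <- dplyr::bind_rows(
      tibble::tibble(line = lines, part = "autosome",
                     rate = rnorm(20, 4.3e-8, 3e-9)),
      tibble::tibble(line = lines, part = "X",
                     rate = rnorm(20, 3.7e-8, 3e-9)))
  })
  cmp <- partition_compare(rates, "part", paired = TRUE)
  expect_equal(nrow(cmp$summary), 2L)
  expect_true(cmp$t_test$paired)
  expect_lt(cmp$t_test$p_value, 0.01)
  expect_gt(cmp$t_test$mean_difference, 0)
  expect_lt(cmp$anova$p_value, 0.05)
  # single line: descriptive output only
  single <- partition_compare(dplyr::filter(rates, line == "L01"), "part")
  expect_equal(nrow(single$anova), 0L)
  expect_equal(nrow(single$t_test), 0L)
})

test_that("paired X-vs-autosome comparison has near-nominal type-I error and detects real deficits", {
  # planted 15% lower X rate: the paired test should find the direction
  detect <- 0L
  null_hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    withr::with_seed(1000 + r, {
      lines <- sprintf("L%02d", 1:20)
      base <- rnorm(20, 4.3e-8, 4e-9)
      eff <- tibble::tibble(line = rep(lines, 2),
                            part = rep(c("autosome", "X"), each = 20),
                            rate = c(base + rnorm(20, 0, 2e-9),
                                     0.85 * base + rnorm(20, 0, 2e-9)))
      nul <- tibble::tibble(line = rep(lines, 2),
                            part = rep(c("autosome", "X"), each = 20),
                            rate = c(base + rnorm(20, 0, 2e-9),
                                     base * 1.0 + rnorm(20, 0, 2e-9) -
                                       base + rnorm(20, 4.3e-8, 4e-9)))
    })
    te <- partition_compare(eff, "part", paired = TRUE)$t_test
    if (te$mean_difference > 0 && te$p_value < 0.05) detect <- detect + 1L
    tn <- partition_compare(nul, "part", paired = TRUE)$t_test
    if (tn$p_value < 0.05) null_hits <- null_hits + 1L
  }
  expect_gte(detect / n_rep, 0.95)
  expect_lte(null_hits / n_rep, 0.15)
})
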