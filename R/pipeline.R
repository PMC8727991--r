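## End-to-end convenience wrappers tying the stages together: simulate an
## experiment with known truth, push candidate calls through the full
## acceptance pipeline, and classify what survives.

#' Simulate a complete MA experiment
#'
#' Builds the reference (unless supplied), plants mutations, and draws
#' read evidence, returning every intermediate object plus the repeat
#' catalog actually used.
#'
#' @param spec A [genome_spec()] (ignored when `reference` is given).
#' @param spectrum A [spectrum_config()].
#' @param experiment An [experiment_config()].
#' @param coverage A [coverage_model()].
#' @param n_noise_sites Systematic noise sites for the read simulation.
#' @param reference Optional pre-built output of [build_reference()].
#' @return List `genome, catalog, truth, evidence, experiment`.
#' @export
simulate_experiment <- function(spec = genome_spec(),
                                spectrum = spectrum_config(),
                                experiment = experiment_config(),
                                coverage = coverage_model(),
                                n_noise_sites = 10000L,
                                reference = NULL) {
  reference <- reference %||% build_reference(spec, seed = experiment$seed)
  genome <- reference$genome
  catalog <- detect_repeats(genome)
  truth <- simulate_ma_lines(genome, spectrum, experiment, catalog = catalog)
  evidence <- simulate_read_evidence(truth, genome, experiment,
                                     coverage = coverage,
                                     n_noise_sites = n_noise_sites)
  list(genome = genome, catalog = catalog, truth = truth,
       evidence = evidence, experiment = experiment)
}

#' Run the full acceptance pipeline on simulated (or imported) evidence
#'
#' Hard filters, cross-line error rates, binomial verification and
#' Holm-Bonferroni retention, followed by mutation classification against
#' the genome and repeat catalog.
#'
#' @param sim Output of [simulate_experiment()], or a list with `calls`,
#'   `coverage`, `ancestor` plus `genome` and `catalog`.
#' @param config A [filter_config()].
#' @param flank Repeat adjacency window for classification.
#' @param coding Classify coding effects.
#' @return List `accepted` (retained calls), `records` (classified
#'   mutation records), `filtered` (hard-filter output with reasons).
#' @export
run_acceptance_pipeline <- function(sim, config = filter_config(),
                                    flank = 1L, coding = TRUE) {
  ev <- sim$evidence %||% sim
  filtered <- apply_hard_filters(ev$calls, ev$ancestor, config)
  accepted <- consensus_filter(filtered, ev$coverage, config = config)
  records <- classify_mutations(accepted, sim$genome, catalog = sim$catalog,
                                flank = flank, coding = coding)
  list(accepted = accepted, records = records, filtered = filtered)
}
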