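# A tiny hand-specified genome used by the annotation and classification
# tests: one 1 kb autosome plus a short X, with one gene each and
# hand-placed domains, so expected labels can be derived by interval
# arithmetic by hand.
make_toy_genome <- function(seed = 42) {
  withr::with_seed(seed, {
    seqs <- c(I = random_dna(1000, gc = 0.4), X = random_dna(400, gc = 0.4))
    g <- mamutspec:::new_ma_genome(seqs, mito_name = "MtDNA", x_names = "X")
    genes <- tibble::tibble(
      gene_id = c("gA", "gB"),
      chrom = c("I", "X"),
      start = c(101L, 51L), end = c(400L, 230L),
      strand = c("+", "+"),
      germline_expressed = c(TRUE, FALSE))
    exons <- tibble::tibble(
      gene_id = c("gA", "gA", "gB"),
      chrom = c("I", "I", "X"),
      start = c(101L, 301L, 51L), end = c(190L, 400L, 230L))
    domains <- tibble::tibble(
      chrom = c("I", "I", "I", "X"),
      start = c(1L, 201L, 801L, 1L),
      end = c(200L, 800L, 1000L, 400L),
      domain = c("tip", "core", "arm", "core"))
    set_annotations(g, genes = genes, exons = exons, domains = domains)
  })
}

# A genome with a single gene whose CDS is fully controlled, for codon
# tests: gene on "I" at 11..40 (one exon, 10 codons of GGA), flanked by
# fixed intergenic sequence.
make_codon_genome <- function() {
  cds <- strrep("GGA", 10)
  seqs <- c(I = paste0("ACGTACGTAC", cds, "ACGTACGTAC"))
  g <- mamutspec:::new_ma_genome(seqs, mito_name = NULL, x_names = character())
  genes <- tibble::tibble(gene_id = "g1", chrom = "I", start = 11L, end = 40L,
                          strand = "+", germline_expressed = TRUE)
  exons <- tibble::tibble(gene_id = "g1", chrom = "I", start = 11L, end = 40L)
  domains <- tibble::tibble(chrom = "I", start = 1L, end = 50L, domain = "core")
  set_annotations(g, genes = genes, exons = exons, domains = domains)
}

small_experiment <- function(n_lines = 5L, generations = 40L, seed = 11L) {
  experiment_config(n_lines = n_lines, generations = generations, seed = seed)
}
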