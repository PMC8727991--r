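## Synthetic reference genomes with known ground truth.
##
## The generator emulates the structure the downstream analysis cares
## about: several chromosomes (autosomes, an X, optionally a small
## mitochondrial chromosome), tip/arm/core recombination domains, gene
## models with exons and introns, germline-expression flags, chromatin
## blocks, A/T-cluster intervals, and a planted catalog of homopolymers and
## dinucleotide microsatellites embedded in random background sequence of
## configurable G+C content.

#' Specification of a synthetic genome
#'
#' @param chromosomes Tibble `name, length` (bp). Names matching `x_names`
#'   are X-linked; append a mitochondrial chromosome with `mito_length`.
#' @param gc Background G+C fraction.
#' @param mito_length Length of an optional mitochondrial chromosome
#'   (0 = none).
#' @param hp_lengths,hp_per_length_at,hp_per_length_gc Homopolymer catalog:
#'   planted run lengths and how many A/T (and G/C) runs of each length to
#'   plant per genome.
#' @param dinuc_copies,dinuc_per_cell Dinucleotide microsatellites: copy
#'   numbers planted for each of the four motif families, and runs per
#'   (family, copy-number) cell.
#' @param genes_per_mb,exons_per_gene,exon_length,intron_length Gene-model
#'   layout; exon lengths keep each CDS a multiple of 3.
#' @param germline_fraction Fraction of genes flagged germline-expressed.
#' @param domain_props Ordered tip/arm/core/arm/tip proportions per
#'   chromosome (must sum to 1).
#' @param chromatin_states,chromatin_block Chromatin-state tokens assigned
#'   in blocks of this many bp.
#' @param at_cluster_density Expected A/T-cluster intervals per kb.
#' @param x_names,mito_name Chromosome-name conventions.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chromosomes = tibble(name = c("I", "II", "III", "X"),
                                             length = c(3e5, 3e5, 2e5, 2e5)),
                        gc = 0.36, mito_length = 0L,
                        hp_lengths = 6:15,
                        hp_per_length_at = 40L, hp_per_length_gc = 15L,
                        dinuc_copies = 4:8, dinuc_per_cell = 4L,
                        genes_per_mb = 120, exons_per_gene = 4L,
                        exon_length = 150L, intron_length = 300L,
                        germline_fraction = 0.5,
                        domain_props = c(tip = 0.05, arm = 0.15, core = 0.60,
                                         arm = 0.15, tip = 0.05),
                        chromatin_states = c("active", "regulated", "border",
                                             "heterochromatin", "low"),
                        chromatin_block = 10000L,
                        at_cluster_density = 0.02,
                        x_names = "X", mito_name = "MtDNA") {
  stopifnot(nrow(chromosomes) >= 1, all(chromosomes$length > 0),
            gc > 0, gc < 1, abs(sum(domain_props) - 1) < 1e-8,
            (exons_per_gene * exon_length) %% 3L == 0L)
  structure(as.list(environment()), class = "genome_spec")
}

sample_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## regular gene grid leaving inter-gene space for repeats
layout_genes <- function(chrom, len, spec, offset_id) {
  gene_span <- spec$exons_per_gene * spec$exon_length +
    (spec$exons_per_gene - 1L) * spec$intron_length
  n_genes <- max(0L, floor(len / 1e6 * spec$genes_per_mb))
  if (n_genes == 0L || gene_span + 200L > len) {
    return(list(genes = tibble(), exons = tibble()))
  }
  pitch <- len %/% n_genes
  n_genes <- min(n_genes, (len - 100L) %/% max(pitch, gene_span + 200L))
  starts <- 100L + (seq_len(n_genes) - 1L) * pitch
  starts <- starts[starts + gene_span - 1L <= len - 100L]
  ids <- sprintf("gene%05d", offset_id + seq_along(starts))
  genes <- tibble(gene_id = ids, chrom = chrom, start = starts,
                  end = starts + gene_span - 1L,
                  strand = sample(c("+", "-"), length(starts), replace = TRUE))
  exons <- purrr::map_dfr(seq_along(starts), function(i) {
    es <- starts[i] + (seq_len(spec$exons_per_gene) - 1L) *
      (spec$exon_length + spec$intron_length)
    tibble(gene_id = ids[i], chrom = chrom, start = es,
           end = es + spec$exon_length - 1L)
  })
  list(genes = genes, exons = exons)
}

## a letter differing from every base in `exclude`, so planted runs stay
## maximal (no same-period extension, including phase-shifted dinucleotide
## extension through the guard)
guard_base <- function(exclude) {
  sample(setdiff(DNA_BASES, exclude), 1L)
}

#' Build a synthetic reference with annotation layers
#'
#' Generates the sequences, plants the repeat catalog outside exons (a
#' user-supplied catalog overlapping coding exons is rejected), lays out
#' domains, genes, chromatin and A/T clusters, and returns an annotated
#' [load_reference()]-compatible genome. With `dir` set, the standard file
#' set (FASTA, GFF3, BED tracks, expression TSV) is also written, and
#' reloading those files reproduces the same annotation layers.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the same seed yields a byte-identical genome.
#' @param dir Optional output directory for the file set.
#' @return List with `genome` (annotated `ma_genome`), `planted_repeats`
#'   (truth tibble of planted runs), and `files` (named paths or `NULL`).
#' @export
build_reference <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(derive_seed(seed, "reference"), {
    chroms <- spec$chromosomes
    if (spec$mito_length > 0L) {
      chroms <- bind_rows(chroms, tibble(name = spec$mito_name,
                                         length = spec$mito_length))
    }
    seqs <- list(); genes <- list(); exons <- list(); planted <- list()
    domains <- list(); chromatin <- list(); at_cl <- list()
    gene_n <- 0L
    for (ci in seq_len(nrow(chroms))) {
      nm <- chroms$name[ci]; len <- as.integer(chroms$length[ci])
      is_mito <- identical(nm, spec$mito_name) && spec$mito_length > 0L
      letters <- sample_bases(len, spec$gc)
      lay <- if (is_mito) list(genes = tibble(), exons = tibble())
             else layout_genes(nm, len, spec, gene_n)
      gene_n <- gene_n + nrow(lay$genes)
      occupied <- logical(len)
      if (nrow(lay$exons)) {
        for (i in seq_len(nrow(lay$exons))) {
          occupied[lay$exons$start[i]:lay$exons$end[i]] <- TRUE
        }
      }
      ## plant repeats proportional to chromosome share of the genome
      share <- len / sum(chroms$length)
      plan <- bind_rows(
        tidyr::crossing(kind = "hp", base_class = "AT", run_len = spec$hp_lengths,
                        idx = seq_len(max(1L, round(spec$hp_per_length_at * share)))),
        tidyr::crossing(kind = "hp", base_class = "GC", run_len = spec$hp_lengths,
                        idx = seq_len(max(1L, round(spec$hp_per_length_gc * share)))),
        tidyr::crossing(kind = "dinuc", motif = c("AT", "AC", "AG", "CG"),
                        copies = spec$dinuc_copies,
                        idx = seq_len(max(1L, round(spec$dinuc_per_cell * share))))
      )
      if (is_mito) plan <- plan |> dplyr::slice_sample(prop = 0.1)
      for (i in seq_len(nrow(plan))) {
        if (identical(plan$kind[i], "hp")) {
          base <- if (plan$base_class[i] == "AT") sample(c("A", "T"), 1L)
                  else sample(c("G", "C"), 1L)
          unit <- base; L <- plan$run_len[i]
        } else {
          unit <- plan$motif[i]; L <- 2L * plan$copies[i]
        }
        placed <- FALSE
        for (try in 1:200) {
          st <- sample.int(len - L - 2L, 1L) + 1L
          span <- (st - 1L):(st + L)
          if (any(occupied[span])) next
          p <- nchar(unit)
          run <- strrep(unit, ceiling(L / p))
          letters[st:(st + L - 1L)] <- strsplit(substr(run, 1L, L), "")[[1]]
          ## left extension needs s[st-1] == s[st+p-1]; right extension needs
          ## s[st+L] == s[st+L-p]
          letters[st - 1L] <- guard_base(c(substr(run, 1L, 1L),
                                           substr(run, p, p)))
          nxt <- L %% p + 1L
          letters[st + L] <- guard_base(c(substr(unit, nxt, nxt),
                                          substr(unit, 1L, 1L)))
          occupied[span] <- TRUE
          planted[[length(planted) + 1L]] <- tibble(
            chrom = nm, start = st, end = st + L - 1L, motif = unit,
            unit_length = nchar(unit), length_bp = L)
          placed <- TRUE
          break
        }
        if (!placed) warn(sprintf("could not place a repeat on %s", nm))
      }
      seqs[[nm]] <- paste(letters, collapse = "")
      genes[[nm]] <- lay$genes; exons[[nm]] <- lay$exons
      ## domains: ordered tip/arm/core/arm/tip segments (mito: single core)
      if (is_mito) {
        domains[[nm]] <- tibble(chrom = nm, start = 1L, end = len, domain = "core")
      } else {
        bnd <- round(cumsum(c(0, spec$domain_props)) * len)
        bnd[length(bnd)] <- len
        domains[[nm]] <- tibble(chrom = nm, start = head(bnd, -1) + 1L,
                                end = bnd[-1], domain = names(spec$domain_props)) |>
          filter(.data$end >= .data$start)
      }
      nb <- ceiling(len / spec$chromatin_block)
      bs <- (seq_len(nb) - 1L) * spec$chromatin_block + 1L
      chromatin[[nm]] <- tibble(chrom = nm, start = bs,
                                end = pmin(bs + spec$chromatin_block - 1L, len),
                                chromatin_state = sample(spec$chromatin_states, nb,
                                                         replace = TRUE))
      n_at <- rpois(1L, spec$at_cluster_density * len / 1000)
      if (n_at > 0L) {
        s_at <- sort(sample.int(len - 40L, n_at))
        at_cl[[nm]] <- tibble(chrom = nm, start = s_at, end = s_at + 29L)
      }
    }
    genome <- new_ma_genome(unlist(seqs), mito_name = spec$mito_name,
                            x_names = spec$x_names)
    genes_tbl <- bind_rows(genes)
    if (nrow(genes_tbl)) {
      genes_tbl$germline_expressed <-
        runif(nrow(genes_tbl)) < spec$germline_fraction
    } else {
      genes_tbl <- tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), germline_expressed = logical())
    }
    exons_tbl <- bind_rows(exons)
    if (!nrow(exons_tbl)) {
      exons_tbl <- tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer())
    }
    genome <- set_annotations(genome, genes = genes_tbl, exons = exons_tbl,
                              domains = bind_rows(domains),
                              chromatin = bind_rows(chromatin),
                              at_clusters = if (length(at_cl)) bind_rows(at_cl))
    files <- NULL
    if (!is.null(dir)) files <- write_reference_files(genome, dir)
    list(genome = genome, planted_repeats = bind_rows(planted), files = files)
  })
}

#' Write the standard annotation file set of a genome
#'
#' @param genome Annotated `ma_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`fasta, gff3, domains_bed,
#'   chromatin_bed, at_clusters_bed, expression_tsv`).
#' @export
write_reference_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    domains_bed = file.path(dir, "domains.bed"),
    chromatin_bed = file.path(dir, "chromatin.bed"),
    at_clusters_bed = file.path(dir, "at_clusters.bed"),
    expression_tsv = file.path(dir, "expression.tsv")
  )
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, paths$fasta)
  a <- genome$annot
  gg <- GenomicRanges::GRanges(a$genes$chrom,
                               IRanges::IRanges(a$genes$start, a$genes$end),
                               strand = a$genes$strand)
  S4Vectors::mcols(gg)$type <- "gene"
  S4Vectors::mcols(gg)$ID <- a$genes$gene_id
  ge <- GenomicRanges::GRanges(a$exons$chrom,
                               IRanges::IRanges(a$exons$start, a$exons$end))
  S4Vectors::mcols(ge)$type <- "exon"
  S4Vectors::mcols(ge)$ID <- sprintf("%s.e%d", a$exons$gene_id,
                                     seq_len(nrow(a$exons)))
  S4Vectors::mcols(ge)$Parent <- a$exons$gene_id
  S4Vectors::mcols(gg)$Parent <- NA_character_
  gff <- c(gg, ge)
  rtracklayer::export(gff, paths$gff3, format = "gff3")
  export_bed <- function(df, name_col, path) {
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$name <- if (is.null(name_col)) "interval" else df[[name_col]]
    rtracklayer::export(gr, path, format = "bed")
  }
  export_bed(a$domains, "domain", paths$domains_bed)
  if (!is.null(a$chromatin)) export_bed(a$chromatin, "chromatin_state", paths$chromatin_bed)
  else paths$chromatin_bed <- NULL
  if (!is.null(a$at_clusters)) export_bed(a$at_clusters, NULL, paths$at_clusters_bed)
  else paths$at_clusters_bed <- NULL
  readr::write_tsv(tibble(gene_id = a$genes$gene_id,
                          germline_expressed = as.integer(a$genes$germline_expressed)),
                   paths$expression_tsv)
  paths
}
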