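## Genome representation and site-level annotation layers.
##
## A `ma_genome` bundles chromosome sequences, the callable-site mask whose
## total is the B denominator of every mutation rate, the autosome/X/mito
## chromosome classification, and (once attached) layered annotations:
## gene models with exons, recombination domains (arm/core/tip), germline
## expression flags, chromatin states and periodic A/T-cluster intervals.
## All coordinates are 1-based closed, the GRanges/Biostrings convention.

new_ma_genome <- function(seqs, mito_name = "MtDNA", x_names = "X") {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    abort("all chromosome sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate chromosome names: %s",
                  paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  }
  if (length(seqs) == 0L || any(nchar(seqs) == 0L)) {
    abort("reference must contain at least one non-empty sequence")
  }
  seqs <- toupper(seqs)
  callable <- lapply(seqs, function(s) {
    r <- charToRaw(s)
    r == as.raw(65L) | r == as.raw(67L) | r == as.raw(71L) | r == as.raw(84L)
  })
  nm <- names(seqs)
  structure(list(
    seq = seqs,
    callable = callable,
    chrom_lengths = setNames(nchar(seqs), nm),
    mito_name = if (!is.null(mito_name) && mito_name %in% nm) mito_name else NULL,
    x_names = intersect(x_names, nm),
    is_autosome = setNames(!(nm %in% c(mito_name, x_names)), nm),
    annot = NULL
  ), class = "ma_genome")
}

#' Load a reference genome from FASTA
#'
#' Reads chromosome sequences and initialises the callable mask: `TRUE` at
#' A/C/G/T, `FALSE` at any other letter (N and ambiguity codes). The total
#' number of callable bases is the denominator of every per-site mutation
#' rate downstream. Mitochondrial and X chromosomes are recognised by
#' configurable name lists.
#'
#' @param fasta_path Path to a FASTA file (gzip accepted).
#' @param mito_name Chromosome name flagged as mitochondrial (if present).
#' @param x_names Chromosome names treated as X-linked.
#' @return An object of class `ma_genome`.
#' @export
load_reference <- function(fasta_path, mito_name = "MtDNA", x_names = "X") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) abort(sprintf("no sequences found in %s", fasta_path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_ma_genome(seqs, mito_name = mito_name, x_names = x_names)
}

#' @export
print.ma_genome <- function(x, ...) {
  cat(sprintf("<ma_genome> %d chromosome(s), %s callable / %s total bases\n",
              length(x$seq),
              format(callable_bases(x), big.mark = ","),
              format(sum(x$chrom_lengths), big.mark = ",")))
  for (nm in names(x$seq)) {
    tag <- if (!is.null(x$mito_name) && nm == x$mito_name) "mito"
           else if (nm %in% x$x_names) "X" else "autosome"
    cat(sprintf("  %-8s %10s bp  [%s]\n", nm,
                format(x$chrom_lengths[[nm]], big.mark = ","), tag))
  }
  cat(if (is.null(x$annot)) "  annotations: none\n" else "  annotations: attached\n")
  invisible(x)
}

#' Number of callable bases
#'
#' @param genome An `ma_genome`.
#' @param chroms Optional subset of chromosome names.
#' @return Integer count of callable (unmasked) positions.
#' @export
callable_bases <- function(genome, chroms = NULL) {
  stopifnot(inherits(genome, "ma_genome"))
  chroms <- chroms %||% names(genome$seq)
  sum(vapply(genome$callable[chroms], sum, numeric(1)))
}

## GRanges constructors kept internal; user surface stays tabular
as_gr <- function(df, label_cols = character()) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  for (cl in label_cols) S4Vectors::mcols(gr)[[cl]] <- df[[cl]]
  gr
}

#' Attach annotation layers from standard files
#'
#' Reads gene/exon models (GFF3), recombination-domain intervals (BED name
#' field holding `arm`/`core`/`tip`), a two-column gene-to-germline-expression
#' table, and optional chromatin-state and A/T-cluster BED tracks, then
#' attaches them to the genome so that every callable site resolves to
#' exactly one functional class and one domain.
#'
#' @param genome An `ma_genome`.
#' @param gff_path GFF3 with `gene` and `exon` records carrying a gene `ID`.
#' @param domains_bed BED of domain intervals; must cover each chromosome
#'   without gaps (an error lists uncovered ranges otherwise).
#' @param expression_table Path to a TSV with columns `gene_id`,
#'   `germline_expressed`, or an equivalent data frame.
#' @param chromatin_bed,at_clusters_bed Optional BED tracks for chromatin
#'   state (name field = state token) and periodic A/T clusters.
#' @param recombination_rates Named numeric vector of cM/Mb per domain label.
#' @return The genome with annotation layers attached.
#' @export
load_annotations <- function(genome, gff_path, domains_bed, expression_table,
                             chromatin_bed = NULL, at_clusters_bed = NULL,
                             recombination_rates = c(tip = 0.1, arm = 5, core = 1)) {
  gff <- rtracklayer::import(gff_path)
  ids <- S4Vectors::mcols(gff)$ID %||% S4Vectors::mcols(gff)$Name
  if (is.null(ids)) {
    ids <- S4Vectors::mcols(gff)$Parent
    ids <- vapply(as.list(ids), function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
  }
  typ <- as.character(S4Vectors::mcols(gff)$type)
  gtab <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = typ,
    gene_id = gene_id_from_gff(gff)
  )
  genes <- gtab |> filter(.data$type == "gene") |> select(-"type")
  exons <- gtab |> filter(.data$type == "exon") |> select(-"type")
  expr <- if (is.data.frame(expression_table)) {
    as_tibble(expression_table)
  } else {
    readr::read_tsv(expression_table, show_col_types = FALSE)
  }
  names(expr)[1:2] <- c("gene_id", "germline_expressed")
  expr$germline_expressed <- as.logical(expr$germline_expressed)
  genes <- left_join(genes, expr, by = "gene_id") |>
    mutate(germline_expressed = !is.na(.data$germline_expressed) &
             .data$germline_expressed)

  dom <- read_bed_labels(domains_bed, "domain")
  chromatin <- if (!is.null(chromatin_bed)) read_bed_labels(chromatin_bed, "chromatin_state")
  at <- if (!is.null(at_clusters_bed)) read_bed_labels(at_clusters_bed, "label")

  set_annotations(genome, genes = genes, exons = exons, domains = dom,
                  chromatin = chromatin, at_clusters = at,
                  recombination_rates = recombination_rates)
}

gene_id_from_gff <- function(gff) {
  mc <- S4Vectors::mcols(gff)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gff))
  if ("Parent" %in% names(mc)) {
    par <- vapply(as.list(mc$Parent), function(p) if (length(p)) as.character(p[[1]])
                  else NA_character_, character(1))
    id <- if_else(is.na(par) | par == "", id, par)
  }
  sub("^(gene|Gene):", "", id)
}

read_bed_labels <- function(path, label_col) {
  gr <- rtracklayer::import(path)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    !!label_col := as.character(S4Vectors::mcols(gr)$name %||% "interval")
  )
}

#' Attach in-memory annotation layers
#'
#' Tabular twin of [load_annotations()]; the synthetic-data generator uses
#' it directly so file round-trips stay optional.
#'
#' @param genome An `ma_genome`.
#' @param genes Tibble with `gene_id, chrom, start, end, strand,
#'   germline_expressed`.
#' @param exons Tibble with `gene_id, chrom, start, end`.
#' @param domains Tibble with `chrom, start, end, domain` covering every
#'   chromosome.
#' @param chromatin,at_clusters Optional interval tibbles.
#' @param recombination_rates Named numeric, cM/Mb per domain label.
#' @return The genome with `$annot` populated.
#' @export
set_annotations <- function(genome, genes, exons, domains,
                            chromatin = NULL, at_clusters = NULL,
                            recombination_rates = c(tip = 0.1, arm = 5, core = 1)) {
  stopifnot(inherits(genome, "ma_genome"))
  check_domain_cover(genome, domains)
  genome$annot <- list(
    genes = as_tibble(genes),
    exons = as_tibble(exons),
    domains = as_tibble(domains),
    chromatin = if (!is.null(chromatin)) as_tibble(chromatin),
    at_clusters = if (!is.null(at_clusters)) as_tibble(at_clusters),
    recombination_rates = recombination_rates,
    gr = list(
      genes = as_gr(genes, c("gene_id", "germline_expressed")),
      exons = as_gr(exons, "gene_id"),
      domains = as_gr(domains, "domain"),
      chromatin = if (!is.null(chromatin)) as_gr(chromatin, "chromatin_state"),
      at_clusters = if (!is.null(at_clusters)) as_gr(at_clusters)
    )
  )
  genome
}

check_domain_cover <- function(genome, domains) {
  for (nm in names(genome$seq)) {
    d <- domains[domains$chrom == nm, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, genome$chrom_lengths[[nm]]), ir)
    if (length(gaps) > 0L) {
      abort(sprintf(
        "domain intervals leave %s uncovered on %s: %s", length(gaps), nm,
        paste(sprintf("%d-%d", IRanges::start(gaps), IRanges::end(gaps))[
          seq_len(min(5L, length(gaps)))], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Annotate genomic sites
#'
#' Resolves each (chrom, pos) to its functional class (exon > intron >
#' intergenic), recombination domain, germline-expression status,
#' recombination rate, chromatin state and A/T-cluster membership. The
#' function is deterministic and total on callable sites; uncallable sites
#' are returned with `callable = FALSE` and `NA` labels.
#'
#' @param genome An annotated `ma_genome` (see [set_annotations()]).
#' @param sites Data frame with columns `chrom` and `pos` (1-based).
#' @return A tibble, one row per input site, in input order.
#' @export
annotate_sites <- function(genome, sites) {
  stopifnot(inherits(genome, "ma_genome"))
  if (is.null(genome$annot)) abort("genome has no annotations; see set_annotations()")
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  bad <- !sites$chrom %in% names(genome$seq) |
    sites$pos < 1L | sites$pos > genome$chrom_lengths[sites$chrom]
  if (any(bad)) abort(sprintf("%d site(s) outside chromosome bounds", sum(bad)))
  n <- nrow(sites)
  qry <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  a <- genome$annot$gr

  in_exon <- rep(FALSE, n)
  hit_ex <- GenomicRanges::findOverlaps(qry, a$exons)
  in_exon[unique(S4Vectors::queryHits(hit_ex))] <- TRUE

  gene_id <- rep(NA_character_, n)
  germ <- rep(FALSE, n)
  hit_g <- GenomicRanges::findOverlaps(qry, a$genes)
  if (length(hit_g)) {
    qh <- S4Vectors::queryHits(hit_g); sh <- S4Vectors::subjectHits(hit_g)
    keep <- !duplicated(qh)
    gene_id[qh[keep]] <- S4Vectors::mcols(a$genes)$gene_id[sh[keep]]
    gl <- tapply(S4Vectors::mcols(a$genes)$germline_expressed[sh], qh, any)
    germ[as.integer(names(gl))] <- as.logical(gl)
  }
  in_gene <- !is.na(gene_id)

  domain <- rep(NA_character_, n)
  hit_d <- GenomicRanges::findOverlaps(qry, a$domains)
  qh <- S4Vectors::queryHits(hit_d); keep <- !duplicated(qh)
  domain[qh[keep]] <- S4Vectors::mcols(a$domains)$domain[S4Vectors::subjectHits(hit_d)[keep]]

  chromatin <- rep("none", n)
  if (!is.null(a$chromatin)) {
    hit_c <- GenomicRanges::findOverlaps(qry, a$chromatin)
    qh <- S4Vectors::queryHits(hit_c); keep <- !duplicated(qh)
    chromatin[qh[keep]] <-
      S4Vectors::mcols(a$chromatin)$chromatin_state[S4Vectors::subjectHits(hit_c)[keep]]
  }
  at_cluster <- rep(FALSE, n)
  if (!is.null(a$at_clusters)) {
    hit_a <- GenomicRanges::findOverlaps(qry, a$at_clusters)
    at_cluster[unique(S4Vectors::queryHits(hit_a))] <- TRUE
  }

  callable <- mapply(function(ch, p) genome$callable[[ch]][p],
                     sites$chrom, sites$pos, USE.NAMES = FALSE)
  fc <- if_else(in_exon, "exon", if_else(in_gene, "intron", "intergenic"))
  fc[!callable] <- NA_character_
  tibble(
    chrom = sites$chrom, pos = sites$pos, callable = callable,
    functional_class = fc,
    domain = if_else(callable, domain, NA_character_),
    gene_id = gene_id,
    germline_expressed = germ & in_gene,
    recombination_rate = unname(genome$annot$recombination_rates[domain]),
    chromatin_state = chromatin,
    at_cluster = at_cluster,
    is_autosome = unname(genome$is_autosome[sites$chrom])
  )
}

#' Annotate a single site
#'
#' @param genome Annotated `ma_genome`.
#' @param chrom,pos Chromosome name and 1-based position.
#' @return One-row tibble as in [annotate_sites()].
#' @export
annotate_site <- function(genome, chrom, pos) {
  out <- annotate_sites(genome, tibble(chrom = chrom, pos = pos))
  if (!out$callable) {
    abort(sprintf("site %s:%d is masked (uncallable)", chrom, pos),
          class = "mamutspec_masked_site")
  }
  out
}

## Per-chromosome cumulative callable counts, for O(1) interval sums.
callable_cum <- function(genome) {
  lapply(genome$callable, function(m) cumsum(as.integer(m)))
}

interval_callable <- function(cum, start, end) {
  cum[end] - if (start > 1L) cum[start - 1L] else 0L
}

#' Census of callable bases by annotation partition
#'
#' Interval arithmetic over the annotation layers: callable base counts per
#' chromosome, recombination domain and functional class. These are the B
#' denominators for partitioned mutation rates; within each chromosome the
#' classes (and the domains) partition the callable sites exactly.
#'
#' @param genome Annotated `ma_genome`.
#' @return Tibble with `chrom, domain, functional_class, is_autosome, bases`.
#' @export
callable_census <- function(genome) {
  stopifnot(inherits(genome, "ma_genome"))
  if (is.null(genome$annot)) abort("genome has no annotations")
  cums <- callable_cum(genome)
  a <- genome$annot$gr
  out <- list()
  for (nm in names(genome$seq)) {
    len <- genome$chrom_lengths[[nm]]
    whole <- IRanges::IRanges(1L, len)
    sel <- function(gr) IRanges::reduce(IRanges::ranges(
      gr[as.character(GenomicRanges::seqnames(gr)) == nm]))
    ex <- sel(a$exons)
    gn <- sel(a$genes)
    intr <- IRanges::setdiff(gn, ex)
    inter <- IRanges::setdiff(whole, gn)
    cls <- list(exon = ex, intron = intr, intergenic = inter)
    dmt <- genome$annot$domains |> filter(.data$chrom == nm)
    for (ci in names(cls)) {
      for (k in seq_len(nrow(dmt))) {
        dd <- IRanges::IRanges(dmt$start[k], dmt$end[k])
        pieces <- IRanges::intersect(cls[[ci]], dd)
        b <- if (length(pieces)) {
          sum(mapply(interval_callable, IRanges::start(pieces), IRanges::end(pieces),
                     MoreArgs = list(cum = cums[[nm]])))
        } else 0L
        out[[length(out) + 1L]] <- tibble(
          chrom = nm, domain = dmt$domain[k], functional_class = ci,
          is_autosome = unname(genome$is_autosome[nm]), bases = as.numeric(b))
      }
    }
  }
  bind_rows(out) |>
    group_by(.data$chrom, .data$domain, .data$functional_class, .data$is_autosome) |>
    summarise(bases = sum(.data$bases), .groups = "drop")
}
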