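## Mutation classification: strand-collapsed substitution classes,
## trinucleotide context, repeat association and coding effects.

SUBSTITUTION_CLASSES <- c("A/T->G/C", "A/T->T/A", "A/T->C/G",
                          "G/C->A/T", "G/C->T/A", "G/C->C/G")
TRANSITION_CLASSES <- c("A/T->G/C", "G/C->A/T")

#' Strand-collapsed substitution class
#'
#' Collapses a base change and its reverse complement into one of six
#' classes (`A/T->G/C`, `A/T->T/A`, `A/T->C/G`, `G/C->A/T`, `G/C->T/A`,
#' `G/C->C/G`); the two transition classes are `A/T->G/C` and `G/C->A/T`.
#'
#' @param ref,alt Single reference and alternate bases (vectorised);
#'   `ref != alt`, both in A/C/G/T.
#' @return Tibble with `substitution_class` and `is_transition`.
#' @export
#' @examples
#' classify_substitution(c("A", "T", "C"), c("G", "A", "A"))
classify_substitution <- function(ref, alt) {
  assert_bases(ref); assert_bases(alt)
  if (any(ref == alt)) abort("ref and alt must differ")
  flip <- ref %in% c("T", "C")
  r <- if_else(flip, complement_base(ref), ref)
  a <- if_else(flip, complement_base(alt), alt)
  cls <- dplyr::case_when(
    r == "A" & a == "G" ~ "A/T->G/C",
    r == "A" & a == "T" ~ "A/T->T/A",
    r == "A" & a == "C" ~ "A/T->C/G",
    r == "G" & a == "A" ~ "G/C->A/T",
    r == "G" & a == "T" ~ "G/C->T/A",
    r == "G" & a == "C" ~ "G/C->C/G"
  )
  tibble(substitution_class = cls,
         is_transition = cls %in% TRANSITION_CLASSES)
}

#' Canonical reverse-complement-collapsed triplet key
#'
#' Maps a trinucleotide and its reverse complement onto one canonical key,
#' written `smaller/larger` (e.g. both `AAT` with a focal A and `ATT` with a
#' focal T yield `AAT/ATT`). 32 keys cover the 64 triplets.
#'
#' @param triplet Character vector of 3-mers over A/C/G/T.
#' @return Character vector of collapsed keys; `NA` for triplets with
#'   non-ACGT letters.
#' @export
collapse_triplet <- function(triplet) {
  rc <- revcomp(triplet)
  lo <- pmin(triplet, rc)
  hi <- pmax(triplet, rc)
  out <- paste0(lo, "/", hi)
  out[stringr::str_detect(triplet, "[^ACGT]") | nchar(triplet) != 3L] <- NA_character_
  out
}

#' Collapsed trinucleotide context of sites
#'
#' Extracts the 5'-x\[focal\]y-3' triplet around each site from the genome
#' and collapses it over strand with [collapse_triplet()]. Sites whose
#' flanks run off the contig or hit masked bases get `NA`.
#'
#' @param genome An `ma_genome`.
#' @param sites Data frame with `chrom`, `pos`.
#' @return Character vector of collapsed triplet keys.
#' @export
collapse_context <- function(genome, sites) {
  sites <- as_tibble(sites)
  len <- unname(genome$chrom_lengths[sites$chrom])
  ok <- sites$pos > 1L & sites$pos < len
  tri <- rep(NA_character_, nrow(sites))
  tri[ok] <- substr(genome$seq[sites$chrom[ok]], sites$pos[ok] - 1L,
                    sites$pos[ok] + 1L)
  collapse_triplet(ifelse(is.na(tri), "NNN", tri))
}

## per-codon fractional synonymous-site counts (Nei-Gojobori style):
## each codon position contributes the fraction of its three possible
## changes that preserve the amino acid (changes to or from stop count as
## nonsynonymous sites).
codon_syn_fraction_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    f <- 0
    for (p in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (code[[alt]] == code[[cd]]) f <- f + 1 / 3
      }
    }
    syn[cd] <- f
  }
  syn
}

gene_cds <- function(genome, gene) {
  ex <- genome$annot$exons |>
    filter(.data$gene_id == gene) |>
    arrange(.data$start)
  chrom <- genome$annot$genes$chrom[genome$annot$genes$gene_id == gene][1]
  seqs <- substr(rep(genome$seq[[chrom]], nrow(ex)), ex$start, ex$end)
  strand <- genome$annot$genes$strand[genome$annot$genes$gene_id == gene][1]
  cds <- paste(seqs, collapse = "")
  ## genomic positions of successive CDS bases, 5' to 3'
  gpos <- unlist(purrr::map2(ex$start, ex$end, seq))
  if (identical(strand, "-")) {
    cds <- revcomp(cds)
    gpos <- rev(gpos)
  }
  list(cds = cds, gpos = gpos, strand = strand, chrom = chrom)
}

#' Coding effect of mutations
#'
#' SNPs inside coding exons are classified synonymous/nonsynonymous by codon
#' translation; exonic indels are `frameshift` when their size is not a
#' multiple of 3 and `in-frame-indel` otherwise; everything else is
#' `noncoding`. Genes whose concatenated exons are not a multiple of 3 are
#' excluded with a warning.
#'
#' @param variants Tibble with `chrom, pos, ref, alt` (and optionally
#'   `variant_type`).
#' @param genome Annotated `ma_genome` whose exons are taken as CDS.
#' @return Character vector of effects, aligned with `variants`.
#' @export
classify_coding_effect <- function(variants, genome) {
  variants <- as_tibble(variants)
  if (is.null(genome$annot)) abort("genome has no annotations")
  if (!"variant_type" %in% names(variants)) {
    variants$variant_type <- variant_type_of(variants$ref, variants$alt)
  }
  ann <- annotate_sites(genome, variants |> select("chrom", "pos"))
  out <- rep("noncoding", nrow(variants))
  exonic <- which(ann$functional_class %in% "exon" & !is.na(ann$gene_id))
  if (!length(exonic)) return(out)

  code <- Biostrings::GENETIC_CODE
  broken <- character()
  cds_cache <- list()
  for (i in exonic) {
    if (variants$variant_type[i] != "snp") {
      sz <- nchar(variants$alt[i]) - nchar(variants$ref[i])
      out[i] <- if (sz %% 3L == 0L) "in-frame-indel" else "frameshift"
      next
    }
    gene <- ann$gene_id[i]
    g <- cds_cache[[gene]]
    if (is.null(g)) {
      g <- gene_cds(genome, gene)
      if (nchar(g$cds) %% 3L != 0L) g$broken <- TRUE
      cds_cache[[gene]] <- g
    }
    if (isTRUE(g$broken)) {
      broken <- union(broken, gene)
      out[i] <- NA_character_
      next
    }
    ci <- match(variants$pos[i], g$gpos)
    if (is.na(ci)) next # exon record outside cached model; leave noncoding
    codon_i <- (ci - 1L) %/% 3L
    codon <- substr(g$cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    off <- (ci - 1L) %% 3L + 1L
    altb <- if (identical(g$strand, "-")) complement_base(variants$alt[i]) else variants$alt[i]
    mcodon <- codon
    substr(mcodon, off, off) <- altb
    out[i] <- if (code[[codon]] == code[[mcodon]]) "synonymous" else "nonsynonymous"
  }
  if (length(broken)) {
    warn(sprintf("excluded %d gene(s) with CDS length not divisible by 3: %s",
                 length(broken), paste(head(broken, 5), collapse = ", ")))
  }
  out
}

#' Synonymous and nonsynonymous site counts per gene
#'
#' Fractional site counting: each codon position contributes the fraction
#' of its three possible single-base changes that leave the amino acid
#' unchanged. Totals per gene satisfy `syn + nonsyn = 3 * n_codons`.
#'
#' @param genome Annotated `ma_genome`.
#' @param genes Optional character vector of gene ids (default all).
#' @return Tibble `gene_id, n_codons, syn_sites, nonsyn_sites`.
#' @export
synonymous_site_counts <- function(genome, genes = NULL) {
  if (is.null(genome$annot)) abort("genome has no annotations")
  genes <- genes %||% genome$annot$genes$gene_id
  syn_tab <- codon_syn_fraction_table()
  purrr::map_dfr(genes, function(gene) {
    g <- gene_cds(genome, gene)
    L <- nchar(g$cds)
    if (L %% 3L != 0L) {
      warn(sprintf("gene %s CDS not divisible by 3; skipped", gene))
      return(tibble(gene_id = gene, n_codons = NA_integer_,
                    syn_sites = NA_real_, nonsyn_sites = NA_real_))
    }
    codons <- substring(g$cds, seq(1L, L, 3L), seq(3L, L, 3L))
    s <- sum(syn_tab[codons])
    tibble(gene_id = gene, n_codons = L %/% 3L,
           syn_sites = s, nonsyn_sites = L - s)
  })
}

#' Build fully classified mutation records
#'
#' Turns accepted variant calls into analysis-ready mutation records:
#' variant type and signed indel size, strand-collapsed substitution class,
#' collapsed trinucleotide context, repeat association against the catalog,
#' site annotations (functional class, domain, germline expression,
#' chromosome) and coding effect. Indels are assigned to partitions by
#' their left-aligned anchor base.
#'
#' @param calls Tibble with `line, chrom, pos, ref, alt` (VCF-style
#'   anchored alleles).
#' @param genome Annotated `ma_genome`.
#' @param catalog Repeat catalog from [detect_repeats()]; computed from the
#'   genome when `NULL`.
#' @param flank Repeat adjacency window in bp.
#' @param coding Also classify coding effects (needs exon models).
#' @return Tibble of mutation records.
#' @export
classify_mutations <- function(calls, genome, catalog = NULL, flank = 1L,
                               coding = TRUE) {
  calls <- as_tibble(calls)
  catalog <- catalog %||% detect_repeats(genome)
  rec <- calls |>
    mutate(variant_type = variant_type_of(.data$ref, .data$alt),
           indel_size = if_else(.data$variant_type == "snp", NA_integer_,
                                nchar(.data$alt) - nchar(.data$ref)))
  is_snp <- rec$variant_type == "snp"
  rec$substitution_class <- NA_character_
  rec$is_transition <- NA
  if (any(is_snp)) {
    cs <- classify_substitution(rec$ref[is_snp], rec$alt[is_snp])
    rec$substitution_class[is_snp] <- cs$substitution_class
    rec$is_transition[is_snp] <- cs$is_transition
  }
  rec$context_triplet <- NA_character_
  if (any(is_snp)) {
    rec$context_triplet[is_snp] <-
      collapse_context(genome, rec[is_snp, c("chrom", "pos")])
  }
  rec <- map_variant_to_repeat(rec, catalog, flank = flank)
  ann <- annotate_sites(genome, rec |> select("chrom", "pos")) |>
    select("functional_class", "domain", "gene_id", "germline_expressed",
           "recombination_rate", "chromatin_state", "at_cluster", "is_autosome")
  rec <- bind_cols(rec, ann)
  rec$coding_effect <- if (coding) classify_coding_effect(rec, genome) else NA_character_
  rec
}
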