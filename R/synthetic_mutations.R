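## Planting mutations in MA lines.
##
## Mutations are planted as fixed (homozygous) per line, matching the
## post-MA inbreeding step of the experimental design; at most one hit per
## site per line is kept (the MA analysis assumption at realistic rates).
## Expected counts follow mu * G * B per class; homopolymer and
## dinucleotide-run indels are planted per catalogued run with
## length-dependent multipliers, and indels are left-aligned with a
## VCF-style anchor base.

#' Mutation-spectrum configuration for the simulator
#'
#' Defaults reproduce the study conditions of an MMR-impaired outcrossing
#' MA experiment: a total substitution rate of 4.22e-8 /site/gen split
#' across the six strand-collapsed classes in the observed proportions
#' (pooled Ts/Tv about 1.12), deletion and insertion rates of 1.47e-7 and
#' 7.59e-8 /site/gen (about a 2:1 deletion bias) of which roughly two
#' thirds fall in homopolymeric runs, run-length multipliers peaking at
#' 11 bp for A/T runs and 8 bp for G/C runs, and dinucleotide families with
#' an insertion bias in AT/TA, a slight deletion bias in AC/GT and AG/CT,
#' and deletions only in CG/GC.
#'
#' @param class_rates Named rates (/site/gen) for the six substitution
#'   classes.
#' @param ins_rate,del_rate Background (non-repeat) indel rates /site/gen.
#' @param deletion_fraction Probability that a background or homopolymer
#'   indel is a deletion.
#' @param hp_rate_at,hp_rate_gc Homopolymer indel rate per run per
#'   generation at multiplier 1.
#' @param hp_multipliers List with `AT` and `GC` named numeric vectors:
#'   run-length (bp) to rate multiplier.
#' @param dinuc_rates Tibble `family, ins_rate, del_rate` per run per
#'   generation for the four dinucleotide families.
#' @param indel_size_probs Probabilities of background indel sizes 1..100.
#' @param context_multipliers Optional named numeric of collapsed triplet
#'   keys; reweights substitution placement within a class.
#' @return A `spectrum_config` list.
#' @export
spectrum_config <- function(
    class_rates = 4.22e-8 * c("A/T->G/C" = 886, "A/T->T/A" = 545,
                              "A/T->C/G" = 403, "G/C->A/T" = 768,
                              "G/C->T/A" = 494, "G/C->C/G" = 29) / 3125,
    ins_rate = 2.5e-8, del_rate = 5.0e-8,
    deletion_fraction = 1.47 / (1.47 + 0.76),
    hp_rate_at = 2e-4, hp_rate_gc = 4e-4,
    hp_multipliers = list(
      AT = c(`6` = 0.10, `7` = 0.18, `8` = 0.32, `9` = 0.52, `10` = 0.78,
             `11` = 1.00, `12` = 0.70, `13` = 0.48, `14` = 0.32, `15` = 0.22),
      GC = c(`6` = 0.25, `7` = 0.55, `8` = 1.00, `9` = 0.70, `10` = 0.45,
             `11` = 0.30, `12` = 0.20, `13` = 0.15, `14` = 0.10, `15` = 0.08)),
    dinuc_rates = tibble(
      family = c("AT/TA", "AC/GT", "AG/CT", "CG/GC"),
      ins_rate = c(4e-4, 1.5e-4, 1.5e-4, 0),
      del_rate = c(2e-4, 1.8e-4, 1.8e-4, 2e-4)),
    indel_size_probs = c(0.955, 0.03, local({
      p <- 0.01 * 0.55^(0:97); p * (0.015 / sum(p))
    })),
    context_multipliers = NULL) {
  stopifnot(length(class_rates) == 6L, all(class_rates >= 0),
            ins_rate >= 0, del_rate >= 0,
            deletion_fraction >= 0, deletion_fraction <= 1,
            length(indel_size_probs) == 100L,
            abs(sum(indel_size_probs) - 1) < 1e-6,
            all(indel_size_probs >= 0))
  if (is.null(names(class_rates))) names(class_rates) <- SUBSTITUTION_CLASSES
  stopifnot(setequal(names(class_rates), SUBSTITUTION_CLASSES))
  structure(list(class_rates = class_rates[SUBSTITUTION_CLASSES],
                 ins_rate = ins_rate, del_rate = del_rate,
                 deletion_fraction = deletion_fraction,
                 hp_rate_at = hp_rate_at, hp_rate_gc = hp_rate_gc,
                 hp_multipliers = hp_multipliers, dinuc_rates = dinuc_rates,
                 indel_size_probs = indel_size_probs,
                 context_multipliers = context_multipliers),
            class = "spectrum_config")
}

#' Experiment design for the simulator
#'
#' @param n_lines Number of MA lines.
#' @param generations Generations per line: a scalar or a length-`n_lines`
#'   vector (the study design was nominally 50 with realised line values
#'   between 28 and 45).
#' @param seed Base seed driving the hierarchical per-line streams.
#' @return An `experiment_config` list with a `lines` tibble.
#' @export
experiment_config <- function(n_lines = 19L, generations = 40L, seed = 1L) {
  stopifnot(n_lines >= 1, all(generations >= 1))
  G <- if (length(generations) == 1L) rep(generations, n_lines) else generations
  stopifnot(length(G) == n_lines)
  structure(list(n_lines = n_lines, seed = seed,
                 lines = tibble(line = sprintf("L%02d", seq_len(n_lines)),
                                generations = as.numeric(G))),
            class = "experiment_config")
}

## Pools of callable positions by base group, flattened genome-wide with
## cumulative offsets so uniform draws are O(1).
site_pools <- function(genome) {
  pools <- list()
  for (grp in c("AT", "GC")) {
    idx <- lapply(names(genome$seq), function(nm) {
      r <- charToRaw(genome$seq[[nm]])
      sel <- if (grp == "AT") r == as.raw(65L) | r == as.raw(84L)
             else r == as.raw(71L) | r == as.raw(67L)
      which(sel & genome$callable[[nm]])
    })
    names(idx) <- names(genome$seq)
    sizes <- vapply(idx, length, numeric(1))
    pools[[grp]] <- list(idx = idx, sizes = sizes, total = sum(sizes),
                         cum = cumsum(sizes))
  }
  pools
}

draw_pool_sites <- function(pool, k, weights = NULL) {
  if (k == 0L) return(tibble(chrom = character(), pos = integer()))
  u <- if (is.null(weights)) sample.int(pool$total, k, replace = TRUE)
       else sample.int(pool$total, k, replace = TRUE, prob = weights)
  ci <- findInterval(u - 1L, c(0, pool$cum), rightmost.closed = FALSE)
  off <- u - c(0, pool$cum)[ci]
  tibble(chrom = names(pool$idx)[ci],
         pos = unlist(purrr::map2(ci, off, function(a, b) pool$idx[[a]][b]),
                      use.names = FALSE))
}

alt_for_class <- function(ref, class) {
  base_alt <- dplyr::case_when(
    class == "A/T->G/C" ~ "G", class == "A/T->T/A" ~ "T",
    class == "A/T->C/G" ~ "C", class == "G/C->A/T" ~ "A",
    class == "G/C->T/A" ~ "T", class == "G/C->C/G" ~ "C")
  if_else(ref %in% c("A", "G"), base_alt, complement_base(base_alt))
}

base_at <- function(genome, chrom, pos) {
  substr(genome$seq[chrom], pos, pos)
}

#' Plant mutations across MA lines
#'
#' Draws, per line and mutation component, Poisson event counts with
#' expectation rate * G * B (substitutions and background indels; B =
#' callable bases) or rate * multiplier * G per catalogued run (repeat
#' indels), places them, and returns the fixed ground-truth mutation set.
#' Collisions at the same (line, position) keep the first event. A warning
#' is raised if any per-site expected mutation load exceeds 10%, where the
#' one-hit approximation breaks down.
#'
#' @param genome Annotated `ma_genome`.
#' @param spectrum A [spectrum_config()].
#' @param experiment An [experiment_config()].
#' @param catalog Repeat catalog (computed from the genome when `NULL`).
#' @return Truth tibble: `line, chrom, pos, ref, alt, variant_type,
#'   indel_size, origin, generation`.
#' @export
simulate_ma_lines <- function(genome, spectrum, experiment, catalog = NULL) {
  stopifnot(inherits(spectrum, "spectrum_config"),
            inherits(experiment, "experiment_config"))
  catalog <- catalog %||% detect_repeats(genome)
  B <- callable_bases(genome)
  pools <- site_pools(genome)
  maxG <- max(experiment$lines$generations)
  site_load <- (sum(spectrum$class_rates) + spectrum$ins_rate + spectrum$del_rate) * maxG
  if (site_load > 0.1) {
    warn("per-site mutation load exceeds 10%; one-hit-per-site model is strained")
  }
  ctx_weights <- NULL
  if (!is.null(spectrum$context_multipliers)) {
    ctx_weights <- lapply(pools, function(pool) {
      keys <- unlist(lapply(names(pool$idx), function(nm) {
        collapse_context(genome, tibble(chrom = nm, pos = pool$idx[[nm]]))
      }), use.names = FALSE)
      w <- spectrum$context_multipliers[keys]
      w[is.na(w)] <- 1
      unname(w)
    })
  }
  hp <- catalog |>
    filter(.data$unit_length == 1L, .data$base_class %in% c("AT", "GC")) |>
    mutate(run_length = .data$end - .data$start + 1L)
  hp$mult <- purrr::map2_dbl(hp$base_class, hp$run_length, function(bc, L) {
    m <- spectrum$hp_multipliers[[bc]][as.character(L)]
    if (is.na(m)) 0 else m
  })
  hp$rate <- if_else(hp$base_class == "AT", spectrum$hp_rate_at,
                     spectrum$hp_rate_gc) * hp$mult
  din <- catalog |>
    filter(.data$unit_length == 2L) |>
    mutate(family = dinucleotide_family(.data$motif)) |>
    left_join(spectrum$dinuc_rates, by = "family")

  out <- purrr::map_dfr(seq_len(experiment$n_lines), function(li) {
    line <- experiment$lines$line[li]
    G <- experiment$lines$generations[li]
    with_seed(derive_seed(experiment$seed, "line", line), {
      rows <- list()
      ## substitutions, class by class
      for (cls in SUBSTITUTION_CLASSES) {
        grp <- if (startsWith(cls, "A/T")) "AT" else "GC"
        k <- rpois(1L, spectrum$class_rates[[cls]] * B * G)
        if (k == 0L) next
        sites <- draw_pool_sites(pools[[grp]], k,
                                 weights = ctx_weights[[grp]])
        ref <- base_at(genome, sites$chrom, sites$pos)
        rows[[length(rows) + 1L]] <- sites |>
          mutate(ref = ref, alt = alt_for_class(ref, cls),
                 variant_type = "snp", indel_size = NA_integer_,
                 origin = "substitution")
      }
      ## background indels
      k <- rpois(1L, (spectrum$ins_rate + spectrum$del_rate) * B * G)
      if (k > 0L) {
        grp_k <- stats::rbinom(1L, k, pools$AT$total / (pools$AT$total + pools$GC$total))
        sites <- bind_rows(draw_pool_sites(pools$AT, grp_k),
                           draw_pool_sites(pools$GC, k - grp_k))
        is_del <- runif(k) < spectrum$deletion_fraction
        sz <- sample.int(100L, k, replace = TRUE, prob = spectrum$indel_size_probs)
        len <- unname(genome$chrom_lengths[sites$chrom])
        ok <- sites$pos + sz < len & sites$pos > 1L
        sites <- sites[ok, ]; is_del <- is_del[ok]; sz <- sz[ok]
        if (nrow(sites)) {
          anchor <- base_at(genome, sites$chrom, sites$pos)
          ref <- if_else(is_del,
                         substr(genome$seq[sites$chrom], sites$pos, sites$pos + sz),
                         anchor)
          ins_seq <- vapply(sz, function(s) paste(sample_bases(s, 0.36), collapse = ""),
                            character(1))
          alt <- if_else(is_del, anchor, paste0(anchor, ins_seq))
          rows[[length(rows) + 1L]] <- sites |>
            mutate(ref = ref, alt = alt,
                   variant_type = if_else(is_del, "deletion", "insertion"),
                   indel_size = as.integer(if_else(is_del, -sz, sz)),
                   origin = "background_indel")
        }
      }
      ## homopolymer-run indels (one unit, left-aligned at the run anchor)
      if (nrow(hp)) {
        ev <- rpois(nrow(hp), hp$rate * G)
        hits <- rep(seq_len(nrow(hp)), ev)
        if (length(hits)) {
          r <- hp[hits, ]
          is_del <- runif(nrow(r)) < spectrum$deletion_fraction
          ok <- r$start > 1L
          r <- r[ok, ]; is_del <- is_del[ok]
          anchor_pos <- r$start - 1L
          anchor <- base_at(genome, r$chrom, anchor_pos)
          runb <- base_at(genome, r$chrom, r$start)
          rows[[length(rows) + 1L]] <- tibble(
            chrom = r$chrom, pos = anchor_pos,
            ref = if_else(is_del, paste0(anchor, runb), anchor),
            alt = if_else(is_del, anchor, paste0(anchor, runb)),
            variant_type = if_else(is_del, "deletion", "insertion"),
            indel_size = as.integer(if_else(is_del, -1L, 1L)),
            origin = "homopolymer_indel")
        }
      }
      ## dinucleotide-run indels (one 2-bp unit)
      if (nrow(din)) {
        for (dir in c("ins", "del")) {
          rate <- if (dir == "ins") din$ins_rate else din$del_rate
          ev <- rpois(nrow(din), rate * G)
          hits <- rep(seq_len(nrow(din)), ev)
          if (!length(hits)) next
          r <- din[hits, ]
          ok <- r$start > 1L
          r <- r[ok, ]
          if (!nrow(r)) next
          anchor_pos <- r$start - 1L
          anchor <- base_at(genome, r$chrom, anchor_pos)
          unit <- substr(genome$seq[r$chrom], r$start, r$start + 1L)
          rows[[length(rows) + 1L]] <- tibble(
            chrom = r$chrom, pos = anchor_pos,
            ref = if (dir == "del") paste0(anchor, unit) else anchor,
            alt = if (dir == "del") anchor else paste0(anchor, unit),
            variant_type = if (dir == "del") "deletion" else "insertion",
            indel_size = if (dir == "del") -2L else 2L,
            origin = "dinucleotide_indel")
        }
      }
      if (!length(rows)) return(tibble())
      bind_rows(rows) |>
        mutate(line = line,
               generation = sample.int(G, dplyr::n(), replace = TRUE)) |>
        distinct(.data$pos, .data$chrom, .keep_all = TRUE) |>
        select("line", "chrom", "pos", "ref", "alt", "variant_type",
               "indel_size", "origin", "generation")
    })
  })
  if (nrow(out) == 0L) {
    return(tibble(line = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(),
                  variant_type = character(), indel_size = integer(),
                  origin = character(), generation = integer()))
  }
  out |> arrange(.data$line, .data$chrom, .data$pos)
}
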