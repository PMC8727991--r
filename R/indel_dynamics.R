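## Repeat-resolved indel (and SNP-adjacency) dynamics.
##
## Homopolymer indel rates are normalised per run: for each (base class,
## run length, direction) cell the event count is divided by the number of
## genomic runs of that length and class times the summed line generations,
## giving events per run per generation. The same normalisation gives the
## SNP-adjacency rate per run length and the per-motif-family dinucleotide
## insertion/deletion rates.

hp_census <- function(catalog) {
  catalog |>
    filter(.data$unit_length == 1L, .data$base_class %in% c("AT", "GC")) |>
    mutate(run_length = .data$end - .data$start + 1L) |>
    count(.data$base_class, .data$run_length, name = "n_runs")
}

#' Homopolymer-resolved indel or SNP-adjacency rates
#'
#' @param records Classified mutation records (see [classify_mutations()]);
#'   events are those with `repeat_status` in `in_repeat`/`adjacent` whose
#'   associated run is a homopolymer.
#' @param catalog Repeat catalog of the same genome.
#' @param lines Tibble `line, generations`.
#' @param type `"indel"` for insertion/deletion rates split by direction,
#'   `"snp_adjacent"` for the substitution-adjacency rate per run length.
#' @return Tibble `base_class, run_length[, direction], events, n_runs,
#'   rate` (events per run per generation); run lengths absent from the
#'   genome are excluded.
#' @export
homopolymer_indel_rates <- function(records, catalog, lines,
                                    type = c("indel", "snp_adjacent")) {
  type <- match.arg(type)
  records <- as_tibble(records)
  census <- hp_census(catalog)
  gen_total <- sum(as_tibble(lines)$generations)
  assoc <- records |>
    filter(.data$repeat_status %in% c("in_repeat", "adjacent"),
           .data$run_unit_length == 1L,
           .data$run_base_class %in% c("AT", "GC"))
  if (type == "indel") {
    ev <- assoc |>
      filter(!is.na(.data$indel_size)) |>
      mutate(direction = if_else(.data$indel_size < 0, "deletion", "insertion")) |>
      count(base_class = .data$run_base_class, run_length = .data$run_length,
            .data$direction, name = "events")
    grid <- tidyr::crossing(census, direction = c("deletion", "insertion"))
  } else {
    ev <- assoc |>
      filter(.data$variant_type == "snp") |>
      count(base_class = .data$run_base_class, run_length = .data$run_length,
            name = "events")
    grid <- census
  }
  grid |>
    left_join(ev, by = intersect(names(grid), names(ev))) |>
    mutate(events = dplyr::coalesce(.data$events, 0L),
           rate = .data$events / (.data$n_runs * gen_total)) |>
    arrange(.data$base_class, .data$run_length)
}

#' Dinucleotide microsatellite insertion/deletion rates by motif family
#'
#' @inheritParams homopolymer_indel_rates
#' @return Tibble `family, direction, events, n_runs, rate` over the four
#'   motif families `AT/TA, AC/GT, AG/CT, CG/GC`; families with no genomic
#'   runs are excluded.
#' @export
dinucleotide_indel_dynamics <- function(records, catalog, lines) {
  records <- as_tibble(records)
  din <- catalog |> filter(.data$unit_length == 2L)
  if (nrow(din) == 0L) {
    return(tibble(family = character(), direction = character(),
                  events = integer(), n_runs = integer(), rate = numeric()))
  }
  census <- din |>
    mutate(family = dinucleotide_family(.data$motif)) |>
    count(.data$family, name = "n_runs")
  gen_total <- sum(as_tibble(lines)$generations)
  ev <- records |>
    filter(!is.na(.data$indel_size),
           .data$repeat_status %in% c("in_repeat", "adjacent"),
           .data$run_unit_length == 2L) |>
    mutate(family = dinucleotide_family(.data$run_motif),
           direction = if_else(.data$indel_size < 0, "deletion", "insertion")) |>
    count(.data$family, .data$direction, name = "events")
  tidyr::crossing(census, direction = c("deletion", "insertion")) |>
    left_join(ev, by = c("family", "direction")) |>
    mutate(events = dplyr::coalesce(.data$events, 0L),
           rate = .data$events / (.data$n_runs * gen_total)) |>
    arrange(.data$family, .data$direction)
}
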