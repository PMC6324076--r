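#' Read-length distribution of a store
#'
#' Marginal count of retained reads per read length (summed over transcripts,
#' positions and ambiguity classes, using 5'-end records so each read is
#' counted once). Totals equal the store's retained-read count.
#'
#' @param store An `end_count_store`.
#' @return A tibble (`read_length`, `count`) sorted by read length.
#' @export
readlength_distribution <- function(store) {
  store |>
    as_tibble() |>
    filter(.data$end == "five_prime") |>
    group_by(.data$read_length) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$read_length)
}

#' Triplet periodicity per read length
#'
#' Elongating ribosomes advance one codon at a time, so footprint positions
#' inside coding regions show 3-nt phasing. For each unambiguous read whose
#' offset-adjusted A-site falls inside a coding region (stop codon excluded:
#' positions `cds_start` to `cds_stop - 1`), the phase
#' `(A-site - cds_start) mod 3` is tallied per read length. The in-frame
#' fraction (largest phase over the total) measures periodicity strength and
#' hence the power to detect translated reading frames.
#'
#' @param store An `end_count_store`.
#' @param reference A `ribo_reference`.
#' @param offsets An `offset_table`.
#' @param positions `"asite"` (default) phases offset-adjusted A-sites;
#'   `"raw"` phases unadjusted 5' ends, for comparison.
#' @param ambiguity Ambiguity mode (default `"unambiguous"`).
#' @return A tibble with one row per read length: `f0`, `f1`, `f2` (counts by
#'   phase), `total`, and `in_frame_fraction` (`NA` when no CDS reads).
#' @export
triplet_periodicity <- function(store, reference, offsets,
                                positions = "asite",
                                ambiguity = "unambiguous") {
  stopifnot_reference(reference)
  positions <- match_arg2(positions, c("asite", "raw"))
  if (positions == "asite") {
    recs <- site_records(store, offsets, reference, end = "five_prime",
                         site = "a", ambiguity = ambiguity)
  } else {
    recs <- store |>
      as_tibble() |>
      filter(.data$end == "five_prime") |>
      filter_ambiguity(ambiguity) |>
      select("transcript_id", "read_length", "position", "count")
  }
  cds <- reference |>
    filter(!is.na(.data$cds_start)) |>
    select("transcript_id", "cds_start", "cds_stop")

  phased <- recs |>
    inner_join(cds, by = "transcript_id") |>
    filter(.data$position >= .data$cds_start, .data$position <= .data$cds_stop - 1L) |>
    mutate(phase = (.data$position - .data$cds_start) %% 3L) |>
    group_by(.data$read_length, .data$phase) |>
    summarise(count = sum(.data$count), .groups = "drop")

  lengths <- sort(unique(recs$read_length))
  tidyr::expand_grid(read_length = lengths, phase = 0:2) |>
    left_join(phased, by = c("read_length", "phase")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "count",
                       names_prefix = "f") |>
    mutate(
      total = .data$f0 + .data$f1 + .data$f2,
      in_frame_fraction = if_else(
        .data$total > 0,
        pmax(.data$f0, .data$f1, .data$f2) / .data$total,
        NA_real_
      )
    ) |>
    arrange(.data$read_length)
}

#' Plot a read-length distribution
#'
#' @param dist Tibble from [readlength_distribution()].
#' @return A ggplot bar chart.
#' @export
plot_readlength_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$read_length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Read length (nt)", y = "Reads") +
    ggplot2::theme_minimal()
}

#' Plot triplet periodicity
#'
#' Three bars per read length, one per phase, mirroring the standard
#' periodicity QC display.
#'
#' @param periodicity Tibble from [triplet_periodicity()].
#' @return A ggplot bar chart.
#' @export
plot_periodicity <- function(periodicity) {
  long <- periodicity |>
    select("read_length", "f0", "f1", "f2") |>
    tidyr::pivot_longer(c("f0", "f1", "f2"),
                        names_to = "phase", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$read_length),
                                     y = .data$count, fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(f0 = "#e41a1c", f1 = "#4daf4a", f2 = "#377eb8")) +
    ggplot2::labs(x = "Read length (nt)", y = "CDS-mapped reads", fill = "Phase") +
    ggplot2::theme_minimal()
}
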