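#' Sub-codon resolution transcript profile
#'
#' Builds the per-position A-site density of one transcript from one or more
#' stores, split by reading frame, together with its three-frame ORF
#' architecture. The frame of a position is the positional residue
#' `(position - 1) mod 3`, so the density of a translated ORF concentrates in
#' the series of the frame it is read in — the basis of frame-coloured
#' footprint displays and of nested/overlapping ORF detection.
#'
#' @param stores An `end_count_store` or list of stores (merged before
#'   profiling).
#' @param reference A `ribo_reference`.
#' @param offsets An `offset_table`.
#' @param transcript_id Transcript to profile.
#' @param min_length,max_length Read-length bounds applied before offsetting
#'   (defaults 25 and unbounded).
#' @param ambiguity Ambiguity mode (default `"unambiguous"`).
#' @param site `"a"` (default) or `"p"` ribosome site.
#' @return A `transcript_profile` object: a list with `transcript_id`,
#'   `gene_name`, `data` (tibble `position`, `nucleotide`, `frame`, `count`),
#'   `architecture` (from [orf_architecture()]), `cds` (start/stop or NULL)
#'   and `options` echoing the filters used.
#' @export
transcript_profile <- function(stores, reference, offsets, transcript_id,
                               min_length = 25L, max_length = Inf,
                               ambiguity = "unambiguous", site = "a") {
  stopifnot_reference(reference)
  store <- merge_stores(stores)
  row <- filter(reference, .data$transcript_id == !!transcript_id)
  if (nrow(row) == 0) {
    near <- reference |>
      filter(stringr::str_detect(
        .data$gene_name,
        stringr::fixed(transcript_id, ignore_case = TRUE)
      )) |>
      pull("transcript_id")
    hint <- if (length(near) > 0) {
      sprintf(" Did you mean (by gene name): %s?", paste(head(near, 5), collapse = ", "))
    } else ""
    abort(sprintf("Unknown transcript '%s'.%s", transcript_id, hint))
  }

  recs <- site_records(store, offsets, reference, end = "five_prime",
                       site = site, ambiguity = ambiguity,
                       min_length = min_length,
                       max_length = if (is.finite(max_length)) max_length else NULL)
  dense <- recs |>
    filter(.data$transcript_id == !!transcript_id) |>
    group_by(.data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")

  len <- row$length[1]
  data <- tibble(position = seq_len(len)) |>
    left_join(dense, by = "position") |>
    mutate(
      count = dplyr::coalesce(.data$count, 0L),
      nucleotide = stringr::str_sub(row$sequence[1], .data$position, .data$position),
      frame = position_frame(.data$position)
    ) |>
    select("position", "nucleotide", "frame", "count")

  structure(
    list(
      transcript_id = transcript_id,
      gene_name = row$gene_name[1],
      data = data,
      architecture = orf_architecture(row$sequence[1]),
      cds = if (is.na(row$cds_start[1])) NULL else
        list(cds_start = row$cds_start[1], cds_stop = row$cds_stop[1]),
      options = list(
        min_length = min_length, max_length = max_length,
        ambiguity = ambiguity, site = site
      )
    ),
    class = "transcript_profile"
  )
}

#' @export
print.transcript_profile <- function(x, ...) {
  cat(sprintf(
    "<transcript_profile> %s (%s): %d nt, %d A-site counts\n",
    x$transcript_id, x$gene_name, nrow(x$data), sum(x$data$count)
  ))
  invisible(x)
}

#' Frame series of a transcript profile
#'
#' Decomposes the A-site vector into three per-position series, one per
#' reading frame: `count_frameF[i]` equals the A-site count at `i` when
#' `(i - 1) mod 3 == F` and 0 otherwise, so the three series sum to the
#' A-site vector exactly.
#'
#' @param profile A `transcript_profile`.
#' @return A tibble `position`, `count_frame0`, `count_frame1`,
#'   `count_frame2`, `total`.
#' @export
profile_frames <- function(profile) {
  stopifnot(inherits(profile, "transcript_profile"))
  profile$data |>
    mutate(
      count_frame0 = if_else(.data$frame == 0L, .data$count, 0L),
      count_frame1 = if_else(.data$frame == 1L, .data$count, 0L),
      count_frame2 = if_else(.data$frame == 2L, .data$count, 0L),
      total = .data$count
    ) |>
    select("position", "count_frame0", "count_frame1", "count_frame2", "total")
}

#' Windowed dominant reading frame
#'
#' Collapses a transcript profile to codons and reports, for each codon
#' window, the frame with the largest A-site mass. With `window_codons = 1`
#' each codon is called individually; larger windows act as a sliding
#' majority smoother for display. Contiguous runs of the same dominant frame
#' delineate translated intervals, e.g. a nested ORF in a shifted frame
#' inside the CDS.
#'
#' @param profile A `transcript_profile`.
#' @param window_codons Odd window width in codons (default 1 = no
#'   smoothing).
#' @return A tibble per codon: `codon_start` (transcript position of the
#'   codon's first nt), `f0`, `f1`, `f2` (window sums) and `dominant_frame`
#'   (`NA` when the window is empty).
#' @export
dominant_frames <- function(profile, window_codons = 1L) {
  stopifnot(inherits(profile, "transcript_profile"))
  if (window_codons %% 2L != 1L) abort("`window_codons` must be odd.")
  d <- profile$data
  n_codons <- nrow(d) %/% 3L
  if (n_codons == 0) {
    return(tibble(codon_start = integer(), f0 = numeric(), f1 = numeric(),
                  f2 = numeric(), dominant_frame = integer()))
  }
  per_codon <- d |>
    filter(.data$position <= 3L * n_codons) |>
    mutate(codon = (.data$position - 1L) %/% 3L) |>
    group_by(.data$codon, .data$frame) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "count",
                       names_prefix = "f", values_fill = 0L)
  for (nm in c("f0", "f1", "f2")) if (!nm %in% names(per_codon)) per_codon[[nm]] <- 0L
  half <- (window_codons - 1L) %/% 2L
  roll <- function(v) {
    if (half == 0L) return(as.numeric(v))
    purrr::map_dbl(seq_along(v), function(i) {
      sum(v[max(1L, i - half):min(length(v), i + half)])
    })
  }
  per_codon |>
    arrange(.data$codon) |>
    mutate(across(c("f0", "f1", "f2"), roll)) |>
    mutate(
      codon_start = 3L * .data$codon + 1L,
      dominant_frame = if_else(
        .data$f0 + .data$f1 + .data$f2 > 0,
        max.col(cbind(.data$f0, .data$f1, .data$f2), ties.method = "first") - 1L,
        NA_integer_
      )
    ) |>
    select("codon_start", "f0", "f1", "f2", "dominant_frame")
}

#' Multi-sample comparison profile for one transcript
#'
#' Plots-ready per-position vectors for several sample groups on the same
#' transcript. Ribo-Seq groups contribute offset-adjusted A-site densities;
#' RNA-Seq groups contribute full-read coverage (offsets are a ribosome
#' concept). With `normalize = TRUE`, each group's vector is scaled to reads
#' per million retained reads, which makes libraries of different depths
#' comparable.
#'
#' @param groups Named list; each element is either a store / list of stores,
#'   or a list with elements `stores` and optionally `sequence_type`
#'   (defaulting to the stores' own metadata).
#' @param reference A `ribo_reference`.
#' @param offsets An `offset_table` (used for riboseq groups).
#' @param transcript_id Transcript to profile.
#' @param normalize Scale each group to reads per million (default TRUE).
#' @param min_length,max_length,ambiguity As in [transcript_profile()].
#' @return A `comparison_profile` object: list with `transcript_id`, `data`
#'   (tibble `group`, `position`, `count`), and `groups` (tibble `group`,
#'   `sequence_type`, `total_reads`, `scale_factor`, `normalized`).
#' @export
compare_profiles <- function(groups, reference, offsets, transcript_id,
                             normalize = TRUE, min_length = 25L,
                             max_length = Inf, ambiguity = "unambiguous") {
  stopifnot_reference(reference)
  if (length(groups) == 0) abort("At least one group is required.")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list.")
  }
  ref_tag <- assembly_tag(reference)
  row <- filter(reference, .data$transcript_id == !!transcript_id)
  if (nrow(row) == 0) abort(sprintf("Unknown transcript '%s'.", transcript_id))
  len <- row$length[1]

  one_group <- function(g, label) {
    if (inherits(g, "end_count_store") || (is.list(g) && is.null(g$stores))) {
      g <- list(stores = g)
    }
    store <- merge_stores(g$stores)
    if (store_meta(store)$assembly != ref_tag) {
      abort(sprintf("Group '%s' was built against a different reference.", label))
    }
    seq_type <- g$sequence_type %||% store_meta(store)$sequence_type
    total <- store_meta(store)$total_retained_reads
    recs <- store |>
      as_tibble() |>
      filter(.data$transcript_id == !!transcript_id, .data$end == "five_prime") |>
      filter_ambiguity(ambiguity) |>
      filter(.data$read_length >= min_length, .data$read_length <= max_length)
    if (seq_type == "rnaseq") {
      # full-read coverage from 5' end + read length
      vec <- numeric(len)
      if (nrow(recs) > 0) {
        for (i in seq_len(nrow(recs))) {
          lo <- recs$position[i]
          hi <- min(len, recs$position[i] + recs$read_length[i] - 1L)
          vec[lo:hi] <- vec[lo:hi] + recs$count[i]
        }
      }
      raw <- tibble(position = seq_len(len), count = vec)
    } else {
      raw <- apply_offsets(
        filter_lengths_store(store, min_length, max_length),
        offsets, reference,
        transcript_id = transcript_id, ambiguity = ambiguity
      )
    }
    scale <- if (normalize) 1e6 / max(total, 1) else 1
    list(
      data = mutate(raw, group = label, count = .data$count * scale),
      meta = tibble(group = label, sequence_type = seq_type,
                    total_reads = total, scale_factor = scale,
                    normalized = normalize)
    )
  }

  parts <- purrr::imap(groups, one_group)
  structure(
    list(
      transcript_id = transcript_id,
      data = bind_rows(purrr::map(parts, "data")) |>
        select("group", "position", "count"),
      groups = bind_rows(purrr::map(parts, "meta")),
      options = list(normalize = normalize, min_length = min_length,
                     max_length = max_length, ambiguity = ambiguity)
    ),
    class = "comparison_profile"
  )
}

# Restrict a store to a read-length window, keeping metadata consistent with
# the retained records.
filter_lengths_store <- function(store, min_length, max_length) {
  meta <- store_meta(store)
  counts <- store |>
    as_tibble() |>
    filter(.data$read_length >= min_length, .data$read_length <= max_length)
  meta$total_retained_reads <- counts |>
    filter(.data$end == "five_prime") |>
    pull("count") |>
    sum()
  new_end_count_store(counts, meta)
}

#' Export a transcript profile as CSV
#'
#' One row per transcript position with the nucleotide and the A-site count
#' decomposed by reading frame, matching the downloadable table of
#' frame-coloured transcript browsers.
#'
#' @param profile A `transcript_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "transcript_profile"))
  profile_frames(profile) |>
    mutate(nucleotide = profile$data$nucleotide) |>
    select("position", "nucleotide", "count_frame0", "count_frame1",
           "count_frame2", "total") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Plot a sub-codon transcript profile
#'
#' Frame-coloured A-site density (red/green/blue for frames 0/1/2) over the
#' transcript, with the three-lane ORF architecture underneath: one lane per
#' frame, start codons as short white ticks and stop codons as longer grey
#' ticks.
#'
#' @param object A `transcript_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transcript_profile <- function(object, ...) {
  frame_cols <- c(`0` = "#e41a1c", `1` = "#4daf4a", `2` = "#377eb8")
  d <- object$data
  ymax <- max(d$count, 1L)
  lane_h <- ymax * 0.06
  lanes <- tibble(frame = 0:2) |>
    mutate(ymin = -lane_h * (.data$frame + 1L), ymax = -lane_h * .data$frame)
  arch <- object$architecture |>
    left_join(lanes, by = "frame") |>
    mutate(
      tick_ymin = .data$ymin,
      tick_ymax = if_else(.data$kind == "start",
                          .data$ymin + 0.5 * lane_h, .data$ymax),
      colour = if_else(.data$kind == "start", "white", "grey30")
    )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = lanes,
      ggplot2::aes(xmin = 1, xmax = nrow(d), ymin = .data$ymin, ymax = .data$ymax,
                   fill = factor(.data$frame)),
      alpha = 0.6
    ) +
    ggplot2::geom_segment(
      data = arch,
      ggplot2::aes(x = .data$position, xend = .data$position,
                   y = .data$tick_ymin, yend = .data$tick_ymax),
      colour = arch$colour, linewidth = 0.4
    ) +
    ggplot2::geom_line(
      data = mutate(d, frame = factor(.data$frame)),
      ggplot2::aes(x = .data$position, y = .data$count, colour = .data$frame,
                   group = .data$frame),
      linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(values = frame_cols) +
    ggplot2::scale_fill_manual(values = frame_cols, guide = "none") +
    ggplot2::labs(
      title = sprintf("%s (%s)", object$transcript_id, object$gene_name),
      x = "Transcript position (nt)", y = "A-site count", colour = "Frame"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a comparison profile
#'
#' One coloured density track per sample group on a common transcript axis.
#'
#' @param object A `comparison_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_profile <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$position, y = .data$count, colour = .data$group)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      title = object$transcript_id,
      x = "Transcript position (nt)",
      y = if (isTRUE(object$options$normalize)) "Reads per million" else "Reads",
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}
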