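#' Start/stop-anchored metagene profile per read length
#'
#' Aggregates read-end counts from all coding transcripts around a common
#' anchor (the first nucleotide of the start or stop codon, relative
#' position 0). The 5'-end profile around start codons shows the
#' characteristic peak of initiating ribosomes upstream of the start codon
#' and is the input to A-site offset calibration.
#'
#' Only coding transcripts with at least `window` nucleotides on both sides
#' of the anchor contribute, so every transcript covers the full window and
#' edge effects cancel.
#'
#' @param store An `end_count_store`.
#' @param reference A `ribo_reference` with at least one coding transcript.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param end Which read end to aggregate: `"five_prime"` or `"three_prime"`.
#' @param window Half-width of the window in nt (default 100).
#' @param ambiguity `"unambiguous"` (default), `"ambiguous"` or `"both"`.
#' @return A tibble of class `metagene_profile` with columns `read_length`,
#'   `rel_pos` (-window..window) and `count`, dense over the grid of read
#'   lengths present in the store.
#' @export
metagene_profile <- function(store, reference, anchor = "start_codon",
                             end = "five_prime", window = 100L,
                             ambiguity = "unambiguous") {
  stopifnot_reference(reference)
  anchor <- match_arg2(anchor, c("start_codon", "stop_codon"))
  end <- match_arg2(end, c("five_prime", "three_prime"))

  coding <- filter(reference, !is.na(.data$cds_start))
  if (nrow(coding) == 0) abort("Reference contains no coding transcripts.")
  anchors <- coding |>
    mutate(anchor_pos = if (anchor == "start_codon") .data$cds_start else .data$cds_stop) |>
    filter(.data$anchor_pos - window >= 1L,
           .data$anchor_pos + window <= .data$length) |>
    select("transcript_id", "anchor_pos")

  recs <- store |>
    as_tibble() |>
    filter(.data$end == !!end) |>
    filter_ambiguity(ambiguity)
  lengths_present <- sort(unique(recs$read_length))

  prof <- recs |>
    inner_join(anchors, by = "transcript_id") |>
    mutate(rel_pos = .data$position - .data$anchor_pos) |>
    filter(abs(.data$rel_pos) <= window) |>
    group_by(.data$read_length, .data$rel_pos) |>
    summarise(count = sum(.data$count), .groups = "drop")

  grid <- tidyr::expand_grid(
    read_length = lengths_present,
    rel_pos = seq.int(-window, window)
  )
  out <- grid |>
    left_join(prof, by = c("read_length", "rel_pos")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$read_length, .data$rel_pos)
  structure(out,
    anchor = anchor, end = end, window = as.integer(window),
    class = c("metagene_profile", class(tibble()))
  )
}

#' Infer per-readlength A-site offsets from metagene peaks
#'
#' For each read length, the 5' offset is the distance between the highest
#' 5'-end metagene peak upstream of the start codon and the start codon
#' itself (where the initiating ribosome holds the start codon in its
#' P-site), plus 3 nt to step from the P-site to the decoding A-site. The 3'
#' offset is the distance to the highest 3'-end peak downstream of the start
#' codon, minus 3. Ties are broken toward the smallest absolute distance.
#' Read lengths with no signal in the search range fall back to a default
#' offset with a warning, as do inferred offsets outside `[1, read_length]`.
#'
#' @param mg5 `metagene_profile` of 5' ends anchored at start codons.
#' @param mg3 `metagene_profile` of 3' ends anchored at start codons.
#' @param fallback Offset used when no peak is found (default 15 nt).
#' @return An `offset_table` tibble: `read_length`, `offset_5`, `offset_3`,
#'   `source` (`"inferred"` or `"fallback"`).
#' @export
infer_offsets <- function(mg5, mg3, fallback = 15L) {
  check_mg <- function(x, want_end, arg) {
    if (!inherits(x, "metagene_profile") || attr(x, "anchor") != "start_codon" ||
        attr(x, "end") != want_end) {
      abort(sprintf("`%s` must be a start-codon metagene profile of %s ends.", arg, want_end))
    }
  }
  check_mg(mg5, "five_prime", "mg5")
  check_mg(mg3, "three_prime", "mg3")

  lengths <- sort(union(unique(mg5$read_length), unique(mg3$read_length)))
  fell_back <- character()

  peak <- function(prof, L, lo, hi) {
    sub <- filter(as_tibble(prof), .data$read_length == L,
                  .data$rel_pos >= lo, .data$rel_pos <= hi)
    if (nrow(sub) == 0 || all(sub$count == 0)) return(NA_integer_)
    sub |>
      arrange(desc(.data$count), abs(.data$rel_pos)) |>
      slice(1) |>
      pull("rel_pos")
  }

  rows <- purrr::map(lengths, function(L) {
    w5 <- attr(mg5, "window")
    w3 <- attr(mg3, "window")
    d5 <- peak(mg5, L, -w5, -1L)
    d3 <- peak(mg3, L, 1L, w3)
    off5 <- if (is.na(d5)) NA_integer_ else abs(d5) + 3L
    off3 <- if (is.na(d3)) NA_integer_ else d3 - 3L
    src <- "inferred"
    bad <- function(o) is.na(o) || o < 1L || o > L
    if (bad(off5) || bad(off3)) {
      if (bad(off5)) off5 <- as.integer(fallback)
      if (bad(off3)) off3 <- as.integer(fallback)
      src <- "fallback"
      fell_back <<- c(fell_back, as.character(L))
    }
    tibble(read_length = L, offset_5 = off5, offset_3 = off3, source = src)
  }) |> bind_rows()

  if (length(fell_back) > 0) {
    warn(sprintf(
      "No usable metagene peak for read length(s) %s; using fallback offset %d.",
      paste(fell_back, collapse = ", "), as.integer(fallback)
    ))
  }
  structure(rows, class = c("offset_table", class(tibble())))
}

#' Build an offset table from known offsets
#'
#' Convenience constructor when offsets are known a priori (e.g. simulation
#' truth, or a published table) rather than inferred from a metagene.
#'
#' @param read_length Integer vector of read lengths.
#' @param offset_5 5' offsets (recycled).
#' @param offset_3 3' offsets (recycled); default `read_length - 1 - offset_5`,
#'   the value consistent with a fixed A-site position within the read.
#' @return An `offset_table`.
#' @export
offset_table <- function(read_length, offset_5, offset_3 = NULL) {
  offset_5 <- as.integer(rep_len(offset_5, length(read_length)))
  if (is.null(offset_3)) offset_3 <- as.integer(read_length) - 1L - offset_5
  tbl <- tibble(
    read_length = as.integer(read_length),
    offset_5 = offset_5,
    offset_3 = as.integer(rep_len(offset_3, length(read_length))),
    source = "supplied"
  )
  structure(tbl, class = c("offset_table", class(tibble())))
}

# Offset-adjust a store's end records to inferred ribosome sites. Returns
# sparse (transcript_id, read_length, position, count) with out-of-bounds
# positions dropped and tallied in attr "dropped". site = "a" uses the
# offsets as-is; "p" shifts 3 nt upstream (P-site).
site_records <- function(store, offsets, reference, end = "five_prime",
                         site = "a", ambiguity = "unambiguous",
                         min_length = NULL, max_length = NULL) {
  if (!inherits(offsets, "offset_table")) abort("`offsets` must be an offset_table.")
  site <- match_arg2(site, c("a", "p"))
  end <- match_arg2(end, c("five_prime", "three_prime"))
  recs <- store |>
    as_tibble() |>
    filter(.data$end == !!end) |>
    filter_ambiguity(ambiguity)
  if (!is.null(min_length)) recs <- filter(recs, .data$read_length >= min_length)
  if (!is.null(max_length)) recs <- filter(recs, .data$read_length <= max_length)

  recs <- left_join(recs, select(as_tibble(offsets), "read_length", "offset_5", "offset_3"),
                    by = "read_length")
  if (anyNA(recs$offset_5)) {
    miss <- sort(unique(recs$read_length[is.na(recs$offset_5)]))
    warn(sprintf(
      "No offset for read length(s) %s; using fallback 15.",
      paste(miss, collapse = ", ")
    ))
    recs$offset_5[is.na(recs$offset_5)] <- 15L
    recs$offset_3[is.na(recs$offset_3)] <- 15L
  }
  shift3 <- if (site == "p") 3L else 0L
  if (end == "five_prime") {
    recs$position <- recs$position + recs$offset_5 - shift3
  } else {
    recs$position <- recs$position - recs$offset_3 - shift3
  }
  recs <- left_join(recs, select(reference, "transcript_id", tx_length = "length"),
                    by = "transcript_id")
  oob <- recs$position < 1L | recs$position > recs$tx_length
  dropped <- sum(recs$count[oob])
  out <- recs[!oob, ] |>
    group_by(.data$transcript_id, .data$read_length, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "dropped") <- dropped
  out
}

#' Offset-adjusted ribosome-site count vector
#'
#' Shifts each read-end record by its read length's offset to the inferred
#' ribosomal A-site (5' position + offset, or 3' position - offset) and
#' accumulates per-position counts. Positions pushed outside the transcript
#' are dropped and tallied in the `dropped` attribute of the result.
#'
#' @param store An `end_count_store`.
#' @param offsets An `offset_table` (from [infer_offsets()] or
#'   [offset_table()]).
#' @param reference A `ribo_reference`.
#' @param transcript_id A single transcript to profile, or `NULL` for a
#'   sparse table over all transcripts.
#' @param end Which stored end to shift (default `"five_prime"`).
#' @param site `"a"` (default) for the A-site, `"p"` for the P-site (3 nt
#'   upstream).
#' @param ambiguity Ambiguity mode, as in [metagene_profile()].
#' @return For a single transcript, a dense tibble (`position`, `count`)
#'   covering 1..length; otherwise a sparse tibble
#'   (`transcript_id`, `position`, `count`).
#' @export
apply_offsets <- function(store, offsets, reference, transcript_id = NULL,
                          end = "five_prime", site = "a",
                          ambiguity = "unambiguous") {
  stopifnot_reference(reference)
  recs <- site_records(store, offsets, reference, end = end, site = site,
                       ambiguity = ambiguity)
  dropped <- attr(recs, "dropped")
  if (is.null(transcript_id)) {
    out <- recs |>
      group_by(.data$transcript_id, .data$position) |>
      summarise(count = sum(.data$count), .groups = "drop")
    attr(out, "dropped") <- dropped
    return(out)
  }
  row <- filter(reference, .data$transcript_id == !!transcript_id)
  if (nrow(row) == 0) abort(sprintf("Unknown transcript '%s'.", transcript_id))
  dense <- recs |>
    filter(.data$transcript_id == !!transcript_id) |>
    group_by(.data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")
  out <- tibble(position = seq_len(row$length[1])) |>
    left_join(dense, by = "position") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(out, "dropped") <- dropped
  out
}

#' Plot a metagene profile
#'
#' Read-end frequency relative to the anchor codon, one line per read length.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$rel_pos, y = .data$count,
                 colour = factor(.data$read_length))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("Position relative to %s (nt)", attr(object, "anchor")),
      y = sprintf("%s end count", if (attr(object, "end") == "five_prime") "5'" else "3'"),
      colour = "Read length"
    ) +
    ggplot2::theme_minimal()
}
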