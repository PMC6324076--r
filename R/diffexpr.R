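#' Per-transcript read counts
#'
#' Total reads per transcript from one or more stores, either over the whole
#' transcript (`region = "all"`: every retained read, counted once via its
#' 5'-end record) or restricted to the annotated coding region
#' (`region = "cds"`: offset-adjusted A-sites within the CDS; non-coding
#' transcripts get 0).
#'
#' @param stores An `end_count_store` or list of stores.
#' @param reference A `ribo_reference`.
#' @param region `"all"` (default) or `"cds"`.
#' @param offsets An `offset_table`; required for `region = "cds"`.
#' @param ambiguity Ambiguity mode (default `"unambiguous"`).
#' @return A tibble (`transcript_id`, `count`) covering every reference
#'   transcript (zeros included).
#' @export
transcript_counts <- function(stores, reference, region = "all",
                              offsets = NULL, ambiguity = "unambiguous") {
  stopifnot_reference(reference)
  region <- match_arg2(region, c("all", "cds"))
  store <- merge_stores(stores)
  if (region == "all") {
    counted <- store |>
      as_tibble() |>
      filter(.data$end == "five_prime") |>
      filter_ambiguity(ambiguity) |>
      group_by(.data$transcript_id) |>
      summarise(count = sum(.data$count), .groups = "drop")
  } else {
    if (is.null(offsets)) abort("`offsets` is required for region = 'cds'.")
    cds <- reference |>
      filter(!is.na(.data$cds_start)) |>
      select("transcript_id", "cds_start", "cds_stop")
    counted <- site_records(store, offsets, reference, end = "five_prime",
                            site = "a", ambiguity = ambiguity) |>
      inner_join(cds, by = "transcript_id") |>
      filter(.data$position >= .data$cds_start,
             .data$position <= .data$cds_stop + 2L) |>
      group_by(.data$transcript_id) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  reference |>
    as_tibble() |>
    select("transcript_id") |>
    left_join(counted, by = "transcript_id") |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$transcript_id)
}

#' Differential expression by geometric-mean binned z-scores
#'
#' Compares per-transcript counts between two conditions. For each transcript
#' the log2 fold change `log2(count_B / count_A)` is plotted against the
#' geometric mean `sqrt(count_A * count_B)`; because count noise shrinks with
#' expression, the spread of null log ratios depends strongly on the
#' geometric mean. Transcripts are therefore ranked by descending geometric
#' mean and partitioned into consecutive bins of `bin_size`, and each
#' transcript's log ratio is standardized against its own bin's mean and
#' standard deviation to give a z-score. Transcripts with `z >= z_threshold`
#' are called up-regulated (in B relative to A), `z <= -z_threshold`
#' down-regulated, the rest not significant.
#'
#' @param counts_a,counts_b Tibbles (`transcript_id`, `count`) or named
#'   numeric vectors over the same transcript universe.
#' @param bin_size Transcripts per bin (default 300). A final partial bin
#'   with fewer than 30 transcripts is merged into the preceding bin.
#' @param z_threshold Call threshold on the z-score (default 2).
#' @param min_count Transcripts with a raw count below this in either
#'   condition are excluded (default 1, i.e. zeros dropped).
#' @param normalize_totals Scale each condition to counts per million of its
#'   total before forming ratios (default FALSE).
#' @param pseudocount Constant added to both (possibly normalized) counts
#'   before ratios (default 0).
#' @return A `zscore_de` object; `tidy()` returns the per-transcript table
#'   (`transcript_id`, `count_a`, `count_b`, `geometric_mean`, `log_ratio`,
#'   `bin`, `z_score`, `call`), `glance()` a one-row summary.
#' @export
zscore_differential <- function(counts_a, counts_b, bin_size = 300L,
                                z_threshold = 2, min_count = 1L,
                                normalize_totals = FALSE, pseudocount = 0) {
  as_counts <- function(x, arg) {
    if (is_tibble(x) || is.data.frame(x)) {
      if (!all(c("transcript_id", "count") %in% names(x))) {
        abort(sprintf("`%s` needs columns transcript_id and count.", arg))
      }
      tibble(transcript_id = x$transcript_id, count = as.numeric(x$count))
    } else if (is.numeric(x) && !is.null(names(x))) {
      tibble(transcript_id = names(x), count = as.numeric(x))
    } else {
      abort(sprintf("`%s` must be a tibble or a named numeric vector.", arg))
    }
  }
  a <- as_counts(counts_a, "counts_a")
  b <- as_counts(counts_b, "counts_b")
  total_a <- sum(a$count)
  total_b <- sum(b$count)

  tbl <- full_join(a, b, by = "transcript_id", suffix = c("_a", "_b")) |>
    mutate(across(c("count_a", "count_b"), ~ dplyr::coalesce(.x, 0))) |>
    filter(.data$count_a >= min_count, .data$count_b >= min_count)
  if (normalize_totals) {
    tbl <- tbl |>
      mutate(
        count_a = .data$count_a * 1e6 / max(total_a, 1),
        count_b = .data$count_b * 1e6 / max(total_b, 1)
      )
  }
  if (pseudocount > 0) {
    tbl <- mutate(tbl, count_a = .data$count_a + pseudocount,
                  count_b = .data$count_b + pseudocount)
  }
  if (nrow(tbl) < 2) abort("Fewer than 2 transcripts survive filtering.")
  if (any(tbl$count_a <= 0 | tbl$count_b <= 0)) {
    abort("Non-positive counts in ratio; raise `min_count` or set a `pseudocount`.")
  }

  tbl <- tbl |>
    mutate(
      geometric_mean = sqrt(.data$count_a * .data$count_b),
      log_ratio = log2(.data$count_b / .data$count_a)
    ) |>
    arrange(desc(.data$geometric_mean), .data$transcript_id) |>
    mutate(bin = (row_number() - 1L) %/% as.integer(bin_size) + 1L)
  n_bins <- max(tbl$bin)
  last_n <- sum(tbl$bin == n_bins)
  if (n_bins > 1 && last_n < 30) {
    tbl$bin[tbl$bin == n_bins] <- n_bins - 1L
  }

  zero_sd_bins <- integer()
  tbl <- tbl |>
    group_by(.data$bin) |>
    mutate(
      bin_mean = mean(.data$log_ratio),
      bin_sd = sd(.data$log_ratio)
    ) |>
    ungroup()
  degenerate <- is.na(tbl$bin_sd) | tbl$bin_sd == 0
  if (any(degenerate)) {
    zero_sd_bins <- sort(unique(tbl$bin[degenerate]))
    warn(sprintf(
      "Bin(s) %s have zero log-ratio variance; z-scores set to 0 there.",
      paste(zero_sd_bins, collapse = ", ")
    ))
  }
  tbl <- tbl |>
    mutate(
      z_score = if_else(.data$bin_sd > 0 & !is.na(.data$bin_sd),
                        (.data$log_ratio - .data$bin_mean) / .data$bin_sd, 0),
      call = dplyr::case_when(
        .data$z_score >= z_threshold ~ "up",
        .data$z_score <= -z_threshold ~ "down",
        TRUE ~ "ns"
      )
    ) |>
    select("transcript_id", "count_a", "count_b", "geometric_mean",
           "log_ratio", "bin", "z_score", "call")

  structure(
    list(
      table = tbl,
      params = list(bin_size = as.integer(bin_size), z_threshold = z_threshold,
                    min_count = min_count, normalize_totals = normalize_totals,
                    pseudocount = pseudocount),
      totals = c(a = total_a, b = total_b),
      zero_sd_bins = zero_sd_bins
    ),
    class = "zscore_de"
  )
}

#' @export
print.zscore_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<zscore_de> %d transcripts in %d bins (bin size %d): %d up, %d down at |z| >= %g\n",
    g$n_transcripts, g$n_bins, x$params$bin_size, g$n_up, g$n_down,
    x$params$z_threshold
  ))
  invisible(x)
}

#' @rdname zscore_differential
#' @param x A `zscore_de` object.
#' @param ... Unused.
#' @export
tidy.zscore_de <- function(x, ...) x$table

#' @rdname zscore_differential
#' @export
glance.zscore_de <- function(x, ...) {
  tibble(
    n_transcripts = nrow(x$table),
    n_bins = dplyr::n_distinct(x$table$bin),
    n_up = sum(x$table$call == "up"),
    n_down = sum(x$table$call == "down"),
    bin_size = x$params$bin_size,
    z_threshold = x$params$z_threshold
  )
}

#' MA-style plot of a binned z-score comparison
#'
#' Log fold change against geometric mean (log scale); up-regulated
#' transcripts in green, down-regulated in red, and the per-bin z-score
#' threshold traced as yellow lines.
#'
#' @param object A `zscore_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zscore_de <- function(object, ...) {
  tbl <- object$table
  thr <- object$params$z_threshold
  bands <- tbl |>
    group_by(.data$bin) |>
    summarise(
      gm_min = min(.data$geometric_mean),
      gm_max = max(.data$geometric_mean),
      upper = mean(.data$log_ratio) + thr * sd(.data$log_ratio),
      lower = mean(.data$log_ratio) - thr * sd(.data$log_ratio),
      .groups = "drop"
    )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$geometric_mean, y = .data$log_ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), size = 0.6, alpha = 0.7) +
    ggplot2::geom_segment(
      data = bands,
      ggplot2::aes(x = .data$gm_min, xend = .data$gm_max,
                   y = .data$upper, yend = .data$upper),
      colour = "gold", inherit.aes = FALSE
    ) +
    ggplot2::geom_segment(
      data = bands,
      ggplot2::aes(x = .data$gm_min, xend = .data$gm_max,
                   y = .data$lower, yend = .data$lower),
      colour = "gold", inherit.aes = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(up = "forestgreen", down = "red", ns = "grey60")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Geometric mean of counts", y = "log2 fold change (B/A)",
                  colour = "Call") +
    ggplot2::theme_minimal()
}
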