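#' Read-length filter for footprint preprocessing
#'
#' Ribosome footprints shorter than a minimum length carry too little
#' information to map reliably and are removed before quantification. The
#' default minimum of 25 nt keeps reads of exactly 25 nt and longer.
#'
#' @param read_length Integer vector of read lengths (nt).
#' @param min_length Minimum retained length (nt); default 25.
#' @return Logical vector: `TRUE` where the read is kept.
#' @examples
#' length_filter(c(20, 24, 25, 30))
#' @export
length_filter <- function(read_length, min_length = 25L) {
  if (any(read_length < 0, na.rm = TRUE)) abort("Read lengths must be non-negative.")
  read_length >= min_length
}

# Constructor: canonical column order, class, and metadata attribute.
new_end_count_store <- function(counts, meta) {
  counts <- counts |>
    select("transcript_id", "read_length", "position", "end", "ambiguity", "count") |>
    arrange(
      .data$transcript_id, .data$read_length, .data$end,
      .data$ambiguity, .data$position
    )
  structure(
    counts,
    meta = meta,
    class = c("end_count_store", class(tibble()))
  )
}

#' Metadata of an end-count store
#'
#' @param store An `end_count_store`.
#' @return A list with `sample_id`, `sequence_type`, `total_retained_reads`,
#'   `min_read_length`, `assembly` and a `skipped` tally of discarded
#'   alignments.
#' @export
store_meta <- function(store) {
  if (!inherits(store, "end_count_store")) abort("Not an end_count_store.")
  attr(store, "meta")
}

#' @export
as_tibble.end_count_store <- function(x, ...) {
  attr(x, "meta") <- NULL
  class(x) <- setdiff(class(x), "end_count_store")
  as_tibble(x, ...)
}

#' @export
print.end_count_store <- function(x, ...) {
  m <- store_meta(x)
  cat(sprintf(
    "<end_count_store> sample '%s' (%s): %d retained reads, %d transcripts, min length %d\n",
    m$sample_id, m$sequence_type, m$total_retained_reads,
    dplyr::n_distinct(x$transcript_id), m$min_read_length
  ))
  NextMethod()
}

# Aligned query length from a CIGAR string: query-consuming operations
# excluding soft clips (M, I, =, X).
cigar_query_length <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  purrr::map_int(ops, function(m) {
    keep <- m[, 3] %in% c("M", "I", "=", "X")
    as.integer(sum(as.numeric(m[keep, 2])))
  })
}

#' Quantify transcriptome alignments into an end-count store
#'
#' Reduces a SAM/BAM file of transcriptome-aligned reads to per-transcript,
#' per-readlength counts of 5' and 3' read-end positions. Each retained
#' alignment contributes one count to its 5'-end record and one to its 3'-end
#' record (3' position = 5' position + read length - 1). A read for which the
#' aligner reported more than one alignment (secondary flag or repeated query
#' name) is counted once per distinct location under `ambiguity =
#' "ambiguous"`; unique alignments are `"unambiguous"`. Unmapped reads,
#' reverse-strand alignments (antisense to the mRNA), reads shorter than
#' `min_length`, alignments to transcripts absent from the reference, and
#' alignments extending past the transcript end are discarded and tallied in
#' the `skipped` metadata.
#'
#' @param path SAM or BAM file of transcriptome alignments (any sort order).
#' @param reference A `ribo_reference` the alignments were made against.
#' @param min_length Minimum retained read length (nt); default 25.
#' @param sample_id Sample label; defaults to the file name.
#' @param sequence_type `"riboseq"` or `"rnaseq"`.
#' @return An `end_count_store`: a tibble of
#'   (`transcript_id`, `read_length`, `position`, `end`, `ambiguity`,
#'   `count`) with metadata available via [store_meta()].
#' @export
quantify_alignments <- function(path, reference, min_length = 25L,
                                sample_id = NULL, sequence_type = "riboseq") {
  stopifnot_reference(reference)
  sequence_type <- match_arg2(sequence_type, c("riboseq", "rnaseq"))
  if (!file.exists(path)) abort(sprintf("Alignment file not found: %s", path))
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)

  bam_path <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  aln <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam_path),
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")
    )
  )[[1]]

  reads <- tibble(
    qname = aln$qname,
    flag = aln$flag,
    transcript_id = as.character(aln$rname),
    pos = aln$pos,
    cigar = aln$cigar
  )
  skipped <- list(unmapped = 0L, reverse_strand = 0L, short = 0L,
                  unknown_transcript = 0L, out_of_bounds = 0L)

  mapped <- !bitwAnd(reads$flag, 4L) & !is.na(reads$pos)
  skipped$unmapped <- sum(!mapped)
  reads <- reads[mapped, ]

  fwd <- !bitwAnd(reads$flag, 16L)
  skipped$reverse_strand <- sum(!fwd)
  reads <- reads[fwd, ]

  if (nrow(reads) > 0) {
    reads$read_length <- cigar_query_length(reads$cigar)
  } else {
    reads$read_length <- integer()
  }
  keep <- length_filter(reads$read_length, min_length)
  skipped$short <- sum(!keep)
  reads <- reads[keep, ]

  known <- reads$transcript_id %in% reference$transcript_id
  if (any(!known)) {
    unknown <- unique(reads$transcript_id[!known])
    inform(sprintf(
      "Skipped %d alignment(s) to %d transcript(s) absent from the reference (e.g. %s).",
      sum(!known), length(unknown), unknown[1]
    ))
  }
  skipped$unknown_transcript <- sum(!known)
  reads <- reads[known, ]

  # ambiguity: >1 reported alignment for the query name; count each distinct
  # location once
  reads <- reads |>
    group_by(.data$qname) |>
    mutate(ambiguous = n() > 1 | any(bitwAnd(.data$flag, 256L) > 0)) |>
    ungroup() |>
    distinct(.data$qname, .data$transcript_id, .data$pos, .data$read_length,
             .keep_all = TRUE)

  reads <- left_join(
    reads,
    select(reference, "transcript_id", tx_length = "length"),
    by = "transcript_id"
  )
  in_bounds <- reads$pos >= 1L & (reads$pos + reads$read_length - 1L) <= reads$tx_length
  skipped$out_of_bounds <- sum(!in_bounds)
  reads <- reads[in_bounds, ]

  counts <- bind_rows(
    reads |> mutate(end = "five_prime", position = .data$pos),
    reads |> mutate(end = "three_prime", position = .data$pos + .data$read_length - 1L)
  ) |>
    mutate(ambiguity = if_else(.data$ambiguous, "ambiguous", "unambiguous")) |>
    count(.data$transcript_id, .data$read_length, .data$position,
          .data$end, .data$ambiguity, name = "count")

  meta <- list(
    sample_id = sample_id,
    sequence_type = sequence_type,
    total_retained_reads = nrow(reads),
    min_read_length = as.integer(min_length),
    assembly = assembly_tag(reference),
    skipped = skipped
  )
  new_end_count_store(counts, meta)
}

#' Merge end-count stores
#'
#' Record-wise sum of several stores built against the same reference, e.g.
#' to aggregate many ribosome profiling samples into one track. Metadata
#' totals are summed; a mismatch in assembly tags is a hard error.
#'
#' @param stores A list of `end_count_store` objects (a single store is
#'   returned unchanged).
#' @return A merged `end_count_store`.
#' @export
merge_stores <- function(stores) {
  if (inherits(stores, "end_count_store")) return(stores)
  if (length(stores) == 0) abort("Nothing to merge.")
  if (!all(purrr::map_lgl(stores, inherits, "end_count_store"))) {
    abort("All elements must be end_count_store objects.")
  }
  if (length(stores) == 1) return(stores[[1]])
  metas <- purrr::map(stores, store_meta)
  tags <- unique(purrr::map_chr(metas, "assembly"))
  if (length(tags) > 1) abort("Cannot merge stores built against different references.")
  counts <- purrr::map(stores, as_tibble) |>
    bind_rows() |>
    group_by(.data$transcript_id, .data$read_length, .data$position,
             .data$end, .data$ambiguity) |>
    summarise(count = sum(.data$count), .groups = "drop")
  types <- unique(purrr::map_chr(metas, "sequence_type"))
  skipped_names <- names(metas[[1]]$skipped)
  meta <- list(
    sample_id = paste(purrr::map_chr(metas, "sample_id"), collapse = "+"),
    sequence_type = if (length(types) == 1) types else "mixed",
    total_retained_reads = sum(purrr::map_int(metas, "total_retained_reads")),
    min_read_length = min(purrr::map_int(metas, "min_read_length")),
    assembly = tags,
    skipped = setNames(
      lapply(skipped_names, function(nm) {
        sum(purrr::map_int(metas, function(m) m$skipped[[nm]] %||% 0L))
      }),
      skipped_names
    )
  )
  new_end_count_store(counts, meta)
}

STORE_FORMAT_TAG <- "#end_count_store"
STORE_FORMAT_VERSION <- "v1"

#' Write / read an end-count store
#'
#' The on-disk format is a single text file: one header line carrying a
#' format tag, a version, and the store metadata as JSON, followed by a
#' tab-separated count table with columns `transcript_id`, `read_length`,
#' `position`, `end`, `ambiguity`, `count`. The format is documented in the
#' README so that other languages can read it. Write then read is the
#' identity on counts and metadata.
#'
#' @param store An `end_count_store`.
#' @param path File path (conventionally `.store`).
#' @return `write_store()` returns `path` invisibly; `read_store()` returns
#'   the store.
#' @export
write_store <- function(store, path) {
  meta <- store_meta(store)
  header <- paste(
    STORE_FORMAT_TAG, STORE_FORMAT_VERSION,
    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
    sep = "\t"
  )
  body <- readr::format_tsv(as_tibble(store))
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  if (!file.exists(path)) abort(sprintf("Store file not found: %s", path))
  header <- readLines(path, n = 1)
  parts <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3 || parts[1] != STORE_FORMAT_TAG) {
    abort(sprintf("Not an end_count_store file: %s", path))
  }
  if (parts[2] != STORE_FORMAT_VERSION) {
    abort(sprintf(
      "Store version '%s' not supported (expected '%s'); re-run quantification to migrate.",
      parts[2], STORE_FORMAT_VERSION
    ))
  }
  meta <- jsonlite::fromJSON(paste(parts[-(1:2)], collapse = "\t"))
  meta$skipped <- as.list(meta$skipped)
  counts <- readr::read_tsv(
    path,
    skip = 1,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      read_length = readr::col_integer(),
      position = readr::col_integer(),
      end = readr::col_character(),
      ambiguity = readr::col_character(),
      count = readr::col_integer()
    ),
    progress = FALSE
  )
  new_end_count_store(counts, meta)
}

# Apply an ambiguity mode to a store's records.
filter_ambiguity <- function(counts, ambiguity_mode) {
  ambiguity_mode <- match_arg2(ambiguity_mode, c("unambiguous", "ambiguous", "both"))
  if (ambiguity_mode == "both") counts else filter(counts, .data$ambiguity == ambiguity_mode)
}
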