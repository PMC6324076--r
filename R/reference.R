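#' Load a transcriptome reference from FASTA and GTF
#'
#' Reads transcript sequences from a FASTA file and coding-region annotation
#' from a GTF file, and projects genomic CDS features through the exon
#' structure into transcript coordinates. The result is the coordinate frame
#' for every downstream analysis: positions are 1-based, inclusive, in
#' transcript space.
#'
#' `cds_start` is the first nucleotide of the start codon and `cds_stop` the
#' first nucleotide of the stop codon. GTF dialects differ on whether CDS
#' features include the stop codon (Gencode excludes it); both give CDS
#' feature lengths divisible by three, so the convention is resolved by
#' checking the transcript sequence for a stop codon at the two candidate
#' positions.
#'
#' @param fasta Path to a transcriptome FASTA file. Sequence IDs (first
#'   whitespace-delimited token) must match GTF `transcript_id` attributes.
#' @param gtf Path to a GTF annotation with `exon` and `CDS` features
#'   carrying `transcript_id` attributes; `gene_name` falls back to
#'   `gene_id`.
#'
#' @return A tibble of class `ribo_reference` with one row per FASTA record:
#'   `transcript_id`, `gene_name`, `sequence`, `length`, `cds_start`,
#'   `cds_stop` (the last two `NA` for non-coding transcripts).
#'
#' @details Transcripts whose annotated CDS length is not divisible by three,
#'   or whose CDS cannot be projected through the exons, are kept but marked
#'   non-coding with a warning. A GTF transcript with no FASTA sequence is a
#'   hard error naming the ID.
#'
#' @examples
#' \dontrun{
#' sim <- simulate_transcriptome(simulation_config(n_transcripts = 3), tempdir())
#' ref <- read_reference(sim$fasta, sim$gtf)
#' }
#' @export
read_reference <- function(fasta, gtf) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- stringr::str_split_i(names(seqs), "\\s+", 1)
  if (anyDuplicated(ids)) abort("Duplicate sequence IDs in FASTA.")
  seq_chr <- toupper(as.character(seqs))
  names(seq_chr) <- ids

  ann <- as_tibble(as.data.frame(rtracklayer::import(gtf, format = "gtf")))
  if (!"transcript_id" %in% names(ann)) {
    abort("GTF carries no transcript_id attributes.")
  }
  if (!"gene_name" %in% names(ann)) ann$gene_name <- NA_character_
  if (!"gene_id" %in% names(ann)) ann$gene_id <- NA_character_
  ann <- ann |>
    filter(.data$type %in% c("exon", "CDS"), !is.na(.data$transcript_id)) |>
    mutate(
      strand = as.character(.data$strand),
      gene_name = dplyr::coalesce(.data$gene_name, .data$gene_id, .data$transcript_id)
    ) |>
    select("transcript_id", "gene_name", "type", "start", "end", "strand")

  missing <- setdiff(unique(ann$transcript_id), ids)
  if (length(missing) > 0) {
    abort(sprintf(
      "Annotated transcript(s) missing from FASTA: %s",
      paste(missing, collapse = ", ")
    ))
  }

  gene_of <- ann |>
    distinct(.data$transcript_id, .data$gene_name) |>
    distinct(.data$transcript_id, .keep_all = TRUE)

  cds_tbl <- purrr::map(ids, function(id) {
    feats <- filter(ann, .data$transcript_id == id)
    project_cds(id, seq_chr[[id]], feats)
  }) |> bind_rows()

  out <- tibble(
    transcript_id = ids,
    sequence = unname(seq_chr),
    length = unname(nchar(seq_chr))
  ) |>
    left_join(gene_of, by = "transcript_id") |>
    mutate(gene_name = dplyr::coalesce(.data$gene_name, .data$transcript_id)) |>
    left_join(cds_tbl, by = "transcript_id") |>
    select("transcript_id", "gene_name", "sequence", "length", "cds_start", "cds_stop")

  class(out) <- c("ribo_reference", class(out))
  out
}

# Project a transcript's genomic CDS features into transcript coordinates by
# walking its exons in transcript order. Returns one row with cds_start /
# cds_stop (first nt of start / stop codon), NA when non-coding or invalid.
project_cds <- function(id, sequence, feats) {
  none <- tibble(transcript_id = id, cds_start = NA_integer_, cds_stop = NA_integer_)
  cds <- filter(feats, .data$type == "CDS")
  if (nrow(cds) == 0) return(none)
  exons <- filter(feats, .data$type == "exon")
  if (nrow(exons) == 0) {
    warn(sprintf("Transcript %s has CDS but no exon features; marked non-coding.", id))
    return(none)
  }
  strand <- exons$strand[1]
  exons <- if (strand == "-") arrange(exons, desc(.data$start)) else arrange(exons, .data$start)
  width <- exons$end - exons$start + 1L
  before <- cumsum(width) - width

  to_tx <- function(g) {
    hit <- which(g >= exons$start & g <= exons$end)
    if (length(hit) == 0) return(NA_integer_)
    hit <- hit[1]
    if (strand == "-") {
      before[hit] + (exons$end[hit] - g + 1L)
    } else {
      before[hit] + (g - exons$start[hit] + 1L)
    }
  }

  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    warn(sprintf(
      "Transcript %s: CDS length %d not divisible by 3; marked non-coding.",
      id, cds_len
    ))
    return(none)
  }
  g_first <- if (strand == "-") max(cds$end) else min(cds$start)
  g_last <- if (strand == "-") min(cds$start) else max(cds$end)
  t_first <- to_tx(g_first)
  t_last <- to_tx(g_last)
  if (is.na(t_first) || is.na(t_last) || t_last <= t_first) {
    warn(sprintf("Transcript %s: CDS not resolvable through exons; marked non-coding.", id))
    return(none)
  }

  len <- nchar(sequence)
  codon_at <- function(p) {
    if (is.na(p) || p < 1L || p + 2L > len) return(NA_character_)
    substr(sequence, p, p + 2L)
  }
  stops <- c("TAA", "TAG", "TGA")
  # stop codon excluded from CDS features (Gencode) vs included
  cds_stop <- if (isTRUE(codon_at(t_last + 1L) %in% stops)) {
    t_last + 1L
  } else if (isTRUE(codon_at(t_last - 2L) %in% stops)) {
    t_last - 2L
  } else {
    t_last + 1L
  }
  cds_start <- as.integer(t_first)
  cds_stop <- as.integer(cds_stop)
  ok <- cds_start >= 1L && cds_start < cds_stop && cds_stop <= len - 2L &&
    (cds_stop - cds_start) %% 3L == 0L
  if (!ok) {
    warn(sprintf("Transcript %s: projected CDS coordinates invalid; marked non-coding.", id))
    return(none)
  }
  tibble(transcript_id = id, cds_start = cds_start, cds_stop = cds_stop)
}

#' Look up the transcripts of a gene
#'
#' Returns all transcript IDs annotated with a gene name (or gene ID); the
#' caller chooses among isoforms.
#'
#' @param reference A `ribo_reference`.
#' @param gene Gene name to look up (exact match).
#' @return Character vector of transcript IDs (possibly empty).
#' @export
gene_transcripts <- function(reference, gene) {
  stopifnot_reference(reference)
  reference |>
    filter(.data$gene_name == gene) |>
    pull("transcript_id")
}

#' Three-frame ORF architecture of a transcript
#'
#' Scans all three reading frames of a transcript sequence for AUG start
#' codons and UAA/UAG/UGA stop codons. Positions are 1-based and refer to the
#' first nucleotide of the codon; a position `p` lies in frame
#' `(p - 1) mod 3`. Codons containing N are neither starts nor stops.
#'
#' @param x A `ribo_reference` (with `transcript_id` naming the row) or a
#'   single nucleotide sequence string (DNA or RNA alphabet).
#' @param transcript_id Transcript to scan when `x` is a reference.
#' @return A tibble with columns `frame` (0/1/2), `kind` (`"start"` or
#'   `"stop"`), and `position`, sorted by frame then position.
#' @examples
#' orf_architecture("ATGTAA")
#' @export
orf_architecture <- function(x, transcript_id = NULL) {
  if (inherits(x, "ribo_reference")) {
    if (is.null(transcript_id)) abort("Supply `transcript_id` with a reference.")
    row <- filter(x, .data$transcript_id == !!transcript_id)
    if (nrow(row) == 0) abort(sprintf("Unknown transcript '%s'.", transcript_id))
    seq <- row$sequence[1]
  } else {
    seq <- x
  }
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("Sequence must be a single non-empty string.")
  }
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n < 3) {
    return(tibble(frame = integer(), kind = character(), position = integer()))
  }
  pos <- seq_len(n - 2L)
  codon <- stringr::str_sub(seq, pos, pos + 2L)
  tibble(position = pos, codon = codon) |>
    filter(.data$codon %in% c("ATG", "TAA", "TAG", "TGA")) |>
    mutate(
      frame = position_frame(.data$position),
      kind = if_else(.data$codon == "ATG", "start", "stop")
    ) |>
    select("frame", "kind", "position") |>
    arrange(.data$frame, .data$position)
}

#' Write a reference manifest
#'
#' Writes a JSON manifest listing `transcript_id`, `gene_name`, `length`,
#' `cds_start` and `cds_stop` for every transcript, for inspection or use by
#' other tools.
#'
#' @param reference A `ribo_reference`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference_manifest <- function(reference, path) {
  stopifnot_reference(reference)
  reference |>
    select("transcript_id", "gene_name", "length", "cds_start", "cds_stop") |>
    jsonlite::write_json(path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}
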