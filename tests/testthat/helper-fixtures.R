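# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small end-to-end simulation reused across modules: 6 transcripts, 20k reads,
# delta = 12 for all lengths, p = 0.9.
basic_fixture <- function() {
  with_fixture("basic", function() {
    dir <- tempfile("sim_basic_")
    cfg <- simulation_config(n_transcripts = 6L, n_reads = 20000L, seed = 42L)
    sim <- simulate_transcriptome(cfg, dir)
    fp <- simulate_footprints(sim$reference, cfg, dir)
    ref <- read_reference(sim$fasta, sim$gtf)
    store <- quantify_alignments(fp$sam, ref)
    offsets <- infer_offsets(
      metagene_profile(store, ref, end = "five_prime"),
      metagene_profile(store, ref, end = "three_prime")
    )
    list(dir = dir, cfg = cfg, sim = sim, fp = fp, ref = ref,
         store = store, offsets = offsets)
  })
}

# Hand-built reference for unit tests that need exact control.
toy_reference <- function(sequence, cds_start = NA_integer_,
                          cds_stop = NA_integer_, id = "TX1", gene = "GENE1") {
  ref <- tibble::tibble(
    transcript_id = id, gene_name = gene, sequence = sequence,
    length = nchar(sequence),
    cds_start = as.integer(cds_start), cds_stop = as.integer(cds_stop)
  )
  class(ref) <- c("ribo_reference", class(ref))
  ref
}

# Hand-built end-count store over a toy reference.
toy_store <- function(counts, reference, total = NULL, sequence_type = "riboseq") {
  counts <- tibble::as_tibble(counts)
  if (is.null(total)) {
    total <- sum(counts$count[counts$end == "five_prime"])
  }
  meta <- list(
    sample_id = "toy", sequence_type = sequence_type,
    total_retained_reads = total, min_read_length = 25L,
    assembly = ribotally:::assembly_tag(reference),
    skipped = list(unmapped = 0L, reverse_strand = 0L, short = 0L,
                   unknown_transcript = 0L, out_of_bounds = 0L)
  )
  ribotally:::new_end_count_store(counts, meta)
}

# Minimal SAM writer for hand-crafted alignment cases.
write_toy_sam <- function(path, reference, reads = NULL) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$transcript_id, reference$length)
  )
  body <- character()
  if (!is.null(reads) && nrow(reads) > 0) {
    reads <- tibble::as_tibble(reads)
    if (is.null(reads$flag)) reads$flag <- 0L
    if (is.null(reads$cigar)) reads$cigar <- paste0(reads$len, "M")
    body <- sprintf(
      "%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t*",
      reads$qname, reads$flag, reads$rname, reads$pos, reads$cigar,
      strrep("A", reads$len)
    )
  }
  writeLines(c(header, body), path)
  path
}

# Synthetic metagene profile with spikes at given relative positions.
toy_metagene <- function(read_length, rel, count, end, window = 30L) {
  grid <- tidyr::expand_grid(
    read_length = unique(read_length),
    rel_pos = seq.int(-window, window)
  )
  spikes <- tibble::tibble(read_length = read_length, rel_pos = rel, count = count)
  out <- dplyr::left_join(grid, spikes, by = c("read_length", "rel_pos"))
  out$count[is.na(out$count)] <- 0L
  structure(out, anchor = "start_codon", end = end, window = as.integer(window),
            class = c("metagene_profile", class(tibble::tibble())))
}
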