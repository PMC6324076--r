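STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Simulation configuration
#'
#' Collects the parameters of the toy transcriptome / footprint simulator.
#' The simulator exists so that every analysis in the package can be tested
#' against known truth: transcripts with known CDS coordinates, reads with a
#' known per-readlength A-site distance from the 5' end, a known in-frame
#' fraction, and optional nested ORFs and fold changes.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_codons Range (min, max) of sense codons per CDS (start codon
#'   included, stop codon extra).
#' @param utr5,utr3 Ranges (min, max) of UTR lengths in nt. Defaults leave
#'   room for a 100-nt metagene window on both sides of the start codon.
#' @param read_lengths Footprint lengths to simulate (default 25:35 nt).
#' @param length_probs Probabilities over `read_lengths` (default a peaked
#'   distribution centred near 29 nt, the canonical footprint size).
#' @param asite_offset True A-site distance from the 5' end, delta(L): a
#'   scalar, or a vector named by read length. Default 12 nt.
#' @param in_frame_fraction Probability p that a footprint's A-site falls on
#'   its sampled codon's first position; the remainder is split evenly
#'   between +1 and +2 nt (must lie in \[1/3, 1\]).
#' @param initiation_boost Sampling weight multiplier for the initiation
#'   position (A-site on codon 2 while the start codon sits in the P-site),
#'   producing the initiation peak that offset calibration relies on.
#' @param expression_sdlog Log-normal sd of per-transcript expression.
#' @param n_reads Reads per simulated sample.
#' @param ambiguous_fraction Fraction of reads given a second (secondary)
#'   alignment at a random position, to exercise ambiguity handling.
#' @param nested_orf `NULL`, or a list with `transcript` (index), `frame_shift`
#'   (1 or 2), `start_codon` (codon index within the CDS where the nested ORF
#'   begins), `length_codons`, and `density` (sampling weight of nested-frame
#'   positions relative to main-frame codons).
#' @param seed Base seed; each transcript draws from its own derived stream
#'   so earlier transcripts are unchanged when `n_transcripts` grows.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_transcripts = 20L,
                              cds_codons = c(100L, 200L),
                              utr5 = c(110L, 140L),
                              utr3 = c(110L, 140L),
                              read_lengths = 25:35,
                              length_probs = NULL,
                              asite_offset = 12L,
                              in_frame_fraction = 0.9,
                              initiation_boost = 5,
                              expression_sdlog = 1,
                              n_reads = 50000L,
                              ambiguous_fraction = 0,
                              nested_orf = NULL,
                              seed = 1L) {
  if (is.null(length_probs)) {
    length_probs <- stats::dnorm(read_lengths, mean = 29, sd = 2)
  }
  length_probs <- length_probs / sum(length_probs)
  if (length(length_probs) != length(read_lengths)) {
    abort("`length_probs` must match `read_lengths`.")
  }
  if (in_frame_fraction < 1 / 3 || in_frame_fraction > 1) {
    abort("`in_frame_fraction` must lie in [1/3, 1].")
  }
  delta <- asite_offset
  if (is.null(names(delta))) {
    delta <- setNames(rep_len(as.integer(delta), length(read_lengths)),
                      as.character(read_lengths))
  }
  if (!all(as.character(read_lengths) %in% names(delta))) {
    abort("`asite_offset` must cover every read length.")
  }
  if (any(delta[as.character(read_lengths)] >= read_lengths)) {
    abort("A-site offsets must be smaller than the read length.")
  }
  if (!is.null(nested_orf)) {
    need <- c("transcript", "frame_shift", "start_codon", "length_codons", "density")
    if (!all(need %in% names(nested_orf))) {
      abort(sprintf("`nested_orf` needs fields: %s.", paste(need, collapse = ", ")))
    }
    if (!nested_orf$frame_shift %in% 1:2) abort("`nested_orf$frame_shift` must be 1 or 2.")
  }
  structure(
    list(
      n_transcripts = as.integer(n_transcripts),
      cds_codons = as.integer(cds_codons), utr5 = as.integer(utr5),
      utr3 = as.integer(utr3),
      read_lengths = as.integer(read_lengths), length_probs = length_probs,
      asite_offset = delta, in_frame_fraction = in_frame_fraction,
      initiation_boost = initiation_boost,
      expression_sdlog = expression_sdlog, n_reads = as.integer(n_reads),
      ambiguous_fraction = ambiguous_fraction, nested_orf = nested_orf,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# sample() treats a length-1 numeric as 1:n; these never do
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
sample_one <- function(x) sample_vec(x, 1L)

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build one CDS (start..sense codons..stop) honouring an optional nested ORF
# in a shifted frame: nested ATG at its start, a stop at its end, no internal
# stops in either the main frame or the nested frame's interval. Rejection
# sampled; gives up (without the sequence-level nested ORF) after max_tries.
make_cds <- function(n_sense, nested = NULL, max_tries = 300L) {
  for (try in seq_len(max_tries)) {
    codons <- c("ATG", sample(SENSE_CODONS, n_sense - 1L, replace = TRUE),
                sample_one(STOP_CODONS))
    cds <- paste(codons, collapse = "")
    if (is.null(nested)) return(cds)
    # nested ORF occupies [nstart, nstart + 3*len - 1] in frame-shifted space
    nstart <- 3L * (nested$start_codon - 1L) + nested$frame_shift + 1L
    nstop <- nstart + 3L * (nested$length_codons - 1L)
    if (nstop + 2L > nchar(cds) - 3L) abort("Nested ORF does not fit in the CDS.")
    substr(cds, nstart, nstart + 2L) <- "ATG"
    substr(cds, nstop, nstop + 2L) <- sample_one(STOP_CODONS)
    main_ok <- !any(purrr::map_lgl(seq_len(n_sense - 1L), function(k) {
      substr(cds, 3L * k + 1L, 3L * k + 3L) %in% STOP_CODONS
    })) && substr(cds, 1L, 3L) == "ATG"
    nested_ok <- !any(purrr::map_lgl(seq_len(nested$length_codons - 1L) - 1L, function(j) {
      p <- nstart + 3L * j
      p < nstop && substr(cds, p, p + 2L) %in% STOP_CODONS
    }))
    if (main_ok && nested_ok) return(cds)
  }
  warn("Could not realize the nested ORF at sequence level; densities still simulated.")
  paste(c("ATG", sample(SENSE_CODONS, n_sense - 1L, replace = TRUE),
          sample_one(STOP_CODONS)), collapse = "")
}

#' Simulate a toy transcriptome
#'
#' Writes a transcriptome FASTA, a matching GTF (exon + CDS features,
#' stop codon excluded from CDS features as in Gencode; a mix of single- and
#' two-exon genes on both strands so coordinate projection is exercised), and
#' a JSON truth manifest. The returned truth table is itself a
#' `ribo_reference`, so downstream functions can run against simulator truth
#' without re-parsing the files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `fasta`, `gtf`, `manifest` (paths), `reference` (the truth
#'   `ribo_reference`), `nested_orf` (truth tibble or `NULL`).
#' @export
simulate_transcriptome <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  nested_truth <- NULL
  records <- purrr::map(seq_len(config$n_transcripts), function(i) {
    withr::with_seed(config$seed + 7919L * i, {
      u5 <- sample_one(seq.int(config$utr5[1], config$utr5[2]))
      u3 <- sample_one(seq.int(config$utr3[1], config$utr3[2]))
      n_sense <- sample_one(seq.int(config$cds_codons[1], config$cds_codons[2]))
      nested <- if (!is.null(config$nested_orf) && config$nested_orf$transcript == i) {
        config$nested_orf
      }
      cds <- make_cds(n_sense, nested)
      sequence <- paste0(random_bases(u5), cds, random_bases(u3))
      cds_start <- u5 + 1L
      cds_stop <- u5 + 3L * n_sense + 1L
      list(
        i = i, sequence = sequence, length = nchar(sequence),
        cds_start = cds_start, cds_stop = cds_stop,
        n_sense = n_sense,
        nested = if (!is.null(nested)) {
          nstart <- cds_start + 3L * (nested$start_codon - 1L) + nested$frame_shift
          tibble(
            transcript_id = sprintf("SIMT%04d", i),
            nested_start = nstart,
            nested_end = nstart + 3L * nested$length_codons - 1L,
            frame = position_frame(nstart),
            density = nested$density
          )
        }
      )
    })
  })

  truth <- purrr::map(records, function(r) {
    tibble(
      transcript_id = sprintf("SIMT%04d", r$i),
      gene_name = sprintf("SIMG%04d", r$i),
      sequence = r$sequence, length = r$length,
      cds_start = r$cds_start, cds_stop = r$cds_stop
    )
  }) |> bind_rows()
  class(truth) <- c("ribo_reference", class(tibble()))
  nested_truth <- purrr::map(records, "nested") |> purrr::compact()
  nested_truth <- if (length(nested_truth) > 0) bind_rows(nested_truth) else NULL

  fasta <- file.path(dir, "transcriptome.fa")
  writeLines(
    paste0(">", truth$transcript_id, "\n", truth$sequence),
    fasta
  )

  gtf_lines <- purrr::map(records, function(r) {
    tid <- sprintf("SIMT%04d", r$i)
    gid <- sprintf("SIMG%04d", r$i)
    strand <- if (r$i %% 2L == 0L) "-" else "+"
    two_exon <- r$i %% 3L == 0L
    len <- r$length
    # exon genomic segments, in transcript order
    if (two_exon) {
      w1 <- len %/% 2L
      ex_tx <- list(c(1L, w1), c(w1 + 1L, len))
      widths <- c(w1, len - w1)
    } else {
      ex_tx <- list(c(1L, len))
      widths <- len
    }
    gstart <- 1000L
    gap <- 100L
    exons <- vector("list", length(widths))
    if (strand == "+") {
      at <- gstart
      for (e in seq_along(widths)) {
        exons[[e]] <- c(at, at + widths[e] - 1L)
        at <- at + widths[e] + gap
      }
    } else {
      # transcript order runs high -> low genomic on the minus strand
      total <- sum(widths) + gap * (length(widths) - 1L)
      at <- gstart + total - 1L
      for (e in seq_along(widths)) {
        exons[[e]] <- c(at - widths[e] + 1L, at)
        at <- at - widths[e] - gap
      }
    }
    # transcript pos -> genomic
    to_g <- function(t) {
      for (e in seq_along(widths)) {
        t1 <- ex_tx[[e]][1]
        t2 <- ex_tx[[e]][2]
        if (t >= t1 && t <= t2) {
          return(if (strand == "+") exons[[e]][1] + (t - t1)
                 else exons[[e]][2] - (t - t1))
        }
      }
      stop("unmapped position")
    }
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";', gid, tid, gid)
    seqname <- sprintf("sim_chr%d", r$i)
    fmt <- function(type, lo, hi) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", seqname, type, lo, hi, strand, attrs)
    }
    lines <- purrr::map_chr(exons, ~ fmt("exon", .x[1], .x[2]))
    # CDS features exclude the stop codon (Gencode convention)
    cds_tx <- c(r$cds_start, r$cds_stop - 1L)
    cds_lines <- purrr::map(seq_along(widths), function(e) {
      t1 <- ex_tx[[e]][1]
      t2 <- ex_tx[[e]][2]
      lo <- max(cds_tx[1], t1)
      hi <- min(cds_tx[2], t2)
      if (lo > hi) return(NULL)
      g1 <- to_g(lo)
      g2 <- to_g(hi)
      fmt("CDS", min(g1, g2), max(g1, g2))
    }) |> purrr::compact()
    c(lines, unlist(cds_lines))
  })
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(unlist(gtf_lines), gtf)

  manifest <- file.path(dir, "truth_manifest.json")
  truth |>
    select("transcript_id", "gene_name", "length", "cds_start", "cds_stop") |>
    jsonlite::write_json(manifest, auto_unbox = FALSE, digits = NA, na = "null")

  list(fasta = fasta, gtf = gtf, manifest = manifest,
       reference = truth, nested_orf = nested_truth)
}

#' Simulate ribosome footprint alignments
#'
#' Samples footprints from a simulated transcriptome and writes them as a
#' plain-text SAM file, together with truth tables against which
#' quantification and offset inference can be checked exactly. Per read: a
#' transcript is drawn by expression weight, an A-site codon is drawn over
#' the CDS (codon 2 boosted by `initiation_boost`; nested-ORF positions, if
#' configured, added at their relative density), a phase error of +1/+2 nt is
#' applied with probability `1 - in_frame_fraction`, a read length `L` is
#' drawn, and the 5' end is placed at `A-site - delta(L)`.
#'
#' @param reference A `ribo_reference`, typically the truth table from
#'   [simulate_transcriptome()].
#' @param config The same [simulation_config()].
#' @param dir Output directory.
#' @param sample_id Sample label (also the SAM file stem).
#' @param fold_changes Optional named vector of expression multipliers per
#'   transcript (for two-condition experiments).
#' @param n_reads Override `config$n_reads`.
#' @param seed Override the sampling seed (default `config$seed + 1`); give
#'   different seeds to different samples.
#' @param nested_orf Truth tibble from [simulate_transcriptome()] (or `NULL`);
#'   supplies the positions of nested-frame density.
#' @return A list: `sam` (path), `store` (truth `end_count_store` equal to
#'   what [quantify_alignments()] must produce), `asite_density` (tibble
#'   `transcript_id`, `position`, `count` of true, phase-error-included
#'   A-sites), `expression` (reads drawn per transcript).
#' @export
simulate_footprints <- function(reference, config, dir,
                                sample_id = "sim_sample",
                                fold_changes = NULL, n_reads = NULL,
                                seed = NULL, nested_orf = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  stopifnot_reference(reference)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_reads <- n_reads %||% config$n_reads
  seed <- seed %||% (config$seed + 1L)
  p <- config$in_frame_fraction
  delta <- config$asite_offset

  coding <- filter(reference, !is.na(.data$cds_start))
  n_tx <- nrow(coding)
  alloc <- withr::with_seed(seed, {
    w <- stats::rlnorm(n_tx, meanlog = 0, sdlog = config$expression_sdlog)
    if (!is.null(fold_changes)) {
      fc <- fold_changes[coding$transcript_id]
      fc[is.na(fc)] <- 1
      w <- w * fc
    }
    as.integer(rmultinom(1, n_reads, w)[, 1])
  })

  all_reads <- purrr::map(seq_len(n_tx), function(i) {
    r <- alloc[i]
    if (r == 0) return(NULL)
    tx <- coding[i, ]
    withr::with_seed(seed + 7919L * i, {
      m <- (tx$cds_stop - tx$cds_start) %/% 3L  # sense codons
      cand <- tx$cds_start + 3L * (seq.int(2L, m) - 1L)
      wts <- rep(1, length(cand))
      wts[1] <- config$initiation_boost
      if (!is.null(nested_orf) && tx$transcript_id %in% nested_orf$transcript_id) {
        no <- filter(nested_orf, .data$transcript_id == tx$transcript_id)
        npos <- seq.int(no$nested_start, no$nested_end - 2L, by = 3L)
        cand <- c(cand, npos)
        wts <- c(wts, rep(no$density, length(npos)))
      }
      asite <- sample_vec(cand, r, replace = TRUE, prob = wts)
      shift <- sample(0:2, r, replace = TRUE, prob = c(p, (1 - p) / 2, (1 - p) / 2))
      asite <- asite + shift
      L <- sample_vec(config$read_lengths, r, replace = TRUE, prob = config$length_probs)
      five <- asite - delta[as.character(L)]
      ok <- five >= 1L & five + L - 1L <= tx$length
      tibble(
        transcript_id = tx$transcript_id,
        asite = asite[ok], read_length = L[ok], five = as.integer(five[ok]),
        tx_length = tx$length
      )
    })
  }) |> bind_rows()

  if (nrow(all_reads) == 0) abort("No reads simulated; raise n_reads.")
  all_reads <- all_reads |>
    mutate(qname = sprintf("r%07d", row_number()))

  # optional multi-mapping: a second, secondary alignment elsewhere
  n_amb <- floor(config$ambiguous_fraction * nrow(all_reads))
  secondary <- NULL
  if (n_amb > 0) {
    secondary <- withr::with_seed(seed + 13L, {
      amb <- head(all_reads, n_amb)
      mutate(amb,
        five = purrr::map2_int(.data$tx_length, .data$read_length,
                               ~ sample.int(.x - .y + 1L, 1L)),
        secondary = TRUE
      )
    })
  }
  primary <- mutate(all_reads, secondary = FALSE)
  aln <- bind_rows(primary, secondary) |>
    mutate(flag = if_else(.data$secondary, 256L, 0L))

  # SAM, coordinate-sorted within the header's reference order
  seq_of <- setNames(reference$sequence, reference$transcript_id)
  aln <- aln |>
    mutate(rorder = match(.data$transcript_id, reference$transcript_id)) |>
    arrange(.data$rorder, .data$five, .data$qname, .data$flag)
  sam <- file.path(dir, paste0(sample_id, ".sam"))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$transcript_id, reference$length)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    aln$qname, aln$flag, aln$transcript_id, aln$five, 42L, aln$read_length,
    substr(seq_of[aln$transcript_id], aln$five, aln$five + aln$read_length - 1L),
    strrep("I", aln$read_length)
  )
  writeLines(c(header, body), sam)

  # truth end-count store: each alignment location once; reads with >1
  # reported alignment are ambiguous at every location
  loc <- aln |>
    group_by(.data$qname) |>
    mutate(ambiguity = if_else(n() > 1, "ambiguous", "unambiguous")) |>
    ungroup() |>
    distinct(.data$qname, .data$transcript_id, .data$five, .data$read_length,
             .keep_all = TRUE)
  counts <- bind_rows(
    loc |> mutate(end = "five_prime", position = .data$five),
    loc |> mutate(end = "three_prime", position = .data$five + .data$read_length - 1L)
  ) |>
    count(.data$transcript_id, .data$read_length, .data$position,
          .data$end, .data$ambiguity, name = "count")
  meta <- list(
    sample_id = sample_id, sequence_type = "riboseq",
    total_retained_reads = nrow(loc),
    min_read_length = min(config$read_lengths),
    assembly = assembly_tag(reference),
    skipped = list(unmapped = 0L, reverse_strand = 0L, short = 0L,
                   unknown_transcript = 0L, out_of_bounds = 0L)
  )
  store <- new_end_count_store(counts, meta)

  asite_density <- primary |>
    count(.data$transcript_id, position = .data$asite, name = "count") |>
    arrange(.data$transcript_id, .data$position)

  expression <- tibble(transcript_id = coding$transcript_id, reads = alloc)

  list(sam = sam, store = store, asite_density = asite_density,
       expression = expression)
}

#' Simulate a two-condition count experiment
#'
#' Count-level companion to [simulate_footprints()] for differential
#' expression at realistic transcriptome scale: per-transcript means are
#' drawn log-uniformly, counts are Poisson in each condition, and a chosen
#' set of transcripts gets a common fold change in condition B.
#'
#' @param n_transcripts Number of transcripts (default 3000).
#' @param lambda_range Range of per-transcript Poisson means, sampled
#'   log-uniformly (default 20 to 2000).
#' @param n_spiked Number of transcripts given the fold change (default 0).
#' @param fold_change Expression multiplier in condition B for spiked
#'   transcripts (default 4).
#' @param library_size_factor Multiplier on condition B means, to emulate
#'   unequal sequencing depth (default 1).
#' @param seed RNG seed.
#' @return A list: `counts_a`, `counts_b` (tibbles `transcript_id`, `count`),
#'   `spiked` (IDs), `lambda`.
#' @export
simulate_de_counts <- function(n_transcripts = 3000L, lambda_range = c(20, 2000),
                               n_spiked = 0L, fold_change = 4,
                               library_size_factor = 1, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("DE%05d", seq_len(n_transcripts))
    lambda <- 10^runif(n_transcripts, log10(lambda_range[1]), log10(lambda_range[2]))
    spiked <- if (n_spiked > 0) sample(ids, n_spiked) else character()
    fc <- if_else(ids %in% spiked, fold_change, 1)
    list(
      counts_a = tibble(transcript_id = ids, count = rpois(n_transcripts, lambda)),
      counts_b = tibble(transcript_id = ids,
                        count = rpois(n_transcripts, lambda * fc * library_size_factor)),
      spiked = spiked,
      lambda = setNames(lambda, ids)
    )
  })
}
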