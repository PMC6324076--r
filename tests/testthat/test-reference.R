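# Exon-walk projection oracle: expected transcript CDS coordinates in the
# cases below were derived by hand-enumerating the exon walk, independently
# of the implementation.

write_fasta <- function(path, ids, seqs) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

gtf_line <- function(seqname, type, start, end, strand, tid, gid = "G1", gname = "GENE1") {
  sprintf(
    '%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    seqname, type, start, end, strand, gid, tid, gname
  )
}

test_that("genomic CDS features project to transcript coordinates across exons and strands", {
  dir <- withr::local_tempdir()
  # plus strand, two exons: exon1 101-150 (t 1..50), exon2 201-260 (t 51..110)
  seq_plus <- paste0(
    strrep("C", 20), "ATG", strrep("CCC", 15), "TAA", strrep("C", 39)
  )
  # minus strand, two exons in transcript order: 501-560 (t 1..60), 301-340 (t 61..100)
  seq_minus <- paste0(
    strrep("C", 10), "ATG", strrep("CCC", 19), "TAA", strrep("C", 27)
  )
  fasta <- write_fasta(file.path(dir, "ref.fa"), c("TXP", "TXM"),
                       c(seq_plus, seq_minus))
  gtf <- file.path(dir, "ref.gtf")
  writeLines(c(
    gtf_line("chrA", "exon", 101, 150, "+", "TXP"),
    gtf_line("chrA", "exon", 201, 260, "+", "TXP"),
    gtf_line("chrA", "CDS", 121, 150, "+", "TXP"),
    gtf_line("chrA", "CDS", 201, 218, "+", "TXP"),
    gtf_line("chrB", "exon", 301, 340, "-", "TXM", gid = "G2", gname = "GENE2"),
    gtf_line("chrB", "exon", 501, 560, "-", "TXM", gid = "G2", gname = "GENE2"),
    gtf_line("chrB", "CDS", 331, 340, "-", "TXM", gid = "G2", gname = "GENE2"),
    gtf_line("chrB", "CDS", 501, 550, "-", "TXM", gid = "G2", gname = "GENE2")
  ), gtf)

  ref <- read_reference(fasta, gtf)
  expect_s3_class(ref, "ribo_reference")
  plus <- ref[ref$transcript_id == "TXP", ]
  minus <- ref[ref$transcript_id == "TXM", ]
  expect_equal(plus$cds_start, 21L)   # hand oracle: 121 -> 21 through exon 1
  expect_equal(plus$cds_stop, 69L)    # last CDS nt 218 -> t 68; stop excluded
  expect_equal(minus$cds_start, 11L)  # 550 on minus strand -> t 11
  expect_equal(minus$cds_stop, 71L)
  expect_equal(plus$gene_name, "GENE1")
  expect_equal(gene_transcripts(ref, "GENE2"), "TXM")
})

test_that("stop-codon-inclusive CDS features resolve to the same anchor convention", {
  dir <- withr::local_tempdir()
  # single exon 81-140 (t 1..60); CDS genomic 101-130 includes the stop codon
  seq <- paste0(strrep("C", 20), "ATG", strrep("CCC", 8), "TAA", strrep("C", 10))
  fasta <- write_fasta(file.path(dir, "ref.fa"), "TXI", seq)
  gtf <- file.path(dir, "ref.gtf")
  writeLines(c(
    gtf_line("chrC", "exon", 81, 140, "+", "TXI"),
    gtf_line("chrC", "CDS", 101, 130, "+", "TXI")
  ), gtf)
  ref <- read_reference(fasta, gtf)
  expect_equal(ref$cds_start, 21L)
  expect_equal(ref$cds_stop, 48L)  # first nt of the stop codon, not the CDS end
})

test_that("degenerate annotation is handled: non-coding records, bad CDS length, missing sequence", {
  dir <- withr::local_tempdir()
  seq <- strrep("ACGT", 30)
  fasta <- write_fasta(file.path(dir, "ref.fa"), c("TXNC", "TXBAD"),
                       c(seq, seq))
  gtf <- file.path(dir, "ref.gtf")
  writeLines(c(
    gtf_line("chrD", "exon", 1, 120, "+", "TXBAD"),
    gtf_line("chrD", "CDS", 11, 39, "+", "TXBAD")  # 29 nt, not divisible by 3
  ), gtf)
  expect_warning(ref <- read_reference(fasta, gtf), "not divisible by 3")
  expect_true(all(is.na(ref$cds_start)))
  expect_equal(nrow(ref), 2L)  # every FASTA record yields a row
  expect_equal(ref$gene_name[ref$transcript_id == "TXNC"], "TXNC")

  gtf2 <- file.path(dir, "ref2.gtf")
  writeLines(c(
    gtf_line("chrD", "exon", 1, 120, "+", "TXGHOST"),
    gtf_line("chrD", "CDS", 11, 40, "+", "TXGHOST")
  ), gtf2)
  expect_error(read_reference(fasta, gtf2), "TXGHOST")
})

test_that("orf_architecture matches the forced codon cases", {
  arch <- orf_architecture("ATGTAA")
  expect_equal(arch$frame, c(0L, 0L))
  expect_equal(arch$kind, c("start", "stop"))
  expect_equal(arch$position, c(1L, 4L))
  expect_equal(nrow(orf_architecture(strrep("C", 100))), 0L)
  # RNA alphabet and N-containing codons
  expect_equal(orf_architecture("AUGUAA")$position, c(1L, 4L))
  expect_equal(nrow(orf_architecture("ANGTAN")), 0L)
})

test_that("orf_architecture equals a brute-force codon scan on random sequences", {
  orf_oracle <- function(seq) {
    n <- nchar(seq)
    rows <- list()
    for (f in 0:2) {
      p <- f + 1L
      while (p + 2L <= n) {
        cod <- substr(seq, p, p + 2L)
        if (cod == "ATG") rows[[length(rows) + 1]] <- c(f, 1L, p)
        if (cod %in% c("TAA", "TAG", "TGA")) rows[[length(rows) + 1]] <- c(f, 2L, p)
        p <- p + 3L
      }
    }
    if (length(rows) == 0) {
      return(tibble::tibble(frame = integer(), kind = character(), position = integer()))
    }
    m <- do.call(rbind, rows)
    tibble::tibble(
      frame = as.integer(m[, 1]),
      kind = c("start", "stop")[m[, 2]],
      position = as.integer(m[, 3])
    ) |> dplyr::arrange(frame, position)
  }
  withr::with_seed(7, {
    for (i in 1:1000) {
      n <- sample(10:200, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      got <- orf_architecture(seq)
      expect_equal(as.data.frame(got), as.data.frame(orf_oracle(seq)))
    }
  })
  # positions lie in their frame and are strictly increasing within it
  withr::with_seed(8, {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    arch <- orf_architecture(seq)
    expect_true(all((arch$position - 1L) %% 3L == arch$frame))
    by_frame <- split(arch$position, interaction(arch$frame, arch$kind))
    expect_true(all(vapply(by_frame, function(p) !is.unsorted(p, strictly = TRUE), TRUE)))
    expect_true(all(arch$position <= 300 - 2L))
  })
})

test_that("build_reference on simulator output reproduces the simulator truth table", {
  fx <- basic_fixture()
  expect_equal(as.data.frame(fx$ref), as.data.frame(fx$sim$reference))
  # manifest roundtrip
  manifest <- jsonlite::fromJSON(fx$sim$manifest)
  expect_equal(manifest$transcript_id, fx$ref$transcript_id)
  expect_equal(manifest$cds_start, fx$ref$cds_start)
  # annotated start/stop codons appear in the matching frame's architecture
  for (i in seq_len(nrow(fx$ref))) {
    row <- fx$ref[i, ]
    arch <- orf_architecture(row$sequence)
    f <- (row$cds_start - 1L) %% 3L
    starts <- arch$position[arch$frame == f & arch$kind == "start"]
    stops <- arch$position[arch$frame == f & arch$kind == "stop"]
    expect_true(row$cds_start %in% starts)
    expect_true(row$cds_stop %in% stops)
  }
})

test_that("reference manifest export lists every transcript", {
  fx <- basic_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_manifest(fx$ref, path)
  got <- jsonlite::fromJSON(path)
  expect_equal(got$transcript_id, fx$ref$transcript_id)
  expect_equal(got$length, fx$ref$length)
})
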