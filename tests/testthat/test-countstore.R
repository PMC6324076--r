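test_that("length filter keeps reads at or above the minimum length", {
  expect_false(length_filter(24L))
  expect_true(length_filter(25L))
  expect_false(length_filter(0L))
  expect_equal(length_filter(c(20, 25, 30), min_length = 25), c(FALSE, TRUE, TRUE))
  expect_error(length_filter(-1L), "non-negative")
})

test_that("a single alignment yields matching 5' and 3' end records", {
  ref <- toy_reference(strrep("ACGT", 20), cds_start = 9, cds_stop = 69)
  sam <- write_toy_sam(
    withr::local_tempfile(fileext = ".sam"), ref,
    data.frame(qname = "r1", rname = "TX1", pos = 11L, len = 30L)
  )
  store <- quantify_alignments(sam, ref)
  tbl <- tibble::as_tibble(store)
  expect_equal(nrow(tbl), 2L)
  five <- tbl[tbl$end == "five_prime", ]
  three <- tbl[tbl$end == "three_prime", ]
  expect_equal(five$position, 11L)
  expect_equal(three$position, 40L)  # pos + len - 1
  expect_equal(five$read_length, 30L)
  expect_true(all(tbl$ambiguity == "unambiguous"))
  expect_equal(store_meta(store)$total_retained_reads, 1L)
})

test_that("unmapped, antisense, short and unknown-transcript alignments are discarded and tallied", {
  ref <- toy_reference(strrep("ACGT", 20), cds_start = 9, cds_stop = 69)
  sam <- write_toy_sam(
    withr::local_tempfile(fileext = ".sam"), ref,
    data.frame(
      qname = c("keep", "rev", "short", "unmapped"),
      flag = c(0L, 16L, 0L, 4L),
      rname = c("TX1", "TX1", "TX1", "*"),
      pos = c(5L, 5L, 5L, 0L),
      len = c(28L, 28L, 20L, 28L),
      cigar = c("28M", "28M", "20M", "*")
    )
  )
  store <- suppressMessages(quantify_alignments(sam, ref))
  m <- store_meta(store)
  expect_equal(m$total_retained_reads, 1L)
  expect_equal(m$skipped$reverse_strand, 1L)
  expect_equal(m$skipped$short, 1L)
  expect_equal(m$skipped$unmapped, 1L)
})

test_that("an empty alignment file yields an empty store", {
  ref <- toy_reference(strrep("ACGT", 20))
  sam <- write_toy_sam(withr::local_tempfile(fileext = ".sam"), ref)
  store <- quantify_alignments(sam, ref)
  expect_equal(nrow(store), 0L)
  expect_equal(store_meta(store)$total_retained_reads, 0L)
})

test_that("quantification reproduces simulator truth counts exactly", {
  fx <- basic_fixture()
  expect_equal(
    as.data.frame(tibble::as_tibble(fx$store)),
    as.data.frame(tibble::as_tibble(fx$fp$store))
  )
  m <- store_meta(fx$store)
  expect_equal(m$total_retained_reads, store_meta(fx$fp$store)$total_retained_reads)
  # count conservation: 5' totals == 3' totals == retained reads
  tbl <- tibble::as_tibble(fx$store)
  expect_equal(sum(tbl$count[tbl$end == "five_prime"]), m$total_retained_reads)
  expect_equal(sum(tbl$count[tbl$end == "three_prime"]), m$total_retained_reads)
})

test_that("multimapping reads are counted once per location as ambiguous", {
  fx <- basic_fixture()
  cfg <- simulation_config(n_transcripts = 4L, n_reads = 2000L,
                           ambiguous_fraction = 0.2, seed = 9L)
  dir <- withr::local_tempdir()
  sim <- simulate_transcriptome(cfg, dir)
  fp <- simulate_footprints(sim$reference, cfg, dir)
  store <- quantify_alignments(fp$sam, sim$reference)
  expect_equal(
    as.data.frame(tibble::as_tibble(store)),
    as.data.frame(tibble::as_tibble(fp$store))
  )
  tbl <- tibble::as_tibble(store)
  expect_true(any(tbl$ambiguity == "ambiguous"))
  # conservation still holds with ambiguous locations counted
  expect_equal(sum(tbl$count[tbl$end == "five_prime"]),
               store_meta(store)$total_retained_reads)
})

test_that("merging stores is identity with empty, doubles with self, and errors across references", {
  fx <- basic_fixture()
  ref <- fx$ref
  empty_sam <- write_toy_sam(withr::local_tempfile(fileext = ".sam"), ref)
  empty <- quantify_alignments(empty_sam, ref)
  m1 <- merge_stores(list(fx$store, empty))
  expect_equal(as.data.frame(tibble::as_tibble(m1)),
               as.data.frame(tibble::as_tibble(fx$store)))
  m2 <- merge_stores(list(fx$store, fx$store))
  expect_equal(tibble::as_tibble(m2)$count, 2L * tibble::as_tibble(fx$store)$count)
  expect_equal(store_meta(m2)$total_retained_reads,
               2L * store_meta(fx$store)$total_retained_reads)

  other_ref <- toy_reference(strrep("ACGT", 25))
  other_sam <- write_toy_sam(withr::local_tempfile(fileext = ".sam"), other_ref)
  other <- quantify_alignments(other_sam, other_ref)
  expect_error(merge_stores(list(fx$store, other)), "different references")
})

test_that("merging per-sample stores equals quantifying the concatenated alignments", {
  cfg <- simulation_config(n_transcripts = 4L, n_reads = 3000L, seed = 11L)
  dir <- withr::local_tempdir()
  sim <- simulate_transcriptome(cfg, dir)
  ref <- sim$reference
  fps <- lapply(1:3, function(k) {
    simulate_footprints(ref, cfg, dir, sample_id = paste0("s", k), seed = 100L + k)
  })
  merged <- merge_stores(lapply(fps, function(f) {
    quantify_alignments(f$sam, ref, sample_id = "s")
  }))
  # concatenate the three SAM bodies with disambiguated read names
  lines <- lapply(seq_along(fps), function(k) {
    l <- readLines(fps[[k]]$sam)
    body <- l[!startsWith(l, "@")]
    sub("^r", sprintf("s%d_r", k), body)
  })
  header <- readLines(fps[[1]]$sam)
  header <- header[startsWith(header, "@")]
  cat_sam <- file.path(dir, "cat.sam")
  writeLines(c(header, unlist(lines)), cat_sam)
  combined <- quantify_alignments(cat_sam, ref)
  expect_equal(as.data.frame(tibble::as_tibble(merged)),
               as.data.frame(tibble::as_tibble(combined)))
  expect_equal(store_meta(merged)$total_retained_reads,
               store_meta(combined)$total_retained_reads)
})

test_that("length-filtering commutes with quantification", {
  cfg <- simulation_config(n_transcripts = 4L, n_reads = 4000L,
                           read_lengths = 20:32, seed = 13L)
  dir <- withr::local_tempdir()
  sim <- simulate_transcriptome(cfg, dir)
  fp <- simulate_footprints(sim$reference, cfg, dir)
  filtered <- quantify_alignments(fp$sam, sim$reference, min_length = 25L)
  unfiltered <- quantify_alignments(fp$sam, sim$reference, min_length = 20L)
  dropped <- dplyr::filter(tibble::as_tibble(unfiltered), read_length >= 25L)
  expect_equal(
    as.data.frame(tibble::as_tibble(filtered)),
    as.data.frame(dropped)
  )
  expect_true(store_meta(unfiltered)$total_retained_reads >
                store_meta(filtered)$total_retained_reads)
})

test_that("store write/read roundtrip is the identity; foreign and stale files error", {
  fx <- basic_fixture()
  path <- withr::local_tempfile(fileext = ".store")
  write_store(fx$store, path)
  back <- read_store(path)
  expect_equal(as.data.frame(tibble::as_tibble(back)),
               as.data.frame(tibble::as_tibble(fx$store)))
  mb <- store_meta(back)
  mo <- store_meta(fx$store)
  expect_equal(mb$total_retained_reads, mo$total_retained_reads)
  expect_equal(mb$assembly, mo$assembly)
  expect_equal(mb$sample_id, mo$sample_id)

  # empty store roundtrip
  ref <- toy_reference(strrep("ACGT", 20))
  empty <- quantify_alignments(
    write_toy_sam(withr::local_tempfile(fileext = ".sam"), ref), ref
  )
  path2 <- withr::local_tempfile(fileext = ".store")
  write_store(empty, path2)
  expect_equal(nrow(read_store(path2)), 0L)

  junk <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a store", junk)
  expect_error(read_store(junk), "Not an end_count_store")

  stale <- withr::local_tempfile(fileext = ".store")
  lines <- readLines(path)
  lines[1] <- sub("\tv1\t", "\tv0\t", lines[1])
  writeLines(lines, stale)
  expect_error(read_store(stale), "v0")
})
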