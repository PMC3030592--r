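# In-line barcode demultiplexing.

test_that("the standard tag set has pairwise Hamming distance 3", {
  tags <- c("CATT", "GTAT", "ACGT", "TGCT")
  expect_identical(min_pairwise_hamming(tags), 3L)
  # enumeration: every pair individually
  chars <- strsplit(tags, "")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gte(sum(chars[[i]] != chars[[j]]), 3L)
  }
  # hence 1 mismatch is unambiguous but 3 would not be
  expect_silent(barcode_spec(tags, max_mismatch = 1L))
  expect_error(barcode_spec(tags, max_mismatch = 3L), "ambiguous")
  expect_error(barcode_spec(c("AAAA", "AAAT"), max_mismatch = 1L), "ambiguous")
})

test_that("exact-match demux recovers constructed per-tag counts", {
  tags <- c("CATT", "GTAT", "ACGT", "TGCT")
  reads <- exact_tag_reads(tags, per_tag = 100L)
  res <- demultiplex(reads, barcode_spec(tags))
  expect_identical(unname(res$report$per_tag), rep(100L, 4))
  expect_identical(res$report$unassigned, 0L)
  expect_equal(res$report$barcode_fraction, 100.0)

  # rotation moves the window: identical report with position = "back"
  rot <- rotate_read(reads, 4)
  res_back <- demultiplex(rot, barcode_spec(tags, position = "back"))
  expect_identical(res_back$report$per_tag, res$report$per_tag)

  # partition completeness
  expect_identical(sum(vapply(res$streams, nrow, integer(1))), nrow(reads))
  expect_identical(sum(res$report$per_tag) + res$report$unassigned,
                   res$report$total_reads)
})

test_that("corrupted barcodes are rejected at zero tolerance and counted exactly", {
  fx <- generate_reads(fixture_config(seed = 13, n_reads = 2000, corrupt_frac = 0.05))
  res <- demultiplex(fx$reads, barcode_spec())
  expect_identical(res$report$unassigned, sum(fx$truth$corrupted))
  # all uncorrupted reads recovered under their true tag
  ok <- !fx$truth$corrupted
  expect_identical(as.character(res$assignment[ok]), fx$truth$tag[ok])
})

test_that("single-error barcodes are recovered at max_mismatch = 1", {
  tags <- c("CATT", "GTAT", "ACGT", "TGCT")
  # every possible single substitution of every tag
  reads <- list()
  truth <- character()
  for (tg in tags) {
    for (p in 1:4) for (sub in setdiff(c("A", "C", "G", "T"), substr(tg, p, p))) {
      mut <- tg
      substr(mut, p, p) <- sub
      reads[[length(reads) + 1L]] <- paste0(mut, strrep("A", 36))
      truth <- c(truth, tg)
    }
  }
  rs <- read_set(sprintf("m%03d", seq_along(truth)), unlist(reads),
                 strrep("I", 40))
  strict <- demultiplex(rs, barcode_spec(tags, max_mismatch = 0L))
  expect_identical(strict$report$unassigned, nrow(rs))
  lenient <- demultiplex(rs, barcode_spec(tags, max_mismatch = 1L))
  expect_identical(as.character(lenient$assignment), truth)
})

test_that("re-demultiplexing concatenated streams reproduces the counts", {
  fx <- generate_reads(fixture_config(seed = 17, n_reads = 500, corrupt_frac = 0.1))
  res <- demultiplex(fx$reads, barcode_spec())
  cat_streams <- do.call(rbind, lapply(unname(res$streams), as.data.frame))
  rs <- read_set(cat_streams$id, cat_streams$bases, cat_streams$quals)
  res2 <- demultiplex(rs, barcode_spec())
  expect_identical(res2$report$per_tag, res$report$per_tag)
  expect_identical(res2$report$unassigned, res$report$unassigned)
})

test_that("short reads are reported and land in unassigned", {
  rs <- read_set(c("a", "b"), c("CAT", "CATTACGT"), c("III", "IIIIIIII"))
  res <- demultiplex(rs, barcode_spec())
  expect_identical(res$report$n_too_short, 1L)
  expect_identical(nrow(res$streams$unassigned), 1L)
  expect_identical(unname(res$report$per_tag[["CATT"]]), 1L)
  expect_equal(res$report$barcode_fraction, 50.0)
})

test_that("demux streams write one FASTQ per tag", {
  dir <- withr::local_tempdir()
  reads <- exact_tag_reads(c("CATT", "GTAT"), per_tag = 5L)
  res <- demultiplex(reads, barcode_spec(c("CATT", "GTAT")))
  paths <- write_demux(res, file.path(dir, "out"))
  expect_identical(length(paths), 3L)  # two tags + unassigned
  expect_identical(nrow(read_fastq(paths[["CATT"]])), 5L)
  expect_identical(nrow(read_fastq(paths[["unassigned"]])), 0L)
})
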