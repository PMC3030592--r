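# Deferred cluster calling: cycle remap, manifest renaming, read rotation.

test_that("the deferred-calling remap sends barcode cycles to the back", {
  m <- build_remap(40, 4)
  expect_identical(m$mapping[c(1L, 4L, 5L, 40L)], c(37L, 40L, 1L, 36L))
  expect_identical(remap_cycles(m, 1:4), 37:40)

  expect_identical(build_remap(10, 0)$mapping, 1:10)

  for (N in c(1, 2, 7, 40, 50)) {
    for (b in seq(0, N - 1)) {
      m <- build_remap(N, b)
      expect_identical(sort(m$mapping), seq_len(N))
      expect_identical(m$inverse[m$mapping], seq_len(N))
      expect_identical(invert_remap(m)$mapping[m$mapping], seq_len(N))
    }
  }

  expect_error(build_remap(40, 40), "smaller")
  expect_error(build_remap(40, 45), "smaller")
  expect_error(remap_cycles(build_remap(10, 2), 11), "1..10")
})

test_that("read rotation moves the barcode to the end and inverts exactly", {
  r <- read_set("r1", "CATTACGTA", "ABCDEFGHI")
  rot <- rotate_read(r, 4)
  expect_identical(rot$bases, "ACGTACATT")
  expect_identical(rot$quals, "EFGHIABCD")
  expect_identical(rot$id, "r1")

  expect_identical(rotate_read(r, 0), r)
  expect_identical(unrotate_read(rotate_read(r, 4), 4), r)
  expect_identical(unrotate_read(read_set("x", "ACGTACATT", "EFGHIABCD"), 4)$bases,
                   "CATTACGTA")
  # full-length rotation is the identity
  expect_identical(rotate_read(r, 9)$bases, "CATTACGTA")

  # random reads: unrotate is the exact inverse; double unrotate is the
  # identity only when 2b = 0 (mod length)
  fx <- generate_reads(fixture_config(seed = 11, n_reads = 50, read_length = 9))
  for (b in 0:9) {
    expect_identical(unrotate_read(rotate_read(fx$reads, b), b), fx$reads)
    twice <- unrotate_read(unrotate_read(fx$reads, b), b)
    if ((2 * b) %% 9 == 0) expect_identical(twice, fx$reads)
    else expect_false(identical(twice, fx$reads))
  }

  expect_error(rotate_read(r, 10), "length")
})

test_that("rotate_fastq streams, round-trips and reports malformed records", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fastq")
  writeLines(character(0), empty)
  expect_identical(rotate_fastq(empty, file.path(dir, "e2.fastq")), 0L)

  fx <- generate_reads(fixture_config(seed = 21, n_reads = 1000))
  fin <- file.path(dir, "in.fastq")
  write_fastq(fx$reads, fin)
  frot <- file.path(dir, "rot.fastq")
  fback <- file.path(dir, "back.fastq")
  expect_identical(rotate_fastq(fin, frot, b = 4, chunk_size = 128L), 1000L)
  # barcodes now trail every read
  rot <- read_fastq(frot)
  expect_identical(substr(rot$bases, 37, 40), fx$truth$tag)
  # multiset of (base, qual) pairs per read is preserved
  expect_identical(sort(strsplit(rot$bases[1], "")[[1]]),
                   sort(strsplit(fx$reads$bases[1], "")[[1]]))
  expect_identical(rotate_fastq(frot, fback, b = 4, direction = "to_front"), 1000L)
  expect_identical(readLines(fback), readLines(fin))

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)  # qual too short
  expect_error(rotate_fastq(bad, file.path(dir, "o.fastq")), "record 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), bad)
  expect_error(rotate_fastq(bad, file.path(dir, "o.fastq")), "record 2")
})

test_that("image-tree rename applies the remap and round-trips byte-for-byte", {
  root <- withr::local_tempdir()
  tree <- file.path(root, "run")
  expect_identical(generate_image_tree(tree, lanes = 1, tiles = c(1, 2), cycles = 40),
                   320L)
  before <- tree_digest(tree)
  mf <- scan_image_manifest(tree)
  expect_identical(nrow(mf), 320L)
  expect_identical(nrow(manifest_missing(mf)), 0L)

  m <- build_remap(40, 4)
  plan <- plan_rename(mf, m)
  expect_identical(nrow(plan), 320L)  # every cycle moves when b > 0

  # dry run touches nothing
  expect_message(execute_rename_plan(plan), "dry run")
  expect_identical(tree_digest(tree), before)

  expect_identical(execute_rename_plan(plan, execute = TRUE), 320L)
  # original cycle-1 images now live at the back of the stack; cycle 5 at front
  expect_match(readLines(file.path(tree, "C37.1", "s_1_1_a.tif")), "cycle=1 ")
  expect_match(readLines(file.path(tree, "C1.1", "s_1_2_t.tif")), "cycle=5 ")
  expect_false(any(grepl("remap-tmp", list.files(tree, recursive = TRUE))))

  # inverse plan restores the original tree exactly
  plan_back <- plan_rename(scan_image_manifest(tree), invert_remap(m))
  execute_rename_plan(plan_back, execute = TRUE)
  expect_identical(tree_digest(tree), before)
})

test_that("identity remaps, incomplete manifests and crashed renames are handled", {
  root <- withr::local_tempdir()
  tree <- file.path(root, "run")
  generate_image_tree(tree, cycles = 8)
  mf <- scan_image_manifest(tree)

  # b = 0: zero effective changes
  plan0 <- plan_rename(mf, build_remap(8, 0))
  expect_identical(nrow(plan0), 0L)
  expect_message(execute_rename_plan(plan0), "zero changes")

  # a missing channel file is reported
  file.remove(file.path(tree, "C3.1", "s_1_1_g.tif"))
  mf2 <- scan_image_manifest(tree)
  miss <- manifest_missing(mf2)
  expect_identical(nrow(miss), 1L)
  expect_identical(miss$cycle, 3L)
  expect_error(plan_rename(mf2, build_remap(8, 2)), "incomplete")
  plan <- plan_rename(mf2, build_remap(8, 2), allow_incomplete = TRUE)

  # simulate a crash mid phase 1, then resume
  i <- 5L
  file.rename(file.path(tree, plan$old_path[i]), file.path(tree, plan$tmp_path[i]))
  expect_identical(execute_rename_plan(plan, execute = TRUE), nrow(plan))
  expect_false(any(grepl("remap-tmp", list.files(tree, recursive = TRUE))))

  # tree is non-empty for the generator
  expect_error(generate_image_tree(tree), "not empty")
})
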