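# Genome-window counting, percentile filtering and track comparison.

two_chrom <- function() genome_def(c(chrI = 5000, chrII = 3000))

test_that("window counting assigns reads by 5' coordinate", {
  g <- two_chrom()
  none <- count_windows(data.frame(chrom = character(), pos = numeric()), g)
  expect_identical(nrow(none), 80L)  # 50 + 30 windows of 100 bp
  expect_true(all(none$count == 0L))

  one <- count_windows(data.frame(chrom = "chrI", pos = 0), g)
  expect_identical(one$count[one$chrom == "chrI" & one$start == 0], 1L)
  expect_identical(sum(one$count), 1L)

  edge <- count_windows(data.frame(chrom = "chrI", pos = c(99, 100)), g)
  expect_identical(edge$count[edge$start == 0 & edge$chrom == "chrI"], 1L)
  expect_identical(edge$count[edge$start == 100 & edge$chrom == "chrI"], 1L)

  # conservation and skip reporting
  mixed <- data.frame(chrom = c("chrI", "chrI", "chrX", "chrII"),
                      pos = c(10, 6000, 5, 2999))
  expect_warning(tr <- count_windows(mixed, g), "2 read")
  expect_identical(attr(tr, "n_assigned"), 2L)
  expect_identical(attr(tr, "n_skipped"), 2L)
  expect_identical(sum(tr$count), 2L)
})

test_that("order of input reads does not matter and sliding windows overlap", {
  g <- two_chrom()
  pos <- generate_positions(g, 500, seed = 3)
  a <- count_windows(pos, g)
  b <- count_windows(pos[rev(seq_len(nrow(pos))), ], g)
  expect_equal(a$count, b$count)

  # step < w: a read lands in w/step windows (away from edges)
  sl <- count_windows(data.frame(chrom = "chrI", pos = 250), g, w = 100, step = 50)
  expect_identical(sum(sl$count), 2L)
  expect_identical(sl$count[sl$chrom == "chrI" & sl$start %in% c(200, 250)], c(1L, 1L))
})

test_that("generated enrichment peaks are recovered within Poisson error", {
  g <- genome_def(c(chrI = 20000))
  peaks <- data.frame(chrom = "chrI", center = 10000, width = 1000, fold = 10)
  pos <- generate_positions(g, 20000, peaks = peaks, seed = 11)
  tr <- count_windows(pos, g)
  inpk <- tr$start >= 9500 & tr$start < 10500
  bg_mean <- mean(tr$count[!inpk])
  pk_mean <- mean(tr$count[inpk])
  expect_gt(pk_mean / bg_mean, 7)
  expect_lt(pk_mean / bg_mean, 13)
})

test_that("nearest-rank percentile filter masks exactly the extreme windows", {
  g <- genome_def(c(chr = 100000))  # 1000 windows of 100 bp
  # ten windows with huge counts, the rest small
  pos <- do.call(rbind, c(
    lapply(0:9, function(i) data.frame(chrom = "chr", pos = rep(i * 10000 + 1, 1000))),
    list(data.frame(chrom = "chr", pos = seq(5, 99995, by = 50) + 2))
  ))
  tr <- count_windows(pos, g)
  expect_identical(sum(tr$count >= 1000), 10L)
  expect_true(max(tr$count[tr$count < 1000]) <= 5)

  f99 <- filter_percentile(tr, 99)
  expect_identical(sum(!f99$mask), 10L)
  expect_true(all(f99$count[!f99$mask] >= 1000))
  # agreement with the type-1 empirical quantile
  expect_equal(attr(f99, "threshold"),
               unname(quantile(tr$count, 0.99, type = 1)))

  expect_true(all(filter_percentile(tr, 100)$mask))
  const <- count_windows(data.frame(chrom = "chr", pos = seq(0, 99999, by = 100)), g)
  expect_true(all(filter_percentile(const, 99)$mask))

  # mask depends only on the multiset of counts
  shuf <- tr
  ord <- sample(nrow(shuf))
  expect_identical(sort(filter_percentile(tr, 99)$count[!filter_percentile(tr, 99)$mask]),
                   sort(filter_percentile(tr[ord, ], 99)$count[!filter_percentile(tr[ord, ], 99)$mask]))
})

test_that("track comparison pairs unmasked windows and computes correlations", {
  g <- two_chrom()
  pos <- generate_positions(g, 3000, seed = 21)
  a <- count_windows(pos, g)
  self <- compare_tracks(a, a)
  expect_equal(self$pearson_log, 1)
  expect_equal(self$spearman, 1)
  expect_identical(self$n, nrow(a))

  doubled <- a
  doubled$count <- a$count * 2L
  expect_equal(compare_tracks(a, doubled)$spearman, 1)

  # independent tracks decorrelate
  b <- count_windows(generate_positions(g, 3000, seed = 22), g)
  expect_lt(abs(compare_tracks(a, b)$pearson_log), 3 / sqrt(nrow(a)) + 0.05)

  # masked windows are excluded from the pairing
  am <- filter_percentile(a, 90)
  cmp <- compare_tracks(am, b)
  expect_identical(cmp$n, sum(am$mask & b$mask))

  wrong <- count_windows(pos, g, w = 200)
  expect_error(compare_tracks(a, wrong), "grids differ")
})

test_that("BED round trip preserves 5' coordinates strand-aware", {
  dir <- withr::local_tempdir()
  g <- two_chrom()
  pos <- generate_positions(g, 200, seed = 31)
  # keep positions where the minus-strand 40-mer fits inside the chromosome
  len <- g$length[match(pos$chrom, g$chrom)]
  pos <- pos[(pos$strand == "+" & pos$pos + 40 <= len) |
             (pos$strand == "-" & pos$pos >= 39), ]
  bed <- file.path(dir, "reads.bed")
  write_positions_bed(pos, bed, read_length = 40L)
  back <- read_positions(bed)
  expect_equal(back$pos, pos$pos)
  expect_identical(back$strand, pos$strand)
  expect_identical(back$chrom, pos$chrom)

  # TSV input path
  tsv <- file.path(dir, "reads.tsv")
  write.table(pos, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_positions(tsv)$pos, pos$pos)

  # bedGraph export covers unmasked windows
  tr <- filter_percentile(count_windows(pos, g), 99)
  bg <- file.path(dir, "track.bedGraph")
  write_bedgraph(tr, bg)
  expect_identical(length(readLines(bg)), sum(tr$mask))
})
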