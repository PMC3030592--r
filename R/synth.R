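# Deterministic synthetic fixtures: reads with in-line barcodes and a
# quality-decay model, placeholder image trees, and mapped-read positions
# with enrichment peaks. Everything the toolkit consumes can be generated
# here, with ground truth recorded, so all modules are testable offline.

#' Synthetic fixture configuration
#'
#' Defaults emulate the study conditions of a Genome Analyzer era run:
#' 40-cycle reads; four-base in-line barcodes CATT/GTAT/ACGT/TGCT in
#' equal proportions; Phred qualities starting around 34 and decaying
#' linearly along the read with Gaussian noise, clamped to the era's
#' [2, 41] range (which makes the all-Phred-2 QC flag representable).
#' A single-tag profile `tags = "CATG"` emulates a restriction-digest
#' (NlaIII) library start instead.
#'
#' @param seed integer seed; all outputs are byte-reproducible from it.
#' @param n_reads number of reads.
#' @param read_length read length in cycles (default 40).
#' @param tags in-line barcode(s) at the read start.
#' @param proportions tag proportions (default equal).
#' @param q_start mean Phred score at cycle 1 (default 34).
#' @param q_decay mean Phred decrease per cycle (default 0.25).
#' @param q_sd Gaussian noise s.d. around the per-cycle mean (default 3).
#' @param corrupt_frac fraction of reads whose barcode is corrupted by 2
#'   substitutions (default 0); the exact count is `round(frac * n)`.
#' @param n_all_b number of injected reads with Phred 2 at every position
#'   (default 0).
#' @param offset quality encoding offset for emitted FASTQ (default 33).
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(seed = 1L, n_reads = 400L, read_length = 40L,
                           tags = c("CATT", "GTAT", "ACGT", "TGCT"),
                           proportions = NULL,
                           q_start = 34, q_decay = 0.25, q_sd = 3,
                           corrupt_frac = 0, n_all_b = 0L, offset = 33L) {
  stop_if_not_count(n_reads, "n_reads")
  stop_if_not_count(read_length, "read_length", min = 1L)
  stop_if_not_count(n_all_b, "n_all_b")
  if (is.null(proportions)) proportions <- rep(1 / length(tags), length(tags))
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1", call. = FALSE)
  if (any(nchar(tags) > read_length)) {
    stop("read length must be at least the barcode length", call. = FALSE)
  }
  if (corrupt_frac < 0 || corrupt_frac > 1) stop("corrupt_frac in [0,1]", call. = FALSE)
  if (n_all_b > n_reads) stop("n_all_b exceeds n_reads", call. = FALSE)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 tags = as.character(tags), proportions = as.numeric(proportions),
                 q_start = q_start, q_decay = q_decay, q_sd = q_sd,
                 corrupt_frac = corrupt_frac, n_all_b = as.integer(n_all_b),
                 offset = as.integer(offset)),
            class = "fixture_config")
}

#' Generate synthetic barcoded reads with ground truth
#'
#' Each read starts with its assigned barcode (unless flagged corrupted,
#' in which case two barcode positions are substituted with different
#' bases), followed by random template bases. Qualities follow the
#' linear-decay model of the config, rounded and clamped to [2, 41].
#' `n_all_b` randomly chosen reads get Phred 2 throughout (the read
#' segment QC indicator). Fully reproducible from the config seed.
#'
#' @param config a [fixture_config()].
#' @return A list: `reads` (a [read_set()]) and `truth` (data.frame with
#'   `id`, `tag`, `corrupted`, `all_b`).
#' @export
#' @examples
#' fx <- generate_reads(fixture_config(seed = 7, n_reads = 40))
#' table(fx$truth$tag)
generate_reads <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_reads
  L <- config$read_length
  alphabet <- c("A", "C", "G", "T")
  out <- with_seed(config$seed, {
    tag_idx <- if (length(config$tags) == 1L) rep(1L, n)
               else sample.int(length(config$tags), n, replace = TRUE,
                               prob = config$proportions)
    tag <- config$tags[tag_idx]
    blen <- nchar(config$tags[[1L]])
    n_corrupt <- round(config$corrupt_frac * n)
    corrupted <- rep(FALSE, n)
    if (n_corrupt > 0) corrupted[sample.int(n, n_corrupt)] <- TRUE
    all_b <- rep(FALSE, n)
    if (config$n_all_b > 0) all_b[sample.int(n, config$n_all_b)] <- TRUE

    bases <- vapply(seq_len(n), function(i) {
      bc <- strsplit(tag[i], "")[[1L]]
      if (corrupted[i]) {
        pos <- sample.int(blen, 2L)
        for (p in pos) bc[p] <- sample(setdiff(alphabet, bc[p]), 1L)
      }
      paste(c(bc, sample(alphabet, L - blen, replace = TRUE)), collapse = "")
    }, character(1))

    mean_q <- config$q_start - config$q_decay * (seq_len(L) - 1)
    quals <- vapply(seq_len(n), function(i) {
      q <- if (all_b[i]) rep(2L, L)
           else pmin(41L, pmax(2L, as.integer(round(rnorm(L, mean_q, config$q_sd)))))
      rawToChar(as.raw(q + config$offset))
    }, character(1))

    list(tag = tag, corrupted = corrupted, all_b = all_b,
         bases = bases, quals = quals)
  })
  id <- sprintf("synth_%06d", seq_len(n))
  list(reads = read_set(id, out$bases, out$quals, offset = config$offset),
       truth = data.frame(id = id, tag = out$tag, corrupted = out$corrupted,
                          all_b = out$all_b, stringsAsFactors = FALSE))
}

#' Generate a placeholder image tree
#'
#' Creates the full image-file tree for the given lanes, tiles and cycles
#' under `root`, following the filename template. Each file's content is
#' its own `(lane, tile, cycle, channel)` fingerprint, so tests can
#' verify content-to-location correspondence after cycle-remap renaming.
#' Pixel data are deliberately not emulated.
#'
#' @param root target directory; must not already contain files.
#' @param lanes,tiles vectors of lane and tile ids (integers).
#' @param cycles number of sequencing cycles.
#' @param template filename template (see [default_image_template()]).
#' @return Invisibly, the number of files created (`lanes x tiles x
#'   cycles x 4` channels).
#' @export
generate_image_tree <- function(root, lanes = 1L, tiles = 1L, cycles = 40L,
                                template = default_image_template()) {
  stop_if_not_count(cycles, "cycles", min = 1L)
  if (dir.exists(root) && length(list.files(root, recursive = TRUE))) {
    stop(sprintf("'%s' is not empty", root), call. = FALSE)
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  n <- 0L
  for (lane in lanes) for (tile in tiles) for (cycle in seq_len(cycles)) {
    for (channel in c("a", "c", "g", "t")) {
      rel <- image_path(lane, tile, cycle, channel, template)
      path <- file.path(root, rel)
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      writeLines(sprintf("lane=%d tile=%d cycle=%d channel=%s",
                         lane, tile, cycle, channel), path)
      n <- n + 1L
    }
  }
  invisible(n)
}

#' Generate mapped-read positions with enrichment peaks
#'
#' Samples `n_reads` 5' start positions over a genome from a flat
#' per-base background plus optional enrichment peaks where the per-base
#' intensity is multiplied by `fold`. Strands are drawn evenly. Seeded
#' and fully reproducible.
#'
#' @param genome a [genome_def()].
#' @param n_reads number of reads to place.
#' @param peaks optional data.frame with columns `chrom`, `center`,
#'   `width`, `fold`; each peak spans `[center - width/2, center +
#'   width/2)` and must lie inside its chromosome.
#' @param seed integer seed.
#' @return A data.frame with columns `chrom`, `pos` (0-based 5'
#'   coordinate), `strand`.
#' @export
generate_positions <- function(genome, n_reads, peaks = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_def"))
  stop_if_not_count(n_reads, "n_reads")
  # per-base sampling weights, chromosome by chromosome
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      ci <- match(peaks$chrom[i], genome$chrom)
      if (is.na(ci)) stop("peak on unknown chromosome", call. = FALSE)
      lo <- peaks$center[i] - peaks$width[i] / 2
      hi <- peaks$center[i] + peaks$width[i] / 2
      if (lo < 0 || hi > genome$length[ci]) {
        stop("peak extends outside its chromosome", call. = FALSE)
      }
    }
  }
  if (n_reads == 0L) {
    return(data.frame(chrom = character(), pos = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    # chromosome weights = length + extra peak mass
    chrom_w <- genome$length
    if (!is.null(peaks)) {
      for (i in seq_len(nrow(peaks))) {
        ci <- match(peaks$chrom[i], genome$chrom)
        chrom_w[ci] <- chrom_w[ci] + peaks$width[i] * (peaks$fold[i] - 1)
      }
    }
    chrom_idx <- sample.int(nrow(genome), n_reads, replace = TRUE,
                            prob = chrom_w / sum(chrom_w))
    pos <- numeric(n_reads)
    for (ci in unique(chrom_idx)) {
      sel <- which(chrom_idx == ci)
      len <- genome$length[ci]
      pk <- if (is.null(peaks)) NULL else peaks[peaks$chrom == genome$chrom[ci], , drop = FALSE]
      if (is.null(pk) || nrow(pk) == 0L) {
        pos[sel] <- floor(runif(length(sel), 0, len))
      } else {
        # mixture: background (whole chromosome, weight len) vs each
        # peak's surplus (weight width * (fold - 1))
        surplus <- pk$width * (pk$fold - 1)
        comp_w <- c(len, surplus)
        comp <- sample.int(length(comp_w), length(sel), replace = TRUE,
                           prob = comp_w / sum(comp_w))
        bg <- comp == 1L
        pos[sel][bg] <- floor(runif(sum(bg), 0, len))
        for (p in seq_len(nrow(pk))) {
          inpk <- comp == p + 1L
          pos[sel][inpk] <- floor(runif(sum(inpk),
                                        pk$center[p] - pk$width[p] / 2,
                                        pk$center[p] + pk$width[p] / 2))
        }
      }
    }
    data.frame(chrom = genome$chrom[chrom_idx], pos = pos,
               strand = sample(c("+", "-"), n_reads, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Write positions as a BED file
#'
#' Each read becomes a `read_length`-bp interval; for `-` strand reads
#' the 5' coordinate is the interval end, matching [read_positions()].
#'
#' @param positions data.frame with `chrom`, `pos`, `strand`.
#' @param path output BED path.
#' @param read_length interval length in bp.
#' @return Invisibly, the path.
#' @export
write_positions_bed <- function(positions, path, read_length = 40L) {
  n <- nrow(positions)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  minus <- positions$strand == "-"
  start <- ifelse(minus, positions$pos - read_length + 1L, positions$pos)
  start <- pmax(0, start)
  end <- ifelse(minus, positions$pos + 1L, positions$pos + read_length)
  write.table(data.frame(positions$chrom, format(start, scientific = FALSE, trim = TRUE),
                         format(end, scientific = FALSE, trim = TRUE),
                         sprintf("read_%06d", seq_len(n)), 0L, positions$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
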