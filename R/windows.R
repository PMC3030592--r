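# Genome-window read counting, percentile outlier filtering, and paired
# track comparison.

#' Genome definition
#'
#' Ordered chromosome names and lengths.
#'
#' @param chrom chromosome names (unique) or a named numeric vector of
#'   lengths.
#' @param length chromosome lengths in bp (> 0); omitted when `chrom` is a
#'   named vector.
#' @return A data.frame of class `"genome_def"`.
#' @export
#' @examples
#' genome_def(c(chrI = 230218, chrII = 813184))
genome_def <- function(chrom, length = NULL) {
  if (is.null(length)) {
    if (is.null(names(chrom))) stop("lengths required", call. = FALSE)
    length <- as.numeric(chrom)
    chrom <- names(chrom)
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  structure(data.frame(chrom = as.character(chrom), length = as.numeric(length),
                       stringsAsFactors = FALSE),
            class = c("genome_def", "data.frame"))
}

window_starts <- function(len, w, s) seq(0, max(0, len - 1), by = s)

#' Count reads in genome windows
#'
#' Assigns each read, by its 5' start coordinate, to every window
#' containing that coordinate (exactly one window when `step == w`, the
#' non-overlapping tiling default). Windows of width `w` start every
#' `step` bp from 0 and tile `[0, length)` per chromosome, 0-based
#' half-open. Reads on unknown chromosomes or outside chromosome bounds
#' are dropped and counted in the `n_skipped` attribute.
#'
#' @param positions a data.frame with columns `chrom`, `pos` (0-based 5'
#'   start coordinate) and optionally `strand` (informational; `pos` is
#'   already the 5' coordinate) — as returned by [read_positions()] or
#'   [generate_positions()].
#' @param genome a [genome_def()].
#' @param w window width in bp (default 100).
#' @param step window step in bp; defaults to `w` (tiling). Must satisfy
#'   `0 < step <= w`.
#' @return A data.frame of class `"window_track"` with columns `chrom`,
#'   `start`, `count` and logical `mask` (initially all `TRUE` = kept),
#'   carrying attributes `w`, `step`, `n_assigned`, `n_skipped`.
#' @export
count_windows <- function(positions, genome, w = 100L, step = w) {
  stopifnot(inherits(genome, "genome_def"))
  stop_if_not_count(w, "w", min = 1L)
  stop_if_not_count(step, "step", min = 1L)
  if (step > w) stop("'step' must not exceed the window width", call. = FALSE)
  if (!all(c("chrom", "pos") %in% names(positions))) {
    stop("positions need columns 'chrom' and 'pos'", call. = FALSE)
  }
  grid <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    data.frame(chrom = genome$chrom[i],
               start = window_starts(genome$length[i], w, step),
               stringsAsFactors = FALSE)
  }))
  grid$count <- 0L

  known <- positions$chrom %in% genome$chrom
  if (any(known)) {
    len <- genome$length[match(positions$chrom[known], genome$chrom)]
    inb <- positions$pos[known] >= 0 & positions$pos[known] < len
  } else {
    inb <- logical(0)
  }
  keep <- which(known)[inb]
  n_skipped <- nrow(positions) - length(keep)
  if (n_skipped > 0) {
    warning(sprintf("%d read(s) skipped (unknown chromosome or out of range)",
                    n_skipped), call. = FALSE)
  }
  if (length(keep)) {
    p <- positions$pos[keep]
    chrom <- positions$chrom[keep]
    # windows containing position p start at step-multiples in (p - w, p]
    lo <- ceiling(pmax(0, p - w + 1) / step)
    hi <- floor(p / step)
    reps <- pmax(0L, hi - lo + 1L)
    win_start <- unlist(mapply(function(l, h) if (h >= l) seq(l, h) else integer(0),
                               lo, hi, SIMPLIFY = FALSE)) * step
    win_chrom <- rep(chrom, reps)
    key <- paste(win_chrom, win_start)
    hit <- match(key, paste(grid$chrom, grid$start))
    valid <- !is.na(hit)
    tab <- tabulate(hit[valid], nbins = nrow(grid))
    grid$count <- as.integer(tab)
  }
  grid$mask <- TRUE
  attr(grid, "w") <- as.integer(w)
  attr(grid, "step") <- as.integer(step)
  attr(grid, "n_assigned") <- if (step == w) length(keep) else sum(grid$count)
  attr(grid, "n_skipped") <- n_skipped
  class(grid) <- c("window_track", "data.frame")
  grid
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("Window track: %d windows of %d bp (step %d), %d reads assigned, %d masked out\n",
              nrow(x), attr(x, "w"), attr(x, "step"),
              attr(x, "n_assigned"), sum(!x$mask)))
  invisible(x)
}

#' Nearest-rank percentile filter on window counts
#'
#' Masks out windows whose count lies strictly above the nearest-rank
#' `upper_percentile` of all window counts — the conventional guard
#' against mapping-artefact pileups. Zero-count windows are part of the
#' distribution (the filter keeps the 0 to `upper_percentile` band).
#' The threshold is the `ceiling(p/100 * n)`-th order statistic; with
#' `upper_percentile = 100` nothing is masked.
#'
#' @param track a [count_windows()] result.
#' @param upper_percentile upper percentile bound (default 99).
#' @return The track with its `mask` column updated (`TRUE` = kept) and a
#'   `threshold` attribute recording the cutoff count.
#' @export
filter_percentile <- function(track, upper_percentile = 99) {
  stopifnot(inherits(track, "window_track"))
  if (nrow(track) == 0L) stop("empty track", call. = FALSE)
  if (upper_percentile <= 0 || upper_percentile > 100) {
    stop("'upper_percentile' must lie in (0, 100]", call. = FALSE)
  }
  thr <- sort(track$count)[max(1L, ceiling(upper_percentile / 100 * nrow(track)))]
  track$mask <- track$count <= thr
  attr(track, "threshold") <- thr
  track
}

#' Compare two window tracks
#'
#' Pairs two tracks over the same genome and window grid by window key,
#' restricted to the intersection of their unmasked windows, and reports
#' Pearson correlation of `log10(count + 1)` and Spearman rank
#' correlation — the numbers behind a scatter comparison of two
#' processing routes of the same lane.
#'
#' @param a,b [count_windows()] results on identical grids.
#' @return A list of class `"track_comparison"`: `table` (window, counts
#'   in both tracks), `n`, `pearson_log`, `spearman`.
#' @export
compare_tracks <- function(a, b) {
  stopifnot(inherits(a, "window_track"), inherits(b, "window_track"))
  if (attr(a, "w") != attr(b, "w") || attr(a, "step") != attr(b, "step") ||
      nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) || !identical(a$start, b$start)) {
    stop("window grids differ; tracks must share genome, width and step",
         call. = FALSE)
  }
  keep <- a$mask & b$mask
  tab <- data.frame(chrom = a$chrom[keep], start = a$start[keep],
                    count_a = a$count[keep], count_b = b$count[keep],
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab, n = nrow(tab),
         pearson_log = cor(log10(tab$count_a + 1), log10(tab$count_b + 1)),
         spearman = cor(tab$count_a, tab$count_b, method = "spearman")),
    class = "track_comparison"
  )
}

#' @export
print.track_comparison <- function(x, ...) {
  cat(sprintf("Track comparison over %d windows: Pearson(log10) = %.3f, Spearman = %.3f\n",
              x$n, x$pearson_log, x$spearman))
  invisible(x)
}

#' Read mapped-read positions
#'
#' Accepts BED (0-based; the 5' coordinate is the interval start for `+`
#' reads and `end - 1` for `-` reads) or a plain TSV with columns
#' `chrom`, `pos`, `strand` where `pos` is already the 0-based 5'
#' coordinate.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return A data.frame with columns `chrom`, `pos`, `strand`.
#' @export
read_positions <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "+"
    # GRanges is 1-based closed; back to 0-based
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)   # half-open end
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = ifelse(strand == "-", end0 - 1L, start0),
               strand = strand, stringsAsFactors = FALSE)
  } else {
    d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos") %in% names(d))) {
      stop("TSV needs columns 'chrom' and 'pos'", call. = FALSE)
    }
    if (is.null(d$strand)) d$strand <- "+"
    d[c("chrom", "pos", "strand")]
  }
}

#' Write a window track as bedGraph
#'
#' Unmasked windows only; window intervals are 0-based half-open.
#'
#' @param track a [count_windows()] result.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "window_track"))
  keep <- which(track$mask)
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom[keep],
    ranges = IRanges::IRanges(start = track$start[keep] + 1L,
                              width = attr(track, "w")),
    score = track$count[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
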