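# Phred quality summaries: per-cycle statistics, per-read mean-quality
# histogram, and the all-Phred-2 read segment QC flag.

phred_matrix <- function(reads, offset = NULL) {
  vals <- phred_values(reads, offset)
  if (length(vals) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  maxlen <- max(lengths(vals))
  do.call(rbind, lapply(vals, function(v) c(v, rep(NA_integer_, maxlen - length(v)))))
}

# lower-interpolation quantile: the ceiling(p*n)-th order statistic, so
# results stay integers in Phred space
quantile_lower <- function(v, p) {
  v <- sort(v)
  v[max(1L, ceiling(p * length(v)))]
}

#' Per-cycle Phred quality statistics
#'
#' Mean, median and quartiles of the Phred score at each sequencing
#' cycle, computed over the reads that cover that cycle (ragged read
#' lengths are allowed). Median and quartiles use the lower-interpolation
#' convention (an order statistic), so they are integers in Phred space.
#'
#' @param reads a [read_set()].
#' @param offset quality encoding offset; defaults to the set's declared
#'   one.
#' @return A data.frame with columns `cycle`, `n`, `mean`, `median`,
#'   `q25`, `q75`.
#' @export
per_base_quality <- function(reads, offset = NULL) {
  m <- phred_matrix(reads, offset)
  if (ncol(m) == 0L) {
    return(data.frame(cycle = integer(), n = integer(), mean = numeric(),
                      median = numeric(), q25 = numeric(), q75 = numeric()))
  }
  out <- lapply(seq_len(ncol(m)), function(cy) {
    v <- m[, cy]
    v <- v[!is.na(v)]
    data.frame(cycle = cy, n = length(v), mean = mean(v),
               median = quantile_lower(v, 0.5),
               q25 = quantile_lower(v, 0.25),
               q75 = quantile_lower(v, 0.75))
  })
  do.call(rbind, out)
}

#' Per-sequence mean-quality histogram
#'
#' Each read's mean Phred score, floored to an integer bin; returns the
#' histogram over occupied and intermediate bins.
#'
#' @inheritParams per_base_quality
#' @return A data.frame with columns `mean_quality` (integer bin) and
#'   `count`; counts sum to the number of reads.
#' @export
per_sequence_quality <- function(reads, offset = NULL) {
  vals <- phred_values(reads, offset)
  if (length(vals) == 0L) {
    return(data.frame(mean_quality = integer(), count = integer()))
  }
  bins <- floor(vapply(vals, mean, numeric(1)))
  rng <- seq(min(bins), max(bins))
  counts <- tabulate(bins - min(bins) + 1L, nbins = length(rng))
  data.frame(mean_quality = as.integer(rng), count = counts)
}

#' Count all-Phred-2 reads
#'
#' Reads whose every position has Phred value exactly 2 — quality
#' character 'B' under the Phred+64 encoding, '#' under Phred+33 — carry
#' the instrument's read-segment quality-control indicator and should be
#' excluded downstream.
#'
#' @inheritParams per_base_quality
#' @return The number of such reads.
#' @export
count_b_reads <- function(reads, offset = NULL) {
  vals <- phred_values(reads, offset)
  sum(vapply(vals, function(v) length(v) > 0L && all(v == 2L), logical(1)))
}
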