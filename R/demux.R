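# In-line barcode demultiplexing.

#' Barcode specification
#'
#' Expected in-line barcodes, their position in the read (leading bases
#' for standard processing, trailing bases after deferred-calling
#' rotation), and the mismatch tolerance. The tolerance must be smaller
#' than the minimum pairwise Hamming distance of the tag set, otherwise a
#' read could sit within tolerance of two tags and the set is rejected as
#' ambiguous. The default tag set CATT/GTAT/ACGT/TGCT has minimum
#' pairwise distance 3, so one mismatch is always unambiguous.
#'
#' @param tags barcode strings, all the same length.
#' @param position `"front"` (default) or `"back"`.
#' @param max_mismatch allowed Hamming mismatches (default 0, exact match).
#' @return An object of class `"barcode_spec"`.
#' @export
#' @examples
#' barcode_spec(c("CATT", "GTAT", "ACGT", "TGCT"))
barcode_spec <- function(tags = c("CATT", "GTAT", "ACGT", "TGCT"),
                         position = c("front", "back"), max_mismatch = 0L) {
  position <- match.arg(position)
  tags <- as.character(tags)
  if (length(tags) == 0L) stop("at least one tag required", call. = FALSE)
  if (anyDuplicated(tags)) stop("tags must be unique", call. = FALSE)
  if (length(unique(nchar(tags))) != 1L) stop("tags must share one length", call. = FALSE)
  stop_if_not_count(max_mismatch, "max_mismatch")
  if (length(tags) > 1L) {
    mind <- min_pairwise_hamming(tags)
    if (max_mismatch >= mind) {
      stop(sprintf("max_mismatch = %d is ambiguous for this tag set (min pairwise Hamming distance %d)",
                   max_mismatch, mind), call. = FALSE)
    }
  }
  structure(list(tags = tags, b = nchar(tags[[1L]]), position = position,
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_spec")
}

#' Minimum pairwise Hamming distance of a tag set
#'
#' @param tags equal-length strings.
#' @return The smallest Hamming distance between any two tags.
#' @export
min_pairwise_hamming <- function(tags) {
  if (length(tags) < 2L) return(nchar(tags[[1L]]))
  chars <- strsplit(tags, "")
  d <- Inf
  for (i in seq_along(tags)[-length(tags)]) {
    for (j in seq((i + 1L), length(tags))) {
      d <- min(d, sum(chars[[i]] != chars[[j]]))
    }
  }
  as.integer(d)
}

hamming_to_tags <- function(windows, tags) {
  # matrix of mismatch counts, reads x tags
  b <- nchar(tags[[1L]])
  wm <- do.call(rbind, strsplit(windows, ""))
  out <- matrix(0L, nrow = length(windows), ncol = length(tags))
  for (j in seq_along(tags)) {
    tj <- strsplit(tags[[j]], "")[[1L]]
    out[, j] <- rowSums(wm != matrix(tj, nrow = length(windows), ncol = b, byrow = TRUE))
  }
  out
}

#' Demultiplex reads by in-line barcode
#'
#' Assigns each read to the unique tag within `max_mismatch` of its
#' barcode window (the first `b` bases for `position = "front"`, the last
#' `b` for `"back"`). Reads matching no tag, matching two or more tags
#' equally, or shorter than `b` bases are unassigned. The partition is
#' complete: every read lands in exactly one output stream.
#'
#' @param reads a [read_set()].
#' @param spec a [barcode_spec()].
#' @return A list of class `"demux_result"`:
#'   * `assignment`: per-read factor over `c(tags, "unassigned")`;
#'   * `streams`: named list of [read_set()]s, one per tag plus
#'     `unassigned`;
#'   * `report`: list of class `"demux_report"` with `total_reads`,
#'     `per_tag` counts, `unassigned`, `barcode_fraction` (percentage of
#'     reads containing an expected barcode, half-up rounded to 1
#'     decimal), `n_too_short`, and an optional `aligned_percentage`
#'     slot (`NA`; for user-supplied alignment rates).
#' @export
demultiplex <- function(reads, spec = barcode_spec()) {
  stopifnot(inherits(reads, "read_set"), inherits(spec, "barcode_spec"))
  n <- nrow(reads)
  levels_ <- c(spec$tags, "unassigned")
  if (n == 0L) {
    assignment <- factor(character(0), levels = levels_)
  } else {
    len <- nchar(reads$bases)
    too_short <- len < spec$b
    window <- if (spec$position == "front") substr(reads$bases, 1L, spec$b)
              else substr(reads$bases, len - spec$b + 1L, len)
    assignment <- rep("unassigned", n)
    ok <- !too_short
    if (any(ok)) {
      if (spec$max_mismatch == 0L) {
        hit <- match(window[ok], spec$tags)
        assignment[ok][!is.na(hit)] <- spec$tags[hit[!is.na(hit)]]
      } else {
        d <- hamming_to_tags(window[ok], spec$tags)
        best <- apply(d, 1L, min)
        nbest <- rowSums(d == best)
        which_best <- max.col(-d, ties.method = "first")
        assign_ok <- best <= spec$max_mismatch & nbest == 1L
        assignment[ok][assign_ok] <- spec$tags[which_best[assign_ok]]
      }
    }
    assignment <- factor(assignment, levels = levels_)
  }
  counts <- table(assignment)
  per_tag <- as.integer(counts[spec$tags])
  names(per_tag) <- spec$tags
  unassigned <- as.integer(counts[["unassigned"]])
  streams <- lapply(levels_, function(lv) {
    idx <- which(assignment == lv)
    read_set(reads$id[idx], reads$bases[idx], reads$quals[idx],
             offset = qual_offset(reads))
  })
  names(streams) <- levels_
  report <- structure(
    list(total_reads = n, per_tag = per_tag, unassigned = unassigned,
         barcode_fraction = if (n == 0L) NA_real_
                            else round_half_up(100 * (n - unassigned) / n, 1),
         n_too_short = if (n == 0L) 0L else sum(nchar(reads$bases) < spec$b),
         aligned_percentage = NA_real_),
    class = "demux_report"
  )
  structure(list(assignment = assignment, streams = streams, report = report),
            class = "demux_result")
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf("Demultiplexing report: %d reads, %.1f%% with an expected barcode\n",
              x$total_reads, x$barcode_fraction))
  for (tag in names(x$per_tag)) cat(sprintf("  %-10s %d\n", tag, x$per_tag[[tag]]))
  cat(sprintf("  %-10s %d\n", "unassigned", x$unassigned))
  invisible(x)
}

#' @export
print.demux_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write demultiplexed streams to FASTQ files
#'
#' One FASTQ per tag plus `unassigned`, named `<prefix>_<tag>.fastq`.
#'
#' @param result a [demultiplex()] result.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_demux <- function(result, prefix) {
  stopifnot(inherits(result, "demux_result"))
  paths <- vapply(names(result$streams), function(tag) {
    p <- sprintf("%s_%s.fastq", prefix, tag)
    write_fastq(result$streams[[tag]], p)
    p
  }, character(1))
  invisible(paths)
}
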