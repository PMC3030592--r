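# FASTQ records: a plain data.frame representation with a declared quality
# encoding offset, plus 4-line-record streaming I/O with per-record
# malformation reporting.

#' Construct an in-memory read set
#'
#' A read set is a data.frame with character columns `id`, `bases`,
#' `quals` and an attached quality-encoding `offset` attribute (33 for
#' Sanger/modern Illumina, 64 for the Genome Analyzer era).
#'
#' @param id read identifiers (without the leading `@`).
#' @param bases base strings over A/C/G/T/N.
#' @param quals quality strings, same lengths as `bases`.
#' @param offset quality encoding offset, 33 or 64.
#' @return A data.frame of class `"read_set"`.
#' @export
read_set <- function(id = character(), bases = character(),
                     quals = character(), offset = 33L) {
  id <- as.character(id); bases <- as.character(bases); quals <- as.character(quals)
  if (length(id) > 1L) {  # scalar bases/quals recycle across ids
    if (length(bases) == 1L) bases <- rep.int(bases, length(id))
    if (length(quals) == 1L) quals <- rep.int(quals, length(id))
  }
  if (length(bases) != length(id) || length(quals) != length(id)) {
    stop("id, bases and quals must have equal length", call. = FALSE)
  }
  if (any(nchar(bases) != nchar(quals))) {
    stop("bases and quals must agree in length for every read", call. = FALSE)
  }
  if (!offset %in% c(33L, 64L)) stop("offset must be 33 or 64", call. = FALSE)
  structure(data.frame(id = id, bases = bases, quals = quals,
                       stringsAsFactors = FALSE),
            offset = as.integer(offset),
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d reads (Phred+%d)\n", nrow(x), attr(x, "offset")))
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}

qual_offset <- function(reads) {
  off <- attr(reads, "offset")
  if (is.null(off)) 33L else off
}

#' Read a FASTQ file into a read set
#'
#' Parses 4-line FASTQ records; a truncated file or a record whose quality
#' string length differs from its base string length is reported with its
#' record number. Qualities are kept as raw strings; `offset` only
#' declares how they are to be interpreted (no auto-detection, which is
#' ambiguous between the 33 and 64 conventions).
#'
#' @param path FASTQ file path (plain text).
#' @param offset declared quality encoding offset, 33 (default) or 64.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, offset = 33L) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
                 length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(read_set(offset = offset))
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seq_ <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop(sprintf("malformed FASTQ record %d: header does not start with '@'", bad_hdr[1L]),
         call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop(sprintf("malformed FASTQ record %d: separator line does not start with '+'",
                 bad_plus[1L]), call. = FALSE)
  }
  bad_len <- which(nchar(seq_) != nchar(qual))
  if (length(bad_len)) {
    stop(sprintf("malformed FASTQ record %d: sequence and quality lengths differ",
                 bad_len[1L]), call. = FALSE)
  }
  read_set(sub("^@", "", hdr), seq_, qual, offset = offset)
}

#' Write a read set to a FASTQ file
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  n <- nrow(reads)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(0L))
  }
  out <- character(4L * n)
  out[4L * seq_len(n) - 3L] <- paste0("@", reads$id)
  out[4L * seq_len(n) - 2L] <- reads$bases
  out[4L * seq_len(n) - 1L] <- "+"
  out[4L * seq_len(n)] <- reads$quals
  writeLines(out, path)
  invisible(n)
}

#' Convert quality strings to Phred integer values
#'
#' @param reads a [read_set()] (or character vector of quality strings with
#'   `offset` given).
#' @param offset encoding offset; defaults to the read set's declared one.
#' @return A list of integer vectors, one per read. Characters outside the
#'   valid Phred range for the declared encoding raise an error.
#' @export
phred_values <- function(reads, offset = NULL) {
  if (inherits(reads, "read_set")) {
    quals <- reads$quals
    if (is.null(offset)) offset <- qual_offset(reads)
  } else {
    quals <- as.character(reads)
    if (is.null(offset)) offset <- 33L
  }
  vals <- lapply(quals, function(q) as.integer(charToRaw(q)) - as.integer(offset))
  bad <- which(vapply(vals, function(v) length(v) && (min(v) < 0L || max(v) > 62L),
                      logical(1)))
  if (length(bad)) {
    stop(sprintf("quality characters outside the Phred+%d range in read %d",
                 offset, bad[1L]), call. = FALSE)
  }
  vals
}

#' Convert a read set between quality encodings
#'
#' Re-encodes quality strings between Phred+33 and Phred+64; Phred-domain
#' statistics are unchanged by construction.
#'
#' @param reads a [read_set()].
#' @param offset target offset, 33 or 64.
#' @return A [read_set()] with the new encoding.
#' @export
convert_offset <- function(reads, offset) {
  stopifnot(inherits(reads, "read_set"))
  if (!offset %in% c(33L, 64L)) stop("offset must be 33 or 64", call. = FALSE)
  from <- qual_offset(reads)
  if (from == offset) return(reads)
  shift <- as.integer(offset) - from
  quals <- vapply(reads$quals, function(q) {
    rawToChar(as.raw(as.integer(charToRaw(q)) + shift))
  }, character(1), USE.NAMES = FALSE)
  read_set(reads$id, reads$bases, quals, offset = offset)
}
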