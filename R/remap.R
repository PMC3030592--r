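# Sequencing-cycle remapping for deferred cluster calling.

#' Build a deferred cluster-calling cycle remap
#'
#' Constructs the bijective old-to-new cycle mapping that moves the first
#' `b` cycles (the barcode / biased cycles) to the back of an `N`-cycle
#' image stack, so that cluster identification — which uses the first
#' cycles of the (renamed) stack — operates on diverse, post-barcode
#' cycles. Original cycles `1..b` become `N-b+1..N`; original cycles
#' `b+1..N` are re-designated `1..N-b`. For a 40-cycle run with 4 deferred
#' cycles, original cycle 1 maps to 37 and original cycle 5 to 1.
#'
#' @param N total number of sequencing cycles.
#' @param b number of deferred (barcode) cycles; `0 <= b < N`. The
#'   Genome Analyzer control software used its first 4 cycles for cluster
#'   calling (5 in later versions), so `b = 4` or `5` are the usual values.
#' @return An object of class `"cycle_remap"`: integer vector `mapping`
#'   (`mapping[old] == new`), its `inverse`, and `N`, `b`.
#' @export
#' @examples
#' m <- build_remap(40, 4)
#' m$mapping[c(1, 4, 5, 40)]  # 37 40 1 36
build_remap <- function(N, b = 4L) {
  stop_if_not_count(N, "N", min = 1L)
  stop_if_not_count(b, "b", min = 0L)
  if (b >= N) stop("'b' must be smaller than the total cycle count N", call. = FALSE)
  N <- as.integer(N); b <- as.integer(b)
  old <- seq_len(N)
  mapping <- ifelse(old <= b, N - b + old, old - b)
  inverse <- integer(N)
  inverse[mapping] <- old
  structure(list(N = N, b = b, mapping = as.integer(mapping),
                 inverse = as.integer(inverse)),
            class = "cycle_remap")
}

#' @export
print.cycle_remap <- function(x, ...) {
  cat(sprintf("Cycle remap: %d cycles, %d deferred (old 1 -> new %d, old %d -> new %d)\n",
              x$N, x$b, x$mapping[1], min(x$b + 1L, x$N), x$mapping[min(x$b + 1L, x$N)]))
  invisible(x)
}

#' Invert a cycle remap
#'
#' @param remap a [build_remap()] result.
#' @return The inverse `"cycle_remap"` (applying both is the identity).
#' @export
invert_remap <- function(remap) {
  stopifnot(inherits(remap, "cycle_remap"))
  structure(list(N = remap$N, b = remap$N - remap$b,
                 mapping = remap$inverse, inverse = remap$mapping),
            class = "cycle_remap")
}

#' Apply a cycle remap to cycle numbers
#'
#' @param remap a [build_remap()] result.
#' @param cycles integer vector of original cycle numbers in `1..N`.
#' @return The remapped cycle numbers.
#' @export
remap_cycles <- function(remap, cycles) {
  stopifnot(inherits(remap, "cycle_remap"))
  if (any(cycles < 1L | cycles > remap$N | cycles != floor(cycles))) {
    stop(sprintf("cycles must be integers in 1..%d", remap$N), call. = FALSE)
  }
  remap$mapping[as.integer(cycles)]
}
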