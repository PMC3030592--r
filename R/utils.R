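# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed sequencing yield tables
#' use conventional half-up rounding, so derived percentages are computed
#' with this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(71.867, 1)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a per-repetition seed from a master seed. A fixed prime stride
# keeps earlier repetitions stable when more are appended.
derive_seed <- function(master, rep) {
  as.integer((as.numeric(master) + as.numeric(rep) * 7919) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
}
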