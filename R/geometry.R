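#' Flow-cell tile geometry
#'
#' One imaged sub-region (tile) of a flow-cell lane. The default dimensions
#' are those of a Genome Analyzer IIx tile, 1888 x 2048 pixels.
#'
#' `boundary_mode` controls how distances near tile edges are treated:
#' `"rectangle"` is a physical tile (points near an edge simply have fewer
#' neighbours); `"periodic"` wraps distances torus-fashion so that the
#' homogeneous Poisson closed form applies without edge corrections.
#'
#' @param width_px,height_px tile dimensions in imaged pixels.
#' @param boundary_mode `"rectangle"` (default) or `"periodic"`.
#' @return An object of class `"tile_geometry"`.
#' @export
#' @examples
#' tile_geometry()
#' tile_geometry(boundary_mode = "periodic")
tile_geometry <- function(width_px = 1888, height_px = 2048,
                          boundary_mode = c("rectangle", "periodic")) {
  boundary_mode <- match.arg(boundary_mode)
  if (!is.numeric(width_px) || width_px <= 0 || !is.numeric(height_px) || height_px <= 0) {
    stop("tile dimensions must be positive", call. = FALSE)
  }
  structure(
    list(width_px = as.numeric(width_px), height_px = as.numeric(height_px),
         boundary_mode = boundary_mode),
    class = "tile_geometry"
  )
}

#' @export
print.tile_geometry <- function(x, ...) {
  cat(sprintf("Tile geometry: %g x %g px (%s boundaries)\n",
              x$width_px, x$height_px, x$boundary_mode))
  invisible(x)
}

tile_area <- function(geometry) geometry$width_px * geometry$height_px

#' Initial-sequence diversity profile
#'
#' The set of initially biased sequences (IBS) present during the
#' cluster-calling cycles, with their proportions. Two clusters drawn from
#' the profile share the same cluster-calling bases with probability
#' \eqn{\sum_i p_i^2} (the match probability), the diversity statistic that
#' drives same-sequence collision rejection.
#'
#' An effectively unlimited-diversity library is represented by the
#' sentinel returned by [unbiased_profile()], whose match probability is 0.
#'
#' @param tags character vector of distinct tag sequences over A/C/G/T, all
#'   of the same length (the cluster-calling bases).
#' @param proportions tag proportions; non-negative, summing to 1. Defaults
#'   to equal proportions.
#' @param id optional profile label used in sweep tables.
#' @return An object of class `"diversity_profile"` with fields `tags`,
#'   `proportions`, `k`, `tag_length` and `match_probability`.
#' @seealso [unbiased_profile()], [equal_profile()]
#' @export
#' @examples
#' diversity_profile(c("CATT", "GTAT", "ACGT", "TGCT"))
#' diversity_profile(c("CATG"))  # single restriction-site start
diversity_profile <- function(tags, proportions = NULL, id = NULL) {
  tags <- as.character(tags)
  if (length(tags) == 0L) {
    stop("empty tag list; use unbiased_profile() for the unlimited-diversity sentinel",
         call. = FALSE)
  }
  if (anyDuplicated(tags)) stop("tags must be unique", call. = FALSE)
  if (length(unique(nchar(tags))) != 1L) stop("tags must share one length", call. = FALSE)
  if (any(grepl("[^ACGT]", tags))) stop("tags must be over {A,C,G,T}", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / length(tags), length(tags))
  if (length(proportions) != length(tags) || any(proportions < 0)) {
    stop("proportions must be non-negative, one per tag", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1", call. = FALSE)
  structure(
    list(tags = tags, proportions = as.numeric(proportions),
         k = length(tags), tag_length = nchar(tags[[1L]]),
         match_probability = sum(proportions^2),
         id = if (is.null(id)) sprintf("k=%d", length(tags)) else as.character(id)),
    class = "diversity_profile"
  )
}

#' Unlimited-diversity sentinel profile
#'
#' Represents an unbiased library: no two clusters are expected to share
#' their cluster-calling bases, so only hard (distance) collisions apply.
#' Encoded by `match_probability = 0`; when placed, every cluster receives
#' a distinct pseudo-tag.
#'
#' For true finite-alphabet sampling instead (tags drawn uniformly from all
#' `4^L` sequences of length `L`, giving match probability `4^-L`), use
#' [equal_profile()] with `enumerate_unbiased()`.
#'
#' @param id profile label.
#' @return A `"diversity_profile"` with `match_probability = 0`.
#' @export
unbiased_profile <- function(id = "unbiased") {
  structure(
    list(tags = character(0), proportions = numeric(0),
         k = Inf, tag_length = NA_integer_, match_probability = 0,
         id = as.character(id)),
    class = "diversity_profile"
  )
}

#' Equal-proportion profile of k arbitrary tags
#'
#' Convenience constructor for the simulation's diversity sweep: `k`
#' distinct placeholder tags in equal proportions, giving match
#' probability `1/k`.
#'
#' @param k number of initially biased sequences.
#' @param tag_length tag length in bases.
#' @return A `"diversity_profile"`.
#' @export
#' @examples
#' equal_profile(4)$match_probability  # 0.25
equal_profile <- function(k, tag_length = 4) {
  stop_if_not_count(k, "k", min = 1L)
  alphabet <- c("A", "C", "G", "T")
  if (k > 4^tag_length) stop("k exceeds the number of distinct tags", call. = FALSE)
  # deterministic distinct tags: base-4 expansion of 0..k-1
  tags <- vapply(seq_len(k) - 1L, function(i) {
    digits <- integer(tag_length)
    for (j in seq_len(tag_length)) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste(alphabet[digits + 1L], collapse = "")
  }, character(1))
  diversity_profile(tags, id = sprintf("k=%d", k))
}

#' All tags of a given length, in equal proportions
#'
#' The finite-alphabet alternative to the [unbiased_profile()] sentinel:
#' every one of the `4^L` possible tag sequences, equally likely, so the
#' match probability is `4^-L` (1/256 for the default 4 cluster-calling
#' cycles).
#'
#' @param tag_length tag length in bases (kept small; `4^L` tags are built).
#' @return A `"diversity_profile"`.
#' @export
enumerate_unbiased <- function(tag_length = 4) {
  p <- equal_profile(4^tag_length, tag_length = tag_length)
  p$id <- sprintf("enumerated_L%d", tag_length)
  p
}

#' @export
print.diversity_profile <- function(x, ...) {
  if (x$match_probability == 0) {
    cat("Diversity profile: unbiased sentinel (match probability 0)\n")
  } else {
    cat(sprintf("Diversity profile '%s': %d tag(s), match probability %.4g\n",
                x$id, x$k, x$match_probability))
    if (x$k <= 8) cat("  tags:", paste(x$tags, collapse = " "),
                      sprintf("(p = %s)\n", paste(signif(x$proportions, 3), collapse = " ")))
  }
  invisible(x)
}

#' Geometric resolvability rules
#'
#' Two-radius proxy for the instrument's cluster purity filtering: cluster
#' centres within `r_hard` pixels of each other are never resolvable
#' regardless of sequence; centres within `r_soft` pixels are rejected only
#' when the two clusters share the same cluster-calling bases (the image
#' analysis cannot separate two spots that look identical over the calling
#' cycles). Distance comparisons are closed (`<=`): a pair at exactly the
#' radius collides.
#'
#' @param r_hard hard collision radius in pixels (default 1.0).
#' @param r_soft same-tag collision radius in pixels (default 2.5).
#' @return An object of class `"resolvability_rules"`.
#' @export
resolvability_rules <- function(r_hard = 1.0, r_soft = 2.5) {
  if (!(r_hard > 0) || !(r_soft > r_hard)) {
    stop("need 0 < r_hard < r_soft", call. = FALSE)
  }
  structure(list(r_hard = as.numeric(r_hard), r_soft = as.numeric(r_soft)),
            class = "resolvability_rules")
}

#' @export
print.resolvability_rules <- function(x, ...) {
  cat(sprintf("Resolvability rules: hard <= %g px (any pair), soft <= %g px (same tag)\n",
              x$r_hard, x$r_soft))
  invisible(x)
}
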