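# Monte-Carlo simulation of cluster placement and resolvability.

#' Place clusters randomly on a tile
#'
#' Draws `n` cluster centres i.i.d. uniform over the tile rectangle and
#' assigns each an initial-sequence tag drawn i.i.d. from the diversity
#' profile's proportions. Fully deterministic in `(n, geometry, profile,
#' seed)`; the caller's RNG stream is left untouched.
#'
#' For the [unbiased_profile()] sentinel every cluster receives a distinct
#' pseudo-tag (encoded internally so the same-sequence rule never fires).
#'
#' @param n number of clusters to place.
#' @param geometry a [tile_geometry()].
#' @param profile a [diversity_profile()].
#' @param seed integer RNG seed (required; there is no hidden global state).
#' @return An object of class `"cluster_field"`: list with numeric `x`, `y`
#'   (pixels) and integer `tag_index` (1-based into `profile$tags`; `NA`
#'   for the unbiased sentinel), plus the geometry and profile used.
#' @export
#' @examples
#' f <- place_clusters(1000, tile_geometry(), equal_profile(4), seed = 1)
#' table(f$tag_index)
place_clusters <- function(n, geometry = tile_geometry(),
                           profile = equal_profile(1), seed) {
  stop_if_not_count(n, "n")
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(inherits(geometry, "tile_geometry"), inherits(profile, "diversity_profile"))
  n <- as.integer(n)
  dat <- with_seed(seed, {
    x <- runif(n, 0, geometry$width_px)
    y <- runif(n, 0, geometry$height_px)
    tag <- if (profile$match_probability == 0) {
      rep(NA_integer_, n)
    } else if (profile$k == 1L) {
      rep(1L, n)
    } else {
      sample.int(profile$k, n, replace = TRUE, prob = profile$proportions)
    }
    list(x = x, y = y, tag = tag)
  })
  structure(
    list(x = dat$x, y = dat$y, tag_index = dat$tag,
         geometry = geometry, profile = profile, seed = as.integer(seed)),
    class = "cluster_field"
  )
}

#' Construct a cluster field from explicit coordinates
#'
#' Builds a `"cluster_field"` from given coordinates and tag indices, for
#' constructed test cases and external data; [place_clusters()] is the
#' random generator. Coordinates must lie inside the tile.
#'
#' @param x,y cluster centre coordinates in pixels.
#' @param tag_index 1-based tag indices into `profile$tags`, or `NA` for
#'   distinct pseudo-tags (unbiased sentinel).
#' @param geometry a [tile_geometry()].
#' @param profile the [diversity_profile()] the tags refer to.
#' @param seed optional seed annotation.
#' @return A `"cluster_field"`.
#' @export
cluster_field <- function(x, y, tag_index = rep(NA_integer_, length(x)),
                          geometry = tile_geometry(),
                          profile = unbiased_profile(), seed = NA_integer_) {
  if (length(y) != length(x) || length(tag_index) != length(x)) {
    stop("x, y and tag_index must agree in length", call. = FALSE)
  }
  if (length(x) && (any(x < 0 | x >= geometry$width_px) ||
                    any(y < 0 | y >= geometry$height_px))) {
    stop("coordinates must lie inside the tile", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 tag_index = as.integer(tag_index),
                 geometry = geometry, profile = profile,
                 seed = as.integer(seed)),
            class = "cluster_field")
}

#' @export
print.cluster_field <- function(x, ...) {
  cat(sprintf("Cluster field: %d clusters on %g x %g px tile (profile '%s')\n",
              length(x$x), x$geometry$width_px, x$geometry$height_px, x$profile$id))
  invisible(x)
}

#' Classify clusters as resolvable or not
#'
#' Applies the two-radius resolvability rules to a placed cluster field: a
#' cluster is usable iff no other cluster lies within `r_hard` pixels
#' (Euclidean, closed comparison) and no cluster sharing its tag lies
#' within `r_soft` pixels. Both members of a colliding pair are rejected.
#' Under periodic boundaries distances wrap torus-fashion.
#'
#' Internally accelerated by spatial grid binning (cell size >= `r_soft`),
#' which is exactly equivalent to the all-pairs evaluation.
#'
#' @param field a [place_clusters()] result.
#' @param rules a [resolvability_rules()].
#' @param geometry tile geometry; defaults to the field's own.
#' @return A list of class `"tile_sim_result"`: `usable` (logical mask,
#'   one per cluster), `n_placed`, `n_usable`, `usable_fraction`
#'   (defined as 1 for an empty field), `per_tag_usable` and `seed`.
#' @export
#' @examples
#' f <- place_clusters(200000, tile_geometry(), equal_profile(1), seed = 7)
#' r <- classify_resolvable(f, resolvability_rules())
#' r$usable_fraction
classify_resolvable <- function(field, rules = resolvability_rules(),
                                geometry = field$geometry) {
  stopifnot(inherits(field, "cluster_field"), inherits(rules, "resolvability_rules"))
  if (length(field$x) &&
      (any(field$x < 0 | field$x >= geometry$width_px) ||
       any(field$y < 0 | field$y >= geometry$height_px))) {
    stop("cluster coordinates fall outside the tile", call. = FALSE)
  }
  n <- length(field$x)
  tag <- field$tag_index
  tag_c <- if (n == 0L) integer(0) else ifelse(is.na(tag), -1L, tag - 1L)
  usable <- .classify_grid(as.numeric(field$x), as.numeric(field$y),
                           as.integer(tag_c),
                           rules$r_hard, rules$r_soft,
                           geometry$width_px, geometry$height_px,
                           geometry$boundary_mode == "periodic")
  per_tag <- if (all(is.na(tag))) {
    integer(0)
  } else {
    nbins <- if (is.finite(field$profile$k)) field$profile$k else max(tag, na.rm = TRUE)
    tabulate(tag[usable], nbins = nbins)
  }
  structure(
    list(usable = usable,
         n_placed = n,
         n_usable = sum(usable),
         usable_fraction = if (n == 0L) 1 else sum(usable) / n,
         per_tag_usable = per_tag,
         seed = field$seed),
    class = "tile_sim_result"
  )
}

#' @export
print.tile_sim_result <- function(x, ...) {
  cat(sprintf("Tile simulation: %d / %d clusters usable (%.1f%%)\n",
              x$n_usable, x$n_placed, 100 * x$usable_fraction))
  invisible(x)
}

#' Simulate one tile at a given cluster density
#'
#' Runs `reps` independent placement + classification rounds at `density`
#' clusters per tile. Per-repetition seeds are derived deterministically
#' from the master seed with a fixed stride, so increasing `reps` never
#' changes earlier repetitions.
#'
#' @param density clusters per tile (non-negative; rounded to an integer
#'   count of placed clusters).
#' @param geometry a [tile_geometry()].
#' @param profile a [diversity_profile()].
#' @param rules a [resolvability_rules()].
#' @param reps number of independent repetitions (default 10).
#' @param seed master integer seed.
#' @return A list of `reps` [classify_resolvable()] results
#'   (`"tile_sim_result"`), with class `"tile_sim"`.
#' @export
simulate_tile <- function(density, geometry = tile_geometry(),
                          profile = equal_profile(1),
                          rules = resolvability_rules(),
                          reps = 10, seed) {
  if (!is.numeric(density) || length(density) != 1L || density < 0) {
    stop("'density' must be a single non-negative number", call. = FALSE)
  }
  stop_if_not_count(reps, "reps", min = 1L)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  n <- as.integer(round(density))
  out <- lapply(seq_len(reps), function(r) {
    f <- place_clusters(n, geometry, profile, seed = derive_seed(seed, r))
    classify_resolvable(f, rules, geometry)
  })
  class(out) <- "tile_sim"
  out
}

#' Sweep cluster density and diversity
#'
#' Simulates every (density, profile) combination and returns a long-format
#' table of usable-cluster summaries, the simulation counterpart of the
#' usable-sequence-vs-density curves. The default density grid spans
#' 125,000-300,000 clusters per tile, the plausible operating band of a
#' GAIIx flow cell.
#'
#' @param densities numeric vector of cluster densities per tile.
#' @param profiles list of [diversity_profile()] objects (a single profile
#'   is accepted).
#' @param geometry,rules,reps,seed as in [simulate_tile()].
#' @param tiles_per_lane tiles per flow-cell lane used for the lane
#'   extrapolation column (default 120).
#' @return A data.frame with columns `density_per_tile`, `profile_id`, `k`,
#'   `match_probability`, `reps`, `mean_usable_fraction`,
#'   `se_usable_fraction` (Monte-Carlo standard error of the mean),
#'   `mean_usable_per_tile`, `lane_estimate`, `source`.
#' @export
#' @examples
#' density_sweep(c(1000, 2000), list(equal_profile(1), equal_profile(4)),
#'               reps = 2, seed = 1)
density_sweep <- function(densities = seq(125000, 300000, by = 25000),
                          profiles = lapply(c(1, 2, 4, 6), equal_profile),
                          geometry = tile_geometry(),
                          rules = resolvability_rules(),
                          reps = 10, seed = 1, tiles_per_lane = 120) {
  if (inherits(profiles, "diversity_profile")) profiles <- list(profiles)
  if (length(densities) == 0L || length(profiles) == 0L) {
    stop("need at least one density and one profile", call. = FALSE)
  }
  rows <- list()
  for (pi in seq_along(profiles)) {
    p <- profiles[[pi]]
    for (d in densities) {
      sim <- simulate_tile(d, geometry, p, rules, reps = reps,
                           seed = derive_seed(seed, pi * 100003L))
      fr <- vapply(sim, `[[`, numeric(1), "usable_fraction")
      nu <- vapply(sim, `[[`, numeric(1), "n_usable")
      rows[[length(rows) + 1L]] <- data.frame(
        density_per_tile = d,
        profile_id = p$id,
        k = if (is.finite(p$k)) p$k else NA_integer_,
        match_probability = p$match_probability,
        reps = reps,
        mean_usable_fraction = mean(fr),
        se_usable_fraction = if (reps > 1) sd(fr) / sqrt(reps) else NA_real_,
        mean_usable_per_tile = mean(nu),
        lane_estimate = extrapolate_to_lane(mean(nu), tiles_per_lane),
        source = "simulation",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Extrapolate per-tile usable clusters to a whole lane
#'
#' Expected usable clusters for an entire flow-cell lane, as usable
#' clusters on one tile times the number of tiles (an expectation, not a
#' re-simulation).
#'
#' @param n_usable usable clusters per tile (a number, or a
#'   `"tile_sim_result"`).
#' @param tiles_per_lane tiles per lane (default 120).
#' @return Expected usable clusters per lane.
#' @export
#' @examples
#' extrapolate_to_lane(183333, 120)
extrapolate_to_lane <- function(n_usable, tiles_per_lane = 120) {
  stop_if_not_count(tiles_per_lane, "tiles_per_lane", min = 1L)
  if (inherits(n_usable, "tile_sim_result")) n_usable <- n_usable$n_usable
  if (!is.numeric(n_usable) || any(n_usable < 0)) {
    stop("'n_usable' must be non-negative", call. = FALSE)
  }
  n_usable * tiles_per_lane
}
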