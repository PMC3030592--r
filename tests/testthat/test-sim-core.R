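# Cluster placement and resolvability classification.

test_that("place_clusters is deterministic, in-bounds and uniform", {
  g <- tile_geometry()
  p <- equal_profile(4)

  expect_equal(length(place_clusters(0, g, p, seed = 1)$x), 0)

  f1 <- place_clusters(1000, g, p, seed = 42)
  f2 <- place_clusters(1000, g, p, seed = 42)
  expect_identical(f1$x, f2$x)
  expect_identical(f1$tag_index, f2$tag_index)
  expect_false(identical(f1$x, place_clusters(1000, g, p, seed = 43)$x))

  expect_true(all(f1$x >= 0 & f1$x < g$width_px))
  expect_true(all(f1$y >= 0 & f1$y < g$height_px))

  single <- place_clusters(1000, g, equal_profile(1), seed = 1)
  expect_true(all(single$tag_index == 1L))

  # uniform mean: SE of the mean of U(0, W) is W / sqrt(12 n)
  n <- 100000
  f <- place_clusters(n, g, p, seed = 7)
  expect_lt(abs(mean(f$x) - g$width_px / 2), 3 * g$width_px / sqrt(12 * n))
  expect_lt(abs(mean(f$y) - g$height_px / 2), 3 * g$height_px / sqrt(12 * n))

  expect_error(place_clusters(-1, g, p, seed = 1), "integer")
  expect_error(place_clusters(10, g, p), "seed")
})

test_that("placement respects profile proportions and the unbiased sentinel", {
  skew <- diversity_profile(c("CATT", "GTAT"), c(0.8, 0.2))
  f <- place_clusters(20000, tile_geometry(), skew, seed = 3)
  obs <- mean(f$tag_index == 1L)
  expect_lt(abs(obs - 0.8), 3 * sqrt(0.8 * 0.2 / 20000))

  fu <- place_clusters(100, tile_geometry(), unbiased_profile(), seed = 1)
  expect_true(all(is.na(fu$tag_index)))
})

test_that("pairwise resolvability rules match their stated semantics", {
  g <- tile_geometry()
  rules <- resolvability_rules(1.0, 2.5)
  p2 <- equal_profile(2)

  lone <- cluster_field(10, 10, 1L, g, p2)
  expect_true(all(classify_resolvable(lone, rules)$usable))

  pair_at <- function(d, tags) {
    cluster_field(c(100, 100 + d), c(100, 100), tags, g, p2)
  }
  # different tags at 2.0 px: outside the hard radius, soft rule inapplicable
  expect_true(all(classify_resolvable(pair_at(2.0, c(1L, 2L)), rules)$usable))
  # any tags at 0.5 px: hard collision, both rejected
  expect_false(any(classify_resolvable(pair_at(0.5, c(1L, 2L)), rules)$usable))
  # same tag at 2.0 px: soft collision, both rejected
  expect_false(any(classify_resolvable(pair_at(2.0, c(1L, 1L)), rules)$usable))
  # closed comparison: ties at exactly the radius collide
  expect_false(any(classify_resolvable(pair_at(1.0, c(1L, 2L)), rules)$usable))
  expect_false(any(classify_resolvable(pair_at(2.5, c(1L, 1L)), rules)$usable))
  # just outside both radii
  expect_true(all(classify_resolvable(pair_at(2.5001, c(1L, 1L)), rules)$usable))
})

test_that("grid classification equals the all-pairs oracle on random fields", {
  rules <- resolvability_rules(1.0, 2.5)
  for (trial in 1:20) {
    mode <- if (trial %% 2L) "rectangle" else "periodic"
    g <- tile_geometry(150, 120, boundary_mode = mode)
    n <- 50 * trial
    f <- place_clusters(n, g, equal_profile(1 + trial %% 4), seed = 1000 + trial)
    got <- classify_resolvable(f, rules)$usable
    expect_identical(got, brute_classify(f, rules), label = paste("trial", trial))
  }
})

test_that("classification invariants hold", {
  rules <- resolvability_rules(1.0, 2.5)
  g <- tile_geometry(200, 200, boundary_mode = "periodic")
  p <- equal_profile(3)
  f <- place_clusters(800, g, p, seed = 5)
  base <- classify_resolvable(f, rules)

  # adding a cluster never rescues a non-usable cluster
  f_plus <- cluster_field(c(f$x, 100), c(f$y, 100), c(f$tag_index, 1L), g, p)
  plus <- classify_resolvable(f_plus, rules)
  expect_true(all(plus$usable[seq_along(f$x)] <= base$usable))

  # relabelling tags leaves the mask unchanged
  perm <- c(3L, 1L, 2L)
  f_perm <- cluster_field(f$x, f$y, perm[f$tag_index], g, p)
  expect_identical(classify_resolvable(f_perm, rules)$usable, base$usable)

  # rigid translation in periodic mode leaves the usable fraction unchanged
  f_shift <- cluster_field((f$x + 37.3) %% g$width_px, (f$y + 91.1) %% g$height_px,
                           f$tag_index, g, p)
  expect_equal(classify_resolvable(f_shift, rules)$usable_fraction,
               base$usable_fraction)

  # with r_soft -> r_hard the profile is irrelevant
  tight <- resolvability_rules(1.0, 1.0 + 1e-12)
  f1 <- cluster_field(f$x, f$y, rep(1L, length(f$x)), g, equal_profile(1))
  expect_identical(classify_resolvable(f1, tight)$usable,
                   classify_resolvable(f, tight)$usable)
})

test_that("tile_sim_result bookkeeping is consistent", {
  f <- place_clusters(5000, tile_geometry(400, 400), equal_profile(4), seed = 9)
  r <- classify_resolvable(f)
  expect_identical(r$n_usable, sum(r$usable))
  expect_equal(r$usable_fraction, r$n_usable / r$n_placed)
  expect_identical(sum(r$per_tag_usable), r$n_usable)
  empty <- classify_resolvable(place_clusters(0, seed = 1))
  expect_equal(empty$usable_fraction, 1)
})

test_that("simulate_tile derives stable per-rep seeds and responds to diversity", {
  g <- tile_geometry()
  one <- simulate_tile(1, g, equal_profile(1), reps = 3, seed = 1)
  expect_true(all(vapply(one, `[[`, numeric(1), "usable_fraction") == 1))

  s5 <- simulate_tile(5000, g, equal_profile(2), reps = 5, seed = 2)
  s8 <- simulate_tile(5000, g, equal_profile(2), reps = 8, seed = 2)
  expect_identical(lapply(s5, `[[`, "usable"), lapply(s8[1:5], `[[`, "usable"))

  # more initial diversity -> more usable clusters at fixed density
  k1 <- simulate_tile(200000, g, equal_profile(1), reps = 20, seed = 30)
  k4 <- simulate_tile(200000, g, equal_profile(4), reps = 20, seed = 30)
  expect_gt(mean(vapply(k4, `[[`, numeric(1), "usable_fraction")),
            mean(vapply(k1, `[[`, numeric(1), "usable_fraction")))
})

test_that("density_sweep covers the operating band and orders by match probability", {
  zero <- density_sweep(0, list(equal_profile(1), equal_profile(4)),
                        reps = 2, seed = 1)
  expect_true(all(zero$mean_usable_fraction == 1))

  expect_true(all(c(125000, 300000) %in%
                    eval(formals(density_sweep)$densities)))

  profs <- list(equal_profile(1), equal_profile(2), equal_profile(6))
  sw <- density_sweep(150000, profs, reps = 5, seed = 4)
  ord <- order(sw$match_probability, decreasing = TRUE)
  expect_true(all(diff(sw$mean_usable_fraction[ord]) > 0))
  expect_named(sw, c("density_per_tile", "profile_id", "k", "match_probability",
                     "reps", "mean_usable_fraction", "se_usable_fraction",
                     "mean_usable_per_tile", "lane_estimate", "source"))
})

test_that("lane extrapolation is plain expectation scaling", {
  expect_equal(extrapolate_to_lane(0, 120), 0)
  expect_equal(extrapolate_to_lane(183333, 120), 21999960)
  expect_equal(extrapolate_to_lane(100, 1), 100)
  expect_error(extrapolate_to_lane(10, 0), "integer")
})
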