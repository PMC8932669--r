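test_that("jaw outlines are simple, closed and deterministic", {
  p <- jaw_params(4, 0, 0.3, 0, 600)
  jaw <- generate_jaw_outline(p, seed = 1)
  expect_equal(nrow(jaw), 600)
  expect_false(detect_self_intersection(jaw))
  expect_gt(abs(outline_area(jaw)), 0)
  jaw2 <- generate_jaw_outline(p, seed = 7)
  jaw3 <- generate_jaw_outline(p, seed = 7)
  expect_identical(jaw2, jaw3)
})

test_that("dorsal curvature moves the dorsal margin across the chord", {
  mean_dorsal_rel_chord <- function(cv) {
    jaw <- generate_jaw_outline(jaw_params(4, cv, 0, 0, 600), seed = 1)
    p <- cbind(jaw$x, jaw$y)
    i1 <- which.min(p[, 1]); i2 <- which.max(p[, 1])
    chord <- function(xq) {
      p[i1, 2] + (xq - p[i1, 1]) * (p[i2, 2] - p[i1, 2]) / (p[i2, 1] - p[i1, 1])
    }
    # dorsal margin: the highest vertex within each of 20 x-slices
    cuts <- cut(p[, 1], 20)
    top <- vapply(split(seq_len(nrow(p)), cuts), function(ix) {
      ix[which.max(p[ix, 2])]
    }, integer(1))
    mean(p[top, 2] - chord(p[top, 1]))
  }
  expect_gt(mean_dorsal_rel_chord(-0.4), 0)  # convex: above the chord
  expect_lt(mean_dorsal_rel_chord(0.4), 0)   # concave: below the chord
})

test_that("parameters outside the valid box are refused", {
  expect_error(generate_jaw_outline(jaw_params(10, 0, 0.3, 0, 600)),
               "valid box")
  expect_error(generate_jaw_outline(jaw_params(4, 0.9, 0.3, 0, 600)),
               "valid box")
  expect_error(generate_jaw_outline(jaw_params(4, 0, 0.3, 0.5, 600)),
               "valid box")
  expect_error(generate_jaw_outline(jaw_params(4, 0, 0.3, 0, 50)),
               "valid box")
})

test_that("outline generator stays simple across the valid parameter box", {
  grid <- expand.grid(
    ratio = c(1.5, 3, 5.5, 8),
    cv = c(-0.5, -0.2, 0, 0.25, 0.5),
    taper = c(0, 0.4, 0.8),
    rough = c(0, 0.02)
  )
  for (k in seq_len(nrow(grid))) {
    jaw <- generate_jaw_outline(
      jaw_params(grid$ratio[k], grid$cv[k], grid$taper[k], grid$rough[k],
                 200),
      seed = k
    )
    expect_false(detect_self_intersection(jaw),
                 label = sprintf("simple outline at row %d", k))
  }
})

test_that("taxon sets have valid ranges, outlines and determinism", {
  bins <- devonian_bins()
  taxa <- generate_taxon_set(30, bins, seed = 3, n_points = 200)
  expect_equal(nrow(taxa), 30)
  expect_true(all(taxa$first_appearance >= taxa$last_appearance))
  expect_true(all(taxa$first_appearance <= max(bins$older_bound)))
  expect_true(all(taxa$last_appearance >= min(bins$younger_bound)))
  expect_true(all(!purrr::map_lgl(taxa$outline, detect_self_intersection)))
  expect_true(all(taxa$clade %in% c("Sarcopterygii", "Placodermi",
                                    "Chondrichthyes", "Actinopterygii")))
  # every range overlaps at least one bin
  memb <- time_bin_taxa(taxa, bins)
  expect_true(all(taxa$taxon_id %in% memb$taxon_id))
  taxa2 <- generate_taxon_set(30, bins, seed = 4, n_points = 200)
  expect_equal(nrow(taxa2), 30)
  expect_false(identical(taxa$length_depth_ratio, taxa2$length_depth_ratio))
  expect_error(generate_taxon_set(1), "at least 2")
})

test_that("timed trees are binary, positive-length and reproducible", {
  tr <- generate_timed_tree(2, root_age = 100, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_true(all(ape::node.depth.edgelength(tr) <= 100 + 1e-9))
  tr99 <- generate_timed_tree(99, root_age = 120, seed = 5)
  expect_equal(tr99$Nnode, 98)  # binary rooted
  expect_true(all(tr99$edge.length > 0))
  expect_identical(ape::write.tree(generate_timed_tree(20, 50, seed = 9)),
                   ape::write.tree(generate_timed_tree(20, 50, seed = 9)))
  expect_error(generate_timed_tree(1), "at least 2")
  expect_error(generate_timed_tree(5, root_age = -1), "positive")
})

test_that("Brownian simulation has the right degenerate and variance behaviour", {
  tr <- generate_timed_tree(6, root_age = 10, seed = 2)
  z <- simulate_bm_traits(tr, c(1.5, -2), matrix(0, 2, 2), seed = 1)
  expect_true(all(abs(z$tip_states[, 1] - 1.5) == 0))
  expect_true(all(abs(z$node_states[, 2] + 2) == 0))
  # increment variance ~ branch length on a 2-tip tree
  tr2 <- ape::read.tree(text = "(A:2.5,B:2.5);")
  tips <- vapply(1:10000, function(i) {
    simulate_bm_traits(tr2, 0, 1, seed = i)$tip_states[1, 1]
  }, numeric(1))
  expect_equal(stats::var(tips), 2.5, tolerance = 0.05 * 2.5)
  expect_identical(simulate_bm_traits(tr, 0, 1, seed = 3)$tip_states,
                   simulate_bm_traits(tr, 0, 1, seed = 3)$tip_states)
  expect_error(simulate_bm_traits(tr, c(0, 0),
                                  matrix(c(1, 2, 2, 1), 2, 2), seed = 1),
               "semi-definite")
})

test_that("tip covariance equals rate times shared path length", {
  # 3-tip tree with known structure: ((A:1,B:1):1,C:2)
  tr <- read_timed_tree("((A:1,B:1):1,C:2);")
  sims <- vapply(1:4000, function(i) {
    simulate_bm_traits(tr, 0, 1, seed = i)$tip_states[, 1]
  }, numeric(3))
  cv <- stats::cov(t(sims))
  expect_equal(cv["A", "B"], 1, tolerance = 0.12)     # shared path 1
  expect_equal(cv["A", "A"], 2, tolerance = 0.15)     # depth 2
  expect_lt(abs(cv["A", "C"]), 0.12)                  # no shared path
})
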