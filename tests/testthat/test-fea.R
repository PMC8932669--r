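rect_outline <- function(L = 4, W = 0.25, y0 = -W / 2) {
  as_outline(data.frame(x = c(0, L, L, 0), y = c(y0, y0, y0 + W, y0 + W)))
}

test_that("landmarks sit at the ends of the near-vertical-normal margin", {
  m <- suppressWarnings(triangulate(rect_outline(2, 1, 0), 400))
  lm <- identify_landmarks(m)
  jp <- m$nodes[lm$joint_node, ]; bp <- m$nodes[lm$bite_node, ]
  # top edge has exactly vertical normals; joint left end, bite right end
  expect_equal(jp[2], 1, tolerance = 1e-9)
  expect_equal(bp[2], 1, tolerance = 1e-9)
  expect_lt(jp[1], 0.3)
  expect_gt(bp[1], 1.7)
})

test_that("circle landmarks fall inside the 30-degree polar window", {
  m <- triangulate(circle_outline(400), 800)
  lm <- identify_landmarks(m, vertical_tolerance_deg = 30)
  ang <- function(i) atan2(m$nodes[i, 2], m$nodes[i, 1]) * 180 / pi
  # radial normals: candidates have polar angle in [60, 120]
  expect_gte(ang(lm$joint_node), 60 - 2)
  expect_lte(ang(lm$joint_node), 120 + 2)
  expect_gte(ang(lm$bite_node), 60 - 2)
  expect_lte(ang(lm$bite_node), 120 + 2)
  expect_gt(m$nodes[lm$bite_node, 1], m$nodes[lm$joint_node, 1])
})

test_that("landmark identification is orientation-dependent by contract", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 400))
  base <- identify_landmarks(m)
  rot <- rotate_outline(jaw, pi / 2)
  m90 <- suppressWarnings(triangulate(rot, 400))
  res <- tryCatch(identify_landmarks(m90), error = function(e) NULL)
  if (is.null(res)) {
    succeed("rotated mesh has no near-vertical margin")
  } else {
    expect_false(isTRUE(all.equal(
      m$nodes[base$joint_node, ], m90$nodes[res$joint_node, ]
    )))
  }
})

test_that("rotational efficiency matches the rectangle closed form", {
  # unit-area 4 x 0.25 rectangle, joint/bite at edge midpoints:
  # I = L^2/3 + W^2/12, RE = L * sqrt(2 / I)
  m <- suppressWarnings(triangulate(rect_outline(4, 0.25), 2500))
  re <- rotational_efficiency(m, c(0, 0), c(4, 0))
  I_exact <- 4^2 / 3 + 0.25^2 / 12
  expect_equal(re, 4 * sqrt(2 / I_exact), tolerance = 5e-3)
  # doubling density divides RE by sqrt(2)
  expect_equal(rotational_efficiency(m, c(0, 0), c(4, 0), density = 2),
               re / sqrt(2), tolerance = 1e-12)
  expect_error(rotational_efficiency(m, c(0, 0), c(0, 0)), "coincide")
})

test_that("rotational efficiency is invariant to rigid motions", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 500))
  lm <- identify_landmarks(m)
  re0 <- rotational_efficiency(m, lm$joint_node, lm$bite_node)
  phi <- 0.7; s <- c(2, -1)
  rotp <- function(p) cbind(cos(phi) * p[, 1] - sin(phi) * p[, 2] + s[1],
                            sin(phi) * p[, 1] + cos(phi) * p[, 2] + s[2])
  m2 <- m
  m2$nodes <- rotp(m$nodes)
  m2$element_centroids <- rotp(m$element_centroids)
  re1 <- rotational_efficiency(m2, lm$joint_node, lm$bite_node)
  expect_equal(re1, re0, tolerance = 1e-9)
})

test_that("the CST solver passes the constant-stress patch test", {
  m <- suppressWarnings(triangulate(rect_outline(2, 1, 0), 400))
  p <- m$nodes
  right <- which(abs(p[, 1] - 2) < 1e-9)
  left <- which(abs(p[, 1]) < 1e-9)
  sigma <- 1234
  ord <- right[order(p[right, 2])]
  seg <- diff(p[ord, 2])
  trib <- c(seg / 2, 0) + c(0, seg / 2)
  f <- numeric(2 * nrow(p))
  f[2 * ord - 1] <- sigma * trib
  fixed <- c(2 * left - 1, 2 * left[which.min(abs(p[left, 2] - 0.5))])
  r <- solve_cst(m, material_model(), fixed, f)
  expect_lt(max(abs(r$stress[, 1] - sigma)) / sigma, 1e-6)
  expect_lt(max(abs(r$stress[, 2])) / sigma, 1e-6)
  expect_lt(max(abs(r$vms - sigma)) / sigma, 1e-6)
})

test_that("zero load gives zero response and forces scale linearly", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 400))
  lm <- identify_landmarks(m)
  ring <- m$boundary_ring
  fn <- ring[round(length(ring) * 0.6)]
  bc0 <- list(joint_node = lm$joint_node, bite_node = lm$bite_node,
              force_node = fn, force_vector = c(0, 0))
  r0 <- solve_cst_fea(m, material_model(), bc0)
  expect_true(all(r0$displacements == 0))
  expect_true(all(r0$vms == 0))
  bc1 <- bc0; bc1$force_vector <- c(0.3, -0.8)
  bc2 <- bc0; bc2$force_vector <- 2.5 * bc1$force_vector
  r1 <- solve_cst_fea(m, material_model(), bc1)
  r2 <- solve_cst_fea(m, material_model(), bc2)
  expect_equal(r2$stress, 2.5 * r1$stress, tolerance = 1e-9)
  expect_equal(r2$median_vms, 2.5 * r1$median_vms, tolerance = 1e-9)
})

test_that("median VMS is invariant to element order", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 300))
  lm <- identify_landmarks(m)
  fn <- m$boundary_ring[round(length(m$boundary_ring) * 0.6)]
  bc <- list(joint_node = lm$joint_node, bite_node = lm$bite_node,
             force_node = fn, force_vector = c(0, -1))
  r1 <- solve_cst_fea(m, material_model(), bc)
  set.seed(1)
  perm <- sample(nrow(m$elements))
  m2 <- m
  m2$elements <- m$elements[perm, , drop = FALSE]
  m2$element_areas <- m$element_areas[perm]
  m2$element_centroids <- m$element_centroids[perm, , drop = FALSE]
  r2 <- solve_cst_fea(m2, material_model(), bc)
  expect_equal(r2$median_vms, r1$median_vms, tolerance = 1e-12)
})

test_that("underconstrained systems raise a rigid-body error", {
  m <- suppressWarnings(triangulate(unit_square(), 100))
  f <- numeric(2 * nrow(m$nodes)); f[2] <- 1
  expect_error(solve_cst(m, material_model(), integer(0), f),
               "rigid-body")
})

test_that("degenerate randomization windows reproduce the base configuration", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 400))
  base <- identify_landmarks(m)
  re0 <- randomize_bcs(m, base, n = 5, mode = "re", window_fraction = 0,
                       seed = 1)
  expect_true(all(re0$joint_x == re0$joint_x[1]))
  expect_equal(re0$joint_x[1], m$nodes[base$joint_node, 1], tolerance = 1e-9)
  expect_equal(re0$bite_y[1], m$nodes[base$bite_node, 2], tolerance = 1e-9)
  v0 <- randomize_bcs(m, base, n = 5, mode = "vms", window_fraction = 0,
                      angle_window_deg = 0, seed = 1)
  expect_equal(length(unique(v0$force_node)), 1)
  expect_equal(v0$fx, rep(v0$fx[1], 5))
  # the base force node sits on the dorsal path between joint and bite
  fn_xy <- m$nodes[v0$force_node[1], ]
  expect_gt(fn_xy[1], m$nodes[base$joint_node, 1])
  expect_lt(fn_xy[1], m$nodes[base$bite_node, 1])
})

test_that("randomized draws respect their hard support bounds", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 400))
  base <- identify_landmarks(m)
  per <- outline_perimeter(m$polygon)
  re_d <- randomize_bcs(m, base, n = 10000, mode = "re",
                        window_fraction = 0.05, seed = 2)
  expect_true(all(abs(re_d$joint_offset) <= 0.05 * per))
  expect_true(all(abs(re_d$bite_offset) <= 0.05 * per))
  v_d <- randomize_bcs(m, base, n = 10000, mode = "vms",
                       window_fraction = 0.05, angle_window_deg = 45,
                       seed = 3)
  expect_true(all(abs(v_d$arc_offset) <= 0.05 * per))
  expect_true(all(abs(v_d$angle_offset_deg) <= 45))
  expect_equal(sqrt(v_d$fx^2 + v_d$fy^2), rep(1, 10000), tolerance = 1e-12)
  # determinism
  expect_identical(v_d, randomize_bcs(m, base, n = 10000, mode = "vms",
                                      window_fraction = 0.05,
                                      angle_window_deg = 45, seed = 3))
})

test_that("Monte-Carlo summaries behave at the degenerate corners", {
  jaw <- standardize_area(test_jaw())
  m <- suppressWarnings(triangulate(jaw, 400))
  p1 <- monte_carlo_performance(m, n_replicates = 1, seed = 4)
  expect_equal(p1$re_mean, p1$re_p5)
  expect_equal(p1$re_mean, p1$re_p95)
  expect_equal(p1$vms_mean, p1$vms_p5)
  pz <- monte_carlo_performance(m, n_replicates = 50, seed = 4,
                                window_fraction = 0, angle_window_deg = 0)
  expect_equal(pz$re_p5, pz$re_p95, tolerance = 1e-12)
  expect_equal(pz$vms_p5, pz$vms_p95, tolerance = 1e-12)
  pa <- monte_carlo_performance(m, n_replicates = 40, seed = 9)
  pb <- monte_carlo_performance(m, n_replicates = 40, seed = 9)
  expect_identical(pa, pb)
  expect_true(pa$re_p5 <= pa$re_mean && pa$re_mean <= pa$re_p95)
  expect_true(all(c(pa$re_mean, pa$vms_mean) > 0))
})

test_that("rotational efficiency rises with elongation for straight jaws", {
  res <- vapply(c(2.5, 3.5, 5, 6.5), function(r) {
    jaw <- standardize_area(
      generate_jaw_outline(jaw_params(r, 0, 0.3, 0, 400), seed = 1)
    )
    m <- suppressWarnings(triangulate(jaw, 600))
    lm <- identify_landmarks(m)
    rotational_efficiency(m, lm$joint_node, lm$bite_node)
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("quadratic surfaces are recovered exactly and noise lowers R2", {
  g <- expand.grid(u = seq(-1, 1, length.out = 7),
                   v = seq(-1, 1, length.out = 7))
  z_exact <- 1 + 2 * g$u - g$v + g$u * g$v
  f1 <- fit_quadratic_surface(g, z_exact)
  expect_equal(f1$sse, 0, tolerance = 1e-18)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  # hyperbolic paraboloid recovered to machine precision
  f2 <- fit_quadratic_surface(g, g$u^2 - g$v^2)
  expect_equal(unname(f2$coefficients), c(0, 0, 0, 1, 0, -1),
               tolerance = 1e-9)
  set.seed(8)
  f3 <- fit_quadratic_surface(g, z_exact + rnorm(nrow(g), 0, 0.5))
  expect_lt(f3$r_squared, 1)
  expect_lte(f3$adj_r_squared, f3$r_squared)
  expect_equal(f3$rmse, sqrt(f3$sse / nrow(g)), tolerance = 1e-12)
  expect_error(fit_quadratic_surface(cbind(1:10, 2 * (1:10)), rnorm(10)),
               "Rank-deficient")
})
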