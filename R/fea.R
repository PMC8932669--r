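#' Linear elastic material for plane-stress analysis
#'
#' Defaults follow the bone-like stiffness used for fossil jaw silhouettes:
#' Young's modulus 2e9 Pa, Poisson's ratio 0.3. Thickness, density and force
#' magnitude are unit-valued: only relative stress and efficiency matter for
#' ranking shapes, so results are in consistent relative units rather than
#' pascals.
#'
#' @param young_modulus Young's modulus (> 0), default 2e9.
#' @param poisson_ratio Poisson's ratio in \[0, 0.5), default 0.3.
#' @param thickness Plate thickness, default 1.
#' @param density Area density used for rotational inertia, default 1.
#' @return A list of class `material_model`.
#' @export
material_model <- function(young_modulus = 2e9, poisson_ratio = 0.3,
                           thickness = 1, density = 1) {
  if (young_modulus <= 0) rlang::abort("`young_modulus` must be positive.")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    rlang::abort("`poisson_ratio` must be in [0, 0.5).")
  }
  structure(
    list(
      young_modulus = young_modulus, poisson_ratio = poisson_ratio,
      thickness = thickness, density = density
    ),
    class = "material_model"
  )
}

ring_cumlen <- function(mesh) {
  p <- mesh$nodes[mesh$boundary_ring, , drop = FALSE]
  n <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:n, 1), ] - p)^2))
  list(pts = p, seg = seg, cum = c(0, cumsum(seg))[seq_len(n)], per = sum(seg))
}

# position and outward normal on the boundary ring at arc length s (mod per)
boundary_at <- function(ring, s) {
  per <- ring$per
  s <- ((s %% per) + per) %% per
  n <- nrow(ring$pts)
  k <- findInterval(s, ring$cum, rightmost.closed = FALSE)
  k[k < 1] <- 1
  frac <- (s - ring$cum[k]) / ring$seg[k]
  nxt <- c(2:n, 1)
  a <- ring$pts[k, , drop = FALSE]
  b <- ring$pts[nxt[k], , drop = FALSE]
  d <- b - a
  len <- sqrt(rowSums(d^2))
  list(
    xy = a + frac * d,
    normal = cbind(d[, 2], -d[, 1]) / len,   # outward for a CCW ring
    node = ifelse(frac < 0.5, k, nxt[k])     # nearest ring vertex
  )
}

#' Locate the jaw joint and bite point on a mesh boundary
#'
#' Scans boundary nodes whose outward normal lies within
#' `vertical_tolerance_deg` of +y (the occlusal margin of a jaw in canonical
#' orientation) and takes the posterior-most (minimum x) as the jaw joint and
#' the anterior-most (maximum x) as the bite point.
#'
#' @param mesh A `tri_mesh` in canonical orientation (anterior +x, dorsal
#'   +y).
#' @param vertical_tolerance_deg Half-angle of the "near vertical" normal
#'   cone (default 30).
#' @return A list with `joint_node`, `bite_node` (node indices), and their
#'   boundary arc positions `joint_s`, `bite_s`.
#' @export
identify_landmarks <- function(mesh, vertical_tolerance_deg = 30) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ring <- ring_cumlen(mesh)
  p <- ring$pts
  n <- nrow(p)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  e_out <- cbind(p[nxt, 2] - p[, 2], -(p[nxt, 1] - p[, 1]))
  e_out <- e_out / sqrt(rowSums(e_out^2))
  e_in <- e_out[prv, , drop = FALSE]
  nrm <- e_out + e_in
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-12] <- 1
  nrm <- nrm / len
  ang <- acos(pmin(1, pmax(-1, nrm[, 2]))) * 180 / pi
  cand <- which(ang <= vertical_tolerance_deg)
  if (length(cand) < 2) {
    rlang::abort("No boundary nodes with near-vertical outward normals: cannot place jaw joint and bite point.")
  }
  jk <- cand[which.min(p[cand, 1])]
  bk <- cand[which.max(p[cand, 1])]
  if (jk == bk) rlang::abort("Joint and bite landmarks coincide.")
  list(
    joint_node = mesh$boundary_ring[jk],
    bite_node = mesh$boundary_ring[bk],
    joint_s = ring$cum[jk],
    bite_s = ring$cum[bk]
  )
}

#' Rotational efficiency of a meshed jaw
#'
#' The speed of the bite point under one unit of rotational kinetic energy
#' about the jaw joint: with moment of inertia `I = sum(m_i * r_i^2)` over
#' elements (mass = density x element area, r = centroid distance to the
#' joint), `E = I w^2 / 2 = 1` gives `w = sqrt(2 / I)` and
#' `RE = L * sqrt(2 / I)` where L is the joint-bite distance.
#'
#' @param mesh A `tri_mesh`.
#' @param joint,bite Node indices (single integers) or xy coordinate pairs.
#' @param density Area density (default 1).
#' @return Rotational efficiency (relative units).
#' @export
rotational_efficiency <- function(mesh, joint, bite, density = 1) {
  stopifnot(inherits(mesh, "tri_mesh"))
  jp <- if (length(joint) == 1) mesh$nodes[joint, ] else as.numeric(joint)
  bp <- if (length(bite) == 1) mesh$nodes[bite, ] else as.numeric(bite)
  L <- sqrt(sum((bp - jp)^2))
  if (L < 1e-12) rlang::abort("Joint and bite point coincide.")
  m <- density * mesh$element_areas
  if (sum(m) <= 0) rlang::abort("Mesh has zero mass.")
  r2 <- (mesh$element_centroids[, 1] - jp[1])^2 +
    (mesh$element_centroids[, 2] - jp[2])^2
  I <- sum(m * r2)
  L * sqrt(2 / I)
}

cst_system <- function(mesh, material) {
  p <- mesh$nodes; tri <- mesh$elements
  E <- material$young_modulus; nu <- material$poisson_ratio
  t <- material$thickness
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  A2 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)  # 2*area, > 0 (CCW)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / A2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / A2
  nel <- nrow(tri)
  # strain-displacement rows per element: ex = sum b_i u_xi ;
  # ey = sum c_i u_yi ; gxy = sum (c_i u_xi + b_i u_yi)
  dof <- matrix(0L, nel, 6)
  dof[, c(1, 3, 5)] <- 2L * tri - 1L
  dof[, c(2, 4, 6)] <- 2L * tri
  # B as three nel x 6 matrices (strain component by dof)
  B1 <- cbind(b[, 1], 0, b[, 2], 0, b[, 3], 0)
  B2 <- cbind(0, cc[, 1], 0, cc[, 2], 0, cc[, 3])
  B3 <- cbind(cc[, 1], b[, 1], cc[, 2], b[, 2], cc[, 3], b[, 3])
  area <- A2 / 2
  # element stiffness K_e = t * A * B' D B, assembled as triplets
  ii <- jj <- integer(36 * nel); vv <- numeric(36 * nel)
  pos <- 1L
  for (a in 1:6) {
    Da <- cbind(
      D[1, 1] * B1[, a] + D[1, 2] * B2[, a] + D[1, 3] * B3[, a],
      D[2, 1] * B1[, a] + D[2, 2] * B2[, a] + D[2, 3] * B3[, a],
      D[3, 1] * B1[, a] + D[3, 2] * B2[, a] + D[3, 3] * B3[, a]
    )
    for (bcol in 1:6) {
      val <- t * area *
        (Da[, 1] * B1[, bcol] + Da[, 2] * B2[, bcol] + Da[, 3] * B3[, bcol])
      rng <- pos:(pos + nel - 1L)
      ii[rng] <- dof[, a]; jj[rng] <- dof[, bcol]; vv[rng] <- val
      pos <- pos + nel
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(2 * nrow(p), 2 * nrow(p)))
  list(K = K, D = D, B1 = B1, B2 = B2, B3 = B3, dof = dof, area = area)
}

constrained_dofs <- function(bc, scheme) {
  scheme <- match.arg(scheme, c("lever", "pinned"))
  if (scheme == "lever") {
    c(2L * bc$joint_node - 1L, 2L * bc$joint_node, 2L * bc$bite_node)
  } else {
    c(2L * bc$joint_node - 1L, 2L * bc$joint_node,
      2L * bc$bite_node - 1L, 2L * bc$bite_node)
  }
}

element_stresses <- function(sys, u) {
  ue <- matrix(u[sys$dof], nrow(sys$dof), 6)
  ex <- rowSums(sys$B1 * ue)
  ey <- rowSums(sys$B2 * ue)
  g <- rowSums(sys$B3 * ue)
  D <- sys$D
  sx <- D[1, 1] * ex + D[1, 2] * ey
  sy <- D[2, 1] * ex + D[2, 2] * ey
  txy <- D[3, 3] * g
  cbind(sx = sx, sy = sy, txy = txy)
}

von_mises <- function(s) {
  sqrt(s[, 1]^2 - s[, 1] * s[, 2] + s[, 2]^2 + 3 * s[, 3]^2)
}

#' Solve a plane-stress constant-strain-triangle model
#'
#' Assembles the CST stiffness matrix, applies the constraint scheme (by
#' default the lever scheme: joint fixed in x and y, bite point fixed in y
#' only, which suppresses rigid-body motion while preserving lever-like load
#' transfer), applies the nodal load, and solves the linear system.
#'
#' @param mesh A `tri_mesh`.
#' @param material A [material_model()].
#' @param bc A list with `joint_node`, `bite_node`, `force_node` (node
#'   indices) and `force_vector` (length-2, any magnitude).
#' @param scheme `"lever"` (joint xy + bite y) or `"pinned"` (both fully
#'   fixed).
#' @return An object of class `fea_result`: `displacements` (n x 2),
#'   `stress` (elements x 3: sx, sy, txy), `vms`, and `median_vms`.
#' @export
solve_cst_fea <- function(mesh, material = material_model(), bc,
                          scheme = "lever") {
  stopifnot(inherits(mesh, "tri_mesh"))
  ndof <- 2L * nrow(mesh$nodes)
  f <- numeric(ndof)
  f[2L * bc$force_node - 1L] <- bc$force_vector[1]
  f[2L * bc$force_node] <- bc$force_vector[2]
  solve_cst(mesh, material, fixed_dofs = constrained_dofs(bc, scheme),
            load = f)
}

#' Solve a CST model under arbitrary constraints and loads
#'
#' Lower-level entry used by [solve_cst_fea()]: takes an explicit set of
#' fixed degrees of freedom (dof `2k - 1` is node k's x, dof `2k` its y) and
#' a full-length load vector, so distributed tractions and custom constraint
#' schemes can be analysed.
#'
#' @param mesh A `tri_mesh`.
#' @param material A [material_model()].
#' @param fixed_dofs Integer vector of constrained dof indices.
#' @param load Numeric load vector of length `2 * n_nodes`.
#' @return An `fea_result` (see [solve_cst_fea()]).
#' @export
solve_cst <- function(mesh, material = material_model(), fixed_dofs, load) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sys <- cst_system(mesh, material)
  ndof <- 2L * nrow(mesh$nodes)
  stopifnot(length(load) == ndof)
  free <- setdiff(seq_len(ndof), as.integer(fixed_dofs))
  u <- numeric(ndof)
  Kff <- sys$K[free, free]
  sol <- tryCatch(
    Matrix::solve(Kff, load[free]),
    error = function(e) {
      rlang::abort("Singular stiffness system: constraints leave rigid-body modes.")
    }
  )
  resid <- max(abs(as.numeric(Kff %*% sol) - load[free]))
  if (!all(is.finite(as.numeric(sol))) ||
      resid > 1e-6 * max(abs(load), 1e-300)) {
    rlang::abort("Singular stiffness system: constraints leave rigid-body modes.")
  }
  u[free] <- as.numeric(sol)
  s <- element_stresses(sys, u)
  v <- von_mises(s)
  structure(
    list(
      displacements = matrix(u, ncol = 2, byrow = TRUE),
      stress = s,
      vms = v,
      median_vms = stats::median(v)
    ),
    class = "fea_result"
  )
}

#' Draw randomized boundary conditions
#'
#' Reproduces the uncertainty model for landmark placement: for `mode =
#' "re"`, the joint and bite points are displaced independently along the
#' boundary by uniform arc offsets within `window_fraction` of the perimeter
#' on either side. For `mode = "vms"` the constraints stay at the base
#' landmarks; the muscle-force node starts one-third of the way along the
#' dorsal boundary path from joint to bite, is displaced within the same
#' window, and the force direction is the outward normal rotated by a
#' uniform angle within `angle_window_deg` on either side (unit magnitude).
#'
#' @param mesh A `tri_mesh`.
#' @param base Landmarks from [identify_landmarks()].
#' @param n Number of draws.
#' @param mode `"re"` or `"vms"`.
#' @param window_fraction Half-window as a fraction of the outline perimeter
#'   (default 0.05).
#' @param angle_window_deg Half-window for the force angle (default 45).
#' @param seed Integer seed.
#' @return For `mode = "re"`, a tibble with joint/bite coordinates per draw;
#'   for `mode = "vms"`, a tibble with `force_node`, `fx`, `fy` per draw.
#' @export
randomize_bcs <- function(mesh, base, n = 1, mode = c("re", "vms"),
                          window_fraction = 0.05, angle_window_deg = 45,
                          seed = 1) {
  mode <- match.arg(mode)
  ring <- ring_cumlen(mesh)
  w <- window_fraction * ring$per
  if (mode == "re") {
    draws <- withr::with_seed(seed, {
      cbind(stats::runif(n, -w, w), stats::runif(n, -w, w))
    })
    jp <- boundary_at(ring, base$joint_s + draws[, 1])
    bp <- boundary_at(ring, base$bite_s + draws[, 2])
    return(tibble::tibble(
      joint_x = jp$xy[, 1], joint_y = jp$xy[, 2],
      bite_x = bp$xy[, 1], bite_y = bp$xy[, 2],
      joint_offset = draws[, 1], bite_offset = draws[, 2]
    ))
  }
  # dorsal path from joint to bite: the ring direction with the higher mean y
  path_f <- arc_path(ring, base$joint_s, base$bite_s, forward = TRUE)
  path_b <- arc_path(ring, base$joint_s, base$bite_s, forward = FALSE)
  use_f <- path_f$mean_y >= path_b$mean_y
  path_len <- if (use_f) path_f$len else path_b$len
  dir_sign <- if (use_f) 1 else -1
  s_force <- base$joint_s + dir_sign * path_len / 3
  draws <- withr::with_seed(seed, {
    cbind(stats::runif(n, -w, w),
          stats::runif(n, -angle_window_deg, angle_window_deg) * pi / 180)
  })
  fp <- boundary_at(ring, s_force + draws[, 1])
  ca <- cos(draws[, 2]); sa <- sin(draws[, 2])
  fx <- ca * fp$normal[, 1] - sa * fp$normal[, 2]
  fy <- sa * fp$normal[, 1] + ca * fp$normal[, 2]
  force_node <- mesh$boundary_ring[fp$node]
  # the force node must not coincide with a constrained landmark
  collide <- force_node %in% c(base$joint_node, base$bite_node)
  if (any(collide)) {
    nb <- length(mesh$boundary_ring)
    shift <- match(fp$node, seq_len(nb)) %% nb + 1L
    force_node[collide] <- mesh$boundary_ring[shift[collide]]
  }
  tibble::tibble(
    force_node = force_node, fx = fx, fy = fy,
    arc_offset = draws[, 1], angle_offset_deg = draws[, 2] * 180 / pi
  )
}

arc_path <- function(ring, s_from, s_to, forward = TRUE) {
  per <- ring$per
  len <- if (forward) (s_to - s_from) %% per else (s_from - s_to) %% per
  if (len == 0) len <- per
  ss <- s_from + (if (forward) 1 else -1) * seq(0, len, length.out = 50)
  ys <- boundary_at(ring, ss)$xy[, 2]
  list(len = len, mean_y = mean(ys))
}

#' Monte-Carlo performance of a meshed shape
#'
#' Computes `n_replicates` rotational-efficiency values under randomized
#' joint/bite placement and `n_replicates` median von Mises stresses under
#' randomized muscle-force placement and orientation (constraints fixed at
#' the base landmarks, so the stiffness factorization is reused across
#' replicates). Summaries are the mean and the 5th/95th empirical
#' percentiles of each metric.
#'
#' @param mesh A `tri_mesh` in canonical orientation.
#' @param material A [material_model()].
#' @param n_replicates Replicates per metric (default 1000).
#' @param seed Integer seed.
#' @param window_fraction,angle_window_deg Randomization windows (defaults
#'   0.05 and 45).
#' @param scheme Constraint scheme for the stress model (default lever).
#' @return A one-row tibble: `re_mean`, `re_p5`, `re_p95`, `vms_mean`,
#'   `vms_p5`, `vms_p95`, `n_replicates`, `seed`.
#' @export
monte_carlo_performance <- function(mesh, material = material_model(),
                                    n_replicates = 1000, seed = 1,
                                    window_fraction = 0.05,
                                    angle_window_deg = 45,
                                    scheme = "lever") {
  stopifnot(inherits(mesh, "tri_mesh"))
  base <- identify_landmarks(mesh)
  # rotational efficiency: randomized joint and bite positions
  re_bc <- randomize_bcs(mesh, base, n = n_replicates, mode = "re",
                         window_fraction = window_fraction, seed = seed)
  m <- material$density * mesh$element_areas
  S0 <- sum(m)
  S1 <- c(sum(m * mesh$element_centroids[, 1]),
          sum(m * mesh$element_centroids[, 2]))
  S2 <- sum(m * rowSums(mesh$element_centroids^2))
  I <- S2 - 2 * (re_bc$joint_x * S1[1] + re_bc$joint_y * S1[2]) +
    (re_bc$joint_x^2 + re_bc$joint_y^2) * S0
  L <- sqrt((re_bc$bite_x - re_bc$joint_x)^2 + (re_bc$bite_y - re_bc$joint_y)^2)
  re <- L * sqrt(2 / I)

  # median VMS: constraints fixed, force randomized; one factorization
  vms_bc <- randomize_bcs(mesh, base, n = n_replicates, mode = "vms",
                          window_fraction = window_fraction,
                          angle_window_deg = angle_window_deg,
                          seed = seed + 1L)
  sys <- cst_system(mesh, material)
  fixed <- constrained_dofs(base, scheme)
  ndof <- 2L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), fixed)
  Fmat <- matrix(0, ndof, n_replicates)
  Fmat[cbind(2L * vms_bc$force_node - 1L, seq_len(n_replicates))] <- vms_bc$fx
  Fmat[cbind(2L * vms_bc$force_node, seq_len(n_replicates))] <- vms_bc$fy
  sol <- tryCatch(
    as.matrix(Matrix::solve(sys$K[free, free], Fmat[free, , drop = FALSE])),
    error = function(e) {
      rlang::abort("Singular stiffness system: constraints leave rigid-body modes.")
    }
  )
  med_vms <- vapply(seq_len(n_replicates), function(k) {
    u <- numeric(ndof)
    u[free] <- sol[, k]
    stats::median(von_mises(element_stresses(sys, u)))
  }, numeric(1))

  q <- function(x, p) as.numeric(stats::quantile(x, p, type = 7))
  tibble::tibble(
    re_mean = mean(re), re_p5 = q(re, 0.05), re_p95 = q(re, 0.95),
    vms_mean = mean(med_vms), vms_p5 = q(med_vms, 0.05),
    vms_p95 = q(med_vms, 0.95),
    n_replicates = n_replicates, seed = seed
  )
}

#' Monte-Carlo performance across a theoretical grid
#'
#' Meshes every valid grid shape and runs [monte_carlo_performance()] on it,
#' returning one row per valid node joined to the node coordinates.
#'
#' @param grid A `theoretical_grid`.
#' @param material A [material_model()].
#' @param target_elements Mesh density per shape (default 2500).
#' @param n_replicates Monte-Carlo replicates per shape (default 1000).
#' @param seed Integer seed; each node uses a seed derived from it.
#' @param ... Passed on to [monte_carlo_performance()].
#' @return A tibble: `node`, `pc1`, `pc2`, plus the performance summary
#'   columns.
#' @export
grid_performance <- function(grid, material = material_model(),
                             target_elements = 2500, n_replicates = 1000,
                             seed = 1, ...) {
  stopifnot(inherits(grid, "theoretical_grid"))
  nodes <- dplyr::filter(grid$nodes, .data$valid)
  res <- purrr::map(seq_len(nrow(nodes)), function(k) {
    mesh <- suppressWarnings(
      triangulate(nodes$outline[[k]], target_elements = target_elements)
    )
    perf <- monte_carlo_performance(
      mesh, material, n_replicates = n_replicates,
      seed = (seed + nodes$node[k]) %% .Machine$integer.max, ...
    )
    dplyr::bind_cols(
      tibble::tibble(node = nodes$node[k], pc1 = nodes$pc1[k],
                     pc2 = nodes$pc2[k]),
      perf
    )
  })
  dplyr::bind_rows(res)
}

#' Least-squares quadratic performance surface
#'
#' Fits `z = c0 + c1 u + c2 v + c3 u^2 + c4 u v + c5 v^2` by ordinary least
#' squares and reports the error statistics used to judge whether a
#' performance surface is well characterized by a second-order polynomial.
#'
#' @param coords A data frame with the first two columns taken as (u, v), or
#'   a two-column matrix.
#' @param values Numeric response vector.
#' @return An object of class `quad_surface_fit` with `coefficients` (c0..
#'   c5), `sse`, `rmse` (sqrt(sse/n)), `r_squared`, `adj_r_squared`, `n`.
#' @export
fit_quadratic_surface <- function(coords, values) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  u <- coords[, 1]; v <- coords[, 2]; z <- as.numeric(values)
  if (length(z) < 6) rlang::abort("Need at least 6 points for a quadratic surface.")
  X <- cbind(1, u, v, u^2, u * v, v^2)
  qr_x <- qr(X)
  if (qr_x$rank < 6) rlang::abort("Rank-deficient design: points are degenerate.")
  beta <- qr.coef(qr_x, z)
  fitted <- as.numeric(X %*% beta)
  res <- z - fitted
  n <- length(z)
  sse <- sum(res^2)
  sst <- sum((z - mean(z))^2)
  r2 <- 1 - sse / sst
  structure(
    list(
      coefficients = stats::setNames(as.numeric(beta),
                                     c("c0", "c1", "c2", "c3", "c4", "c5")),
      sse = sse,
      rmse = sqrt(sse / n),
      r_squared = r2,
      adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 6),
      n = n,
      fitted = fitted,
      residuals = res
    ),
    class = "quad_surface_fit"
  )
}

#' @export
print.quad_surface_fit <- function(x, ...) {
  cat(sprintf(
    "<quad_surface_fit: n = %d, SSE = %.4g, RMSE = %.4g, R2 = %.4f, adj R2 = %.4f>\n",
    x$n, x$sse, x$rmse, x$r_squared, x$adj_r_squared
  ))
  invisible(x)
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf(
    "<fea_result: %d elements, median VMS %.4g, max VMS %.4g>\n",
    length(x$vms), x$median_vms, max(x$vms)
  ))
  invisible(x)
}
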