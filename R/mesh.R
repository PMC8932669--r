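#' Triangulate a simple outline into constant-strain triangles
#'
#' Meshes the interior of a simple closed outline with roughly uniform
#' triangles of a target count. Boundary nodes are placed at equal arc length
#' along the outline; interior nodes on a hexagonal lattice matched to the
#' target element size; the Delaunay triangulation of the combined set is
#' clipped to the polygon and relaxed by Laplacian smoothing. The lattice
#' pitch is adjusted iteratively until the element count is within 10% of
#' `target_elements`. Meshing is fully deterministic: the same outline and
#' target give the same mesh.
#'
#' @param outline A simple `jaw_outline`.
#' @param target_elements Desired element count (>= 10; default 2500).
#' @param min_angle_deg Quality floor checked after smoothing; a warning is
#'   emitted if the final mesh violates it (default 20).
#' @return An object of class `tri_mesh`: `nodes` (n x 2), `elements`
#'   (T x 3, counterclockwise), `boundary_ring` (ordered node indices along
#'   the outline), `element_areas`, `element_centroids`, and `polygon` (the
#'   boundary-node outline actually meshed; its vertices lie exactly on the
#'   input polygon).
#' @export
triangulate <- function(outline, target_elements = 2500, min_angle_deg = 20) {
  outline <- as_outline(outline)
  if (target_elements < 10) rlang::abort("`target_elements` must be >= 10.")
  if (detect_self_intersection(outline)) {
    rlang::abort("Refusing to mesh a self-intersecting outline.")
  }
  A <- outline_area(outline)
  per <- outline_perimeter(outline)
  # pitch of an equilateral-triangle lattice with elements of area ~ A/N
  h <- sqrt(4 / sqrt(3) * A / target_elements)
  mesh <- NULL
  for (iter in 1:5) {
    mesh <- mesh_once(outline, h, per)
    n_el <- nrow(mesh$elements)
    if (abs(n_el - target_elements) <= 0.10 * target_elements) break
    h <- h * sqrt(n_el / target_elements)
  }
  mesh$target_elements <- target_elements
  ang <- min_mesh_angle(mesh)
  if (ang < min_angle_deg) {
    rlang::warn(sprintf(
      "Mesh minimum interior angle %.1f deg is below the %.0f deg floor.",
      ang, min_angle_deg
    ))
  }
  mesh
}

mesh_once <- function(outline, h, per) {
  bnd <- sample_boundary(outline, h)
  n_b <- nrow(bnd)
  poly <- outline_xy(bnd)
  interior <- hex_lattice_points(poly, h)
  pts <- rbind(poly, interior)
  # connectivity is computed on jittered copies (all points, to break exact
  # cocircular/collinear configurations); true coordinates stay untouched
  retri <- function(p) {
    tri <- delaunay_bw(jitter_points(p, h, fixed = integer(0)))
    clip_to_polygon(tri, p, poly)
  }
  tri <- retri(pts)
  # Laplacian relaxation of interior nodes with re-triangulation
  pts_s <- smooth_interior(pts, tri, fixed = seq_len(n_b), passes = 4)
  tri <- retri(pts_s)
  pts_s <- smooth_interior(pts_s, tri, fixed = seq_len(n_b), passes = 3)
  tri <- retri(pts_s)
  # drop slivers that are degenerate at the true coordinates (collinear
  # boundary runs); their long edge lies on the boundary, so removal keeps
  # the mesh conforming and costs no area
  tri <- tri[abs(tri_signed_areas(pts_s, tri)) > 1e-7 * h^2, , drop = FALSE]
  tri <- orient_ccw(tri, pts_s)
  dimnames(pts_s) <- NULL
  geo <- tri_geometry(pts_s, tri)
  structure(
    list(
      nodes = pts_s,
      elements = tri,
      boundary_ring = seq_len(n_b),
      element_areas = geo$areas,
      element_centroids = geo$centroids,
      polygon = bnd,
      h = h
    ),
    class = "tri_mesh"
  )
}

# Boundary nodes at ~h spacing that preserve genuine polygon corners
# (including the sharp anterior/posterior tips of jaw silhouettes): the
# ring is split into chains at vertices whose turning angle exceeds 10
# degrees and each chain is subdivided evenly. Smooth (densely digitized)
# outlines have no such corners and reduce to plain equal-arc resampling.
sample_boundary <- function(outline, h) {
  p <- outline_xy(outline)
  n <- nrow(p)
  prv <- c(n, 1:(n - 1)); nxt <- c(2:n, 1)
  v1 <- p - p[prv, , drop = FALSE]
  v2 <- p[nxt, , drop = FALSE] - p
  turn <- abs(atan2(
    v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
    v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
  ))
  corners <- which(turn > 10 * pi / 180)
  if (length(corners) == 0) {
    per <- outline_perimeter(outline)
    return(resample_outline(outline, max(8L, round(per / h))))
  }
  corners <- sort(corners)
  # a sharp tip digitized across two vertices yields adjacent "corners";
  # keep only the sharpest of any cluster closer than h/2 along the arc
  if (length(corners) > 1) {
    seg <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
    cum <- c(0, cumsum(seg))[seq_len(n)]
    per <- sum(seg)
    repeat {
      pos <- cum[corners]
      gap <- diff(c(pos, pos[1] + per))
      close_next <- which(gap < 0.5 * h)
      if (length(close_next) == 0 || length(corners) == 1) break
      # drop the blunter member of the closest pair
      kk <- close_next[1]
      j2 <- if (kk == length(corners)) 1L else kk + 1L
      drop <- if (turn[corners[kk]] >= turn[corners[j2]]) j2 else kk
      corners <- corners[-drop]
    }
  }
  # walk chains between consecutive corners, resampling each at spacing ~h
  out <- list()
  for (ci in seq_along(corners)) {
    a <- corners[ci]
    b <- corners[if (ci == length(corners)) 1 else ci + 1]
    idx <- if (b > a) a:b else c(a:n, 1:b)
    chain <- p[idx, , drop = FALSE]
    seg <- sqrt(rowSums((chain[-1, , drop = FALSE] -
                           chain[-nrow(chain), , drop = FALSE])^2))
    clen <- sum(seg)
    k <- max(1L, round(clen / h))
    targ <- clen * (0:(k - 1)) / k
    cum <- c(0, cumsum(seg))
    ji <- findInterval(targ, cum, rightmost.closed = TRUE)
    ji[ji >= nrow(chain)] <- nrow(chain) - 1L
    frac <- (targ - cum[ji]) / seg[ji]
    frac[!is.finite(frac)] <- 0
    out[[ci]] <- chain[ji, , drop = FALSE] +
      frac * (chain[ji + 1L, , drop = FALSE] - chain[ji, , drop = FALSE])
  }
  q <- do.call(rbind, out)
  as_outline(data.frame(x = q[, 1], y = q[, 2]), enforce_ccw = FALSE)
}

hex_lattice_points <- function(poly, h) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  dy <- h * sqrt(3) / 2
  ys <- seq(yr[1] - h, yr[2] + h, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) h / 2 else 0
    xs <- seq(xr[1] - h + off, xr[2] + h, by = h)
    cbind(xs, ys[r])
  }))
  inside <- point_in_polygon(pts[, 1], pts[, 2], poly)
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) == 0) return(pts)
  d <- dist_to_polygon(pts, poly)
  pts[d >= 0.6 * h, , drop = FALSE]
}

# deterministic symmetry-breaking jitter (hash of index), boundary kept exact
jitter_points <- function(pts, h, fixed) {
  n <- nrow(pts)
  idx <- seq_len(n)
  u <- ((idx * 2654435761) %% 104729) / 104729 - 0.5
  v <- ((idx * 97531) %% 104723) / 104723 - 0.5
  out <- pts
  mov <- setdiff(idx, fixed)
  out[mov, 1] <- out[mov, 1] + 1e-5 * h * u[mov]
  out[mov, 2] <- out[mov, 2] + 1e-5 * h * v[mov]
  out
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    cross <- ((ys[k] > py) != (ye[k] > py)) &
      (px < (xe[k] - xs[k]) * (py - ys[k]) / (ye[k] - ys[k]) + xs[k])
    inside <- xor(inside, cross)
  }
  inside
}

dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  d2 <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (k in seq_len(n)) {
    vx <- xe[k] - xs[k]; vy <- ye[k] - ys[k]
    len2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((px - xs[k]) * vx + (py - ys[k]) * vy) / len2))
    d2 <- pmin(d2, (px - xs[k] - t * vx)^2 + (py - ys[k] - t * vy)^2)
  }
  sqrt(d2)
}

# Bowyer-Watson incremental Delaunay triangulation of a point set
delaunay_bw <- function(pts) {
  n <- nrow(pts)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  span <- max(diff(xr), diff(yr), 1e-12)
  cx <- mean(xr); cy <- mean(yr)
  sup <- rbind(
    c(cx - 20 * span, cy - 10 * span),
    c(cx + 20 * span, cy - 10 * span),
    c(cx, cy + 20 * span)
  )
  P <- rbind(pts, sup)
  cap <- 4 * n + 16
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); r2 <- numeric(cap)
  alive <- logical(cap)
  tri[1, ] <- c(n + 1L, n + 2L, n + 3L)
  cc <- circumcircle(P, tri[1, , drop = FALSE])
  ccx[1] <- cc$x; ccy[1] <- cc$y; r2[1] <- cc$r2
  alive[1] <- TRUE
  m <- 1L
  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    live <- which(alive[seq_len(m)])
    bad <- live[(px - ccx[live])^2 + (py - ccy[live])^2 < r2[live]]
    if (length(bad) == 0) next  # should not happen inside the super-triangle
    edges <- rbind(
      tri[bad, c(1, 2), drop = FALSE],
      tri[bad, c(2, 3), drop = FALSE],
      tri[bad, c(3, 1), drop = FALSE]
    )
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    boundary <- edges[once, , drop = FALSE]
    alive[bad] <- FALSE
    nb <- nrow(boundary)
    if (m + nb > cap) {
      grow <- max(cap, nb) * 2L
      tri <- rbind(tri, matrix(NA_integer_, grow, 3))
      ccx <- c(ccx, numeric(grow)); ccy <- c(ccy, numeric(grow))
      r2 <- c(r2, numeric(grow)); alive <- c(alive, logical(grow))
      cap <- cap + grow
    }
    newt <- cbind(boundary, i)
    rows <- (m + 1L):(m + nb)
    tri[rows, ] <- newt
    cc <- circumcircle(P, newt)
    ccx[rows] <- cc$x; ccy[rows] <- cc$y; r2[rows] <- cc$r2
    alive[rows] <- TRUE
    m <- m + nb
  }
  keep <- which(alive[seq_len(m)])
  out <- tri[keep, , drop = FALSE]
  out[rowSums(out > n) == 0, , drop = FALSE]
}

circumcircle <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

clip_to_polygon <- function(tri, pts, poly) {
  cx <- (pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3
  cy <- (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3
  tri[point_in_polygon(cx, cy, poly), , drop = FALSE]
}

smooth_interior <- function(pts, tri, fixed, passes = 3) {
  n <- nrow(pts)
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  for (p in seq_len(passes)) {
    acc <- rowsum(
      cbind(pts[edges[, 2], 1], pts[edges[, 2], 2], 1),
      group = edges[, 1]
    )
    idx <- as.integer(rownames(acc))
    mov <- setdiff(idx, fixed)
    pos <- match(mov, idx)
    pts[mov, 1] <- acc[pos, 1] / acc[pos, 3]
    pts[mov, 2] <- acc[pos, 2] / acc[pos, 3]
  }
  pts
}

orient_ccw <- function(tri, pts) {
  a <- tri_signed_areas(pts, tri)
  flip <- a < 0
  tmp <- tri[flip, 2]
  tri[flip, 2] <- tri[flip, 3]
  tri[flip, 3] <- tmp
  tri
}

tri_signed_areas <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

tri_geometry <- function(pts, tri) {
  a <- tri_signed_areas(pts, tri)
  list(
    areas = abs(a),
    centroids = cbind(
      (pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3,
      (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3
    )
  )
}

min_mesh_angle <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$elements
  ang <- function(ox, oy, ax, ay, bx, by) {
    ux <- ax - ox; uy <- ay - oy; vx <- bx - ox; vy <- by - oy
    acos(pmin(1, pmax(-1, (ux * vx + uy * vy) /
                        sqrt((ux^2 + uy^2) * (vx^2 + vy^2)))))
  }
  a1 <- ang(p[tri[, 1], 1], p[tri[, 1], 2], p[tri[, 2], 1], p[tri[, 2], 2],
            p[tri[, 3], 1], p[tri[, 3], 2])
  a2 <- ang(p[tri[, 2], 1], p[tri[, 2], 2], p[tri[, 3], 1], p[tri[, 3], 2],
            p[tri[, 1], 1], p[tri[, 1], 2])
  a3 <- pi - a1 - a2
  min(c(a1, a2, a3)) * 180 / pi
}

#' Summary geometry of a triangular mesh
#'
#' @param mesh A `tri_mesh`.
#' @return A list with `total_area`, `centroid` (area-weighted), and the
#'   per-element `areas` and `centroids`.
#' @export
mesh_properties <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  w <- mesh$element_areas
  list(
    total_area = sum(w),
    centroid = c(
      sum(w * mesh$element_centroids[, 1]) / sum(w),
      sum(w * mesh$element_centroids[, 2]) / sum(w)
    ),
    areas = w,
    centroids = mesh$element_centroids
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh: %d nodes, %d elements, area %.6g, min angle %.1f deg>\n",
    nrow(x$nodes), nrow(x$elements), sum(x$element_areas), min_mesh_angle(x)
  ))
  invisible(x)
}
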