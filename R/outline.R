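#' Closed outline objects
#'
#' An outline is an ordered, closed polygon stored as a tibble with `x` and
#' `y` columns (the first vertex is not repeated at the end). Outlines are
#' kept counterclockwise; [as_outline()] validates and, if needed, reverses
#' the vertex order.
#'
#' @param data A data frame (or matrix) with columns/plain columns `x`, `y`.
#' @param enforce_ccw Reverse the vertex order when the signed area is
#'   negative (default `TRUE`).
#' @return A tibble of class `jaw_outline` with columns `x`, `y`.
#' @export
#' @examples
#' sq <- as_outline(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' outline_area(sq)
as_outline <- function(data, enforce_ccw = TRUE) {
  if (is.matrix(data)) data <- data.frame(x = data[, 1], y = data[, 2])
  if (!all(c("x", "y") %in% names(data))) {
    rlang::abort("`data` must have columns `x` and `y`.")
  }
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  if (anyNA(x) || anyNA(y)) rlang::abort("Outline coordinates contain NA.")
  n <- length(x)
  # drop an explicitly repeated closing vertex
  if (n > 3 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) rlang::abort("An outline needs at least 3 vertices.")
  out <- tibble::tibble(x = x, y = y)
  if (enforce_ccw && signed_area(x, y) < 0) out <- out[rev(seq_len(n)), ]
  class(out) <- c("jaw_outline", class(tibble::tibble()))
  out
}

outline_xy <- function(outline) {
  cbind(outline$x, outline$y)
}

signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area, perimeter and centroid of an outline
#'
#' @param outline A `jaw_outline` (or any data frame with `x`, `y`).
#' @return `outline_area()` and `outline_perimeter()` return a single number;
#'   `outline_centroid()` returns a length-2 numeric vector (area centroid).
#' @export
outline_area <- function(outline) {
  abs(signed_area(outline$x, outline$y))
}

#' @rdname outline_area
#' @export
outline_perimeter <- function(outline) {
  x <- outline$x; y <- outline$y
  j <- c(2:length(x), 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' @rdname outline_area
#' @export
outline_centroid <- function(outline) {
  x <- outline$x; y <- outline$y
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Resample an outline to equally spaced vertices
#'
#' Places `n_points` vertices at equal arc-length spacing along the closed
#' polygonal boundary, starting at the original first vertex and preserving
#' orientation.
#'
#' @param outline A `jaw_outline`.
#' @param n_points Number of vertices (>= 3).
#' @return A `jaw_outline` with `n_points` vertices.
#' @export
resample_outline <- function(outline, n_points) {
  outline <- as_outline(outline, enforce_ccw = FALSE)
  if (n_points < 3) rlang::abort("`n_points` must be at least 3.")
  x <- outline$x; y <- outline$y
  n <- length(x)
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  per <- sum(seg)
  if (per <= 0) rlang::abort("Degenerate outline: zero perimeter.")
  cum <- c(0, cumsum(seg))
  target <- per * (seq_len(n_points) - 1) / n_points
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (target - cum[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  out <- tibble::tibble(
    x = xc[idx] + frac * (xc[idx + 1] - xc[idx]),
    y = yc[idx] + frac * (yc[idx + 1] - yc[idx])
  )
  class(out) <- c("jaw_outline", class(tibble::tibble()))
  out
}

#' Scale an outline to a target enclosed area
#'
#' Isotropic scaling about the area centroid, so shape and aspect ratio are
#' preserved while the polygon area becomes `target_area`.
#'
#' @param outline A simple `jaw_outline` with positive area.
#' @param target_area Target polygon area (default 1).
#' @return The rescaled `jaw_outline`.
#' @export
standardize_area <- function(outline, target_area = 1) {
  outline <- as_outline(outline, enforce_ccw = FALSE)
  a <- outline_area(outline)
  if (a <= .Machine$double.eps * 100) {
    rlang::abort("Outline area must be positive to standardize.")
  }
  if (target_area <= 0) rlang::abort("`target_area` must be positive.")
  s <- sqrt(target_area / a)
  ctr <- outline_centroid(outline)
  out <- tibble::tibble(
    x = ctr[1] + s * (outline$x - ctr[1]),
    y = ctr[2] + s * (outline$y - ctr[2])
  )
  class(out) <- c("jaw_outline", class(tibble::tibble()))
  out
}

#' Test a closed polygon for self-intersection
#'
#' Returns `TRUE` if any two non-adjacent edges of the closed polygon cross
#' (edges sharing an endpoint are excluded).
#'
#' @param outline A `jaw_outline` (>= 3 vertices).
#' @return Logical scalar.
#' @export
detect_self_intersection <- function(outline) {
  p <- outline_xy(as_outline(outline, enforce_ccw = FALSE))
  n <- nrow(p)
  q <- rbind(p, p[1, , drop = FALSE])
  a <- q[-(n + 1), , drop = FALSE]   # segment starts
  b <- q[-1, , drop = FALSE]         # segment ends
  # all pairs (i, j) with j > i + 1, excluding the (1, n) wrap pair
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- idx[, 2] > idx[, 1] + 1 & !(idx[, 1] == 1 & idx[, 2] == n)
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(FALSE)
  i <- idx[, 1]; j <- idx[, 2]
  any(segments_intersect(
    a[i, 1], a[i, 2], b[i, 1], b[i, 2],
    a[j, 1], a[j, 2], b[j, 1], b[j, 2]
  ))
}

# vectorized proper/improper segment intersection test
segments_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- cross2(x3, y3, x4, y4, x1, y1)
  d2 <- cross2(x3, y3, x4, y4, x2, y2)
  d3 <- cross2(x1, y1, x2, y2, x3, y3)
  d4 <- cross2(x1, y1, x2, y2, x4, y4)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  onseg <- (d1 == 0 & on_segment(x3, y3, x4, y4, x1, y1)) |
    (d2 == 0 & on_segment(x3, y3, x4, y4, x2, y2)) |
    (d3 == 0 & on_segment(x1, y1, x2, y2, x3, y3)) |
    (d4 == 0 & on_segment(x1, y1, x2, y2, x4, y4))
  proper | onseg
}

cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
    py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' Put an outline into the canonical anatomical frame
#'
#' Lateral jaw silhouettes are analysed with the anterior (biting) end toward
#' +x and the dorsal (tooth-bearing) margin up. The outline is centred,
#' rotated so its major principal axis lies along x, then reflected so that
#' (i) the thinner, tapering end points to +x and (ii) the bulk of the blade
#' (the area centroid) lies below the chord joining the two x-extremes.
#' Reflections reverse vertex order, so counterclockwise orientation is
#' restored afterwards.
#'
#' @param outline A `jaw_outline`.
#' @return A `jaw_outline` in canonical orientation.
#' @export
canonicalize_outline <- function(outline) {
  outline <- as_outline(outline)
  p <- outline_xy(outline)
  ctr <- outline_centroid(outline)
  p <- sweep(p, 2, ctr)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  v <- ev$vectors[, 1]
  rot <- rbind(c(v[1], v[2]), c(-v[2], v[1]))
  p <- p %*% t(rot)
  out <- as_outline(data.frame(x = p[, 1], y = p[, 2]))
  # thin end to +x: compare y-extent in the outer x quartiles
  p <- outline_xy(out)
  xr <- range(p[, 1])
  qlo <- p[, 1] <= xr[1] + 0.25 * diff(xr)
  qhi <- p[, 1] >= xr[2] - 0.25 * diff(xr)
  if (sum(qhi) > 2 && sum(qlo) > 2 &&
      diff(range(p[qhi, 2])) > diff(range(p[qlo, 2]))) {
    out <- as_outline(data.frame(x = -p[, 1], y = p[, 2]))
  }
  # bulk below the chord joining the x-extremes
  p <- outline_xy(out)
  i1 <- which.min(p[, 1]); i2 <- which.max(p[, 1])
  chord_y <- function(xq) {
    p[i1, 2] + (xq - p[i1, 1]) * (p[i2, 2] - p[i1, 2]) / (p[i2, 1] - p[i1, 1])
  }
  ctr <- outline_centroid(out)
  if (ctr[2] > chord_y(ctr[1])) {
    out <- as_outline(data.frame(x = p[, 1], y = -p[, 2]))
  }
  out
}

#' @export
print.jaw_outline <- function(x, ...) {
  cat(sprintf(
    "<jaw_outline: %d vertices, area %.4g, perimeter %.4g>\n",
    nrow(x), outline_area(x), outline_perimeter(x)
  ))
  NextMethod()
}
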