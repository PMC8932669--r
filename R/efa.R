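#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes Kuhl-Giardina elliptic Fourier coefficients of the closed polygon
#' traced by `outline`. Each harmonic n contributes an ellipse with
#' coefficients (a_n, b_n) for x(t) and (c_n, d_n) for y(t), t being arc
#' length around the boundary; the dc offset (A0, C0) carries position.
#'
#' @param outline A `jaw_outline` (closed, simple, >= 2*n_harmonics + 1
#'   vertices).
#' @param n_harmonics Number of harmonics H (default 12).
#' @return An object of class `efa` with fields `harmonics` (H x 4 matrix,
#'   columns a, b, c, d), `dc_offset` (A0, C0), `perimeter`, and
#'   `normalized = FALSE`.
#' @seealso [normalize_efa()], [efa_reconstruct()], [flatten_efa()]
#' @export
efa_decompose <- function(outline, n_harmonics = 12) {
  outline <- as_outline(outline, enforce_ccw = FALSE)
  n <- nrow(outline)
  if (n < 2 * n_harmonics + 1) {
    rlang::abort("Too few vertices for the requested number of harmonics.")
  }
  x <- outline$x; y <- outline$y
  dx <- diff(c(x, x[1]))
  dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt)          # t_i
  t0 <- c(0, t1[-length(t1)])  # t_{i-1}
  T_per <- t1[length(t1)]

  H <- n_harmonics
  coefs <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(H)) {
    w <- 2 * pi * h / T_per
    const <- T_per / (2 * pi^2 * h^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    coefs[h, 1] <- const * sum(dx / dt * dcos)
    coefs[h, 2] <- const * sum(dx / dt * dsin)
    coefs[h, 3] <- const * sum(dy / dt * dcos)
    coefs[h, 4] <- const * sum(dy / dt * dsin)
  }

  # dc component (Kuhl & Giardina A0/C0 for a polygon)
  xi <- c(0, cumsum(dx))[-(length(dx) + 1)] - (dx / dt) * t0
  delta <- c(0, cumsum(dy))[-(length(dy) + 1)] - (dy / dt) * t0
  A0 <- x[1] + sum(dx / (2 * dt) * (t1^2 - t0^2) + xi * (t1 - t0)) / T_per
  C0 <- y[1] + sum(dy / (2 * dt) * (t1^2 - t0^2) + delta * (t1 - t0)) / T_per

  structure(
    list(
      harmonics = coefs,
      dc_offset = c(A0 = A0, C0 = C0),
      perimeter = T_per,
      normalized = FALSE
    ),
    class = "efa"
  )
}

#' Remove size, rotation and starting-point from EFA coefficients
#'
#' Applies the standard first-harmonic normalization: the parameter origin is
#' rotated to the first-ellipse semi-major axis (removing starting-point
#' dependence), the coefficient frame is rotated to the first-ellipse
#' orientation (removing rotation), and all coefficients are divided by the
#' first semi-major axis length (removing size). Afterwards a1 = 1 and
#' b1 = c1 = 0, leaving 4H - 3 free parameters; the dc offset is set to zero.
#' Reflection is deliberately not removed: outlines are expected in the
#' canonical anatomical frame (see [canonicalize_outline()]), so chirality is
#' shape information.
#'
#' @param coeffs An unnormalized `efa` object with a non-degenerate first
#'   harmonic.
#' @return A normalized `efa` object.
#' @export
normalize_efa <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa"))
  if (isTRUE(coeffs$normalized)) return(coeffs)
  m <- coeffs$harmonics
  a1 <- m[1, 1]; b1 <- m[1, 2]; c1 <- m[1, 3]; d1 <- m[1, 4]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-300) {
    rlang::abort("Degenerate first harmonic: cannot normalize.")
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # the half-angle formula yields a critical point of the first-harmonic
  # cosine amplitude; pick the branch aligned with the semi-MAJOR axis,
  # then resolve the remaining half-turn so that a1 ends up positive
  amp <- function(th) {
    av <- a1 * cos(th) + b1 * sin(th)
    cv <- c1 * cos(th) + d1 * sin(th)
    av^2 + cv^2
  }
  if (amp(theta + pi / 2) > amp(theta)) theta <- theta + pi / 2
  # theta and theta + pi both end with a1 = 1 (a start half-turn); resolve
  # deterministically by lexicographic comparison of the coefficient vectors,
  # which is invariant to the digitization starting point
  cand1 <- apply_efa_normalization(m, theta)
  cand2 <- apply_efa_normalization(m, theta + pi)
  v1 <- as.vector(t(cand1$m)); v2 <- as.vector(t(cand2$m))
  k <- which(abs(v1 - v2) > 1e-9)
  out <- if (length(k) == 0 || v1[k[1]] >= v2[k[1]]) cand1 else cand2
  # the pinned first-harmonic entries are exact by construction
  out$m[1, 1:3] <- c(1, 0, 0)
  if (out$scale < 1e-300) {
    rlang::abort("Degenerate first harmonic: zero semi-major axis.")
  }
  structure(
    list(
      harmonics = out$m,
      dc_offset = c(A0 = 0, C0 = 0),
      perimeter = coeffs$perimeter,
      normalized = TRUE
    ),
    class = "efa"
  )
}

apply_efa_normalization <- function(m, theta) {
  H <- nrow(m)
  res <- m
  for (h in seq_len(H)) {
    rot <- matrix(c(cos(h * theta), sin(h * theta),
                    -sin(h * theta), cos(h * theta)), 2, 2)
    res[h, ] <- as.vector(t(matrix(m[h, ], 2, 2, byrow = TRUE) %*% rot))
  }
  a1s <- res[1, 1]; c1s <- res[1, 3]
  psi <- atan2(c1s, a1s)
  rot_psi <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)
  for (h in seq_len(H)) {
    res[h, ] <- as.vector(t(rot_psi %*% matrix(res[h, ], 2, 2, byrow = TRUE)))
  }
  scale <- sqrt(a1s^2 + c1s^2)
  list(m = res / scale, scale = scale)
}

#' Trace an outline from EFA coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values over one period.
#'
#' @param coeffs An `efa` object.
#' @param n_points Number of outline vertices to generate.
#' @param n_harmonics Use only the first `n_harmonics` harmonics (default:
#'   all available).
#' @return A `jaw_outline`.
#' @export
efa_reconstruct <- function(coeffs, n_points = 300, n_harmonics = NULL) {
  stopifnot(inherits(coeffs, "efa"))
  m <- coeffs$harmonics
  H <- if (is.null(n_harmonics)) nrow(m) else min(n_harmonics, nrow(m))
  tt <- 2 * pi * (seq_len(n_points) - 1) / n_points
  x <- rep(coeffs$dc_offset[["A0"]], n_points)
  y <- rep(coeffs$dc_offset[["C0"]], n_points)
  for (h in seq_len(H)) {
    ch <- cos(h * tt); sh <- sin(h * tt)
    x <- x + m[h, 1] * ch + m[h, 2] * sh
    y <- y + m[h, 3] * ch + m[h, 4] * sh
  }
  as_outline(data.frame(x = x, y = y), enforce_ccw = FALSE)
}

#' Flatten EFA coefficients to the free-parameter vector
#'
#' A normalized H-harmonic decomposition has a1 = 1 and b1 = c1 = 0 fixed, so
#' its free parameters are d1 followed by (a, b, c, d) for harmonics 2..H:
#' a vector of length 4H - 3 (45 at H = 12). `unflatten_efa()` inverts the
#' layout exactly.
#'
#' @param coeffs A normalized `efa` object.
#' @return A named numeric vector (`d1`, `a2`, `b2`, `c2`, `d2`, ...).
#' @export
flatten_efa <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa"))
  if (!isTRUE(coeffs$normalized)) {
    rlang::abort("Only normalized coefficients flatten to the free-parameter vector.")
  }
  m <- coeffs$harmonics
  H <- nrow(m)
  v <- c(m[1, 4], as.vector(t(m[-1, , drop = FALSE])))
  names(v) <- c("d1", as.vector(t(outer(2:H, c("a", "b", "c", "d"),
                                        function(h, l) paste0(l, h)))))
  v
}

#' @rdname flatten_efa
#' @param v A free-parameter vector of length 4H - 3.
#' @export
unflatten_efa <- function(v) {
  v <- as.numeric(v)
  if ((length(v) + 3) %% 4 != 0) {
    rlang::abort("Free-parameter vector length must be 4H - 3.")
  }
  H <- (length(v) + 3) / 4
  m <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  m[1, ] <- c(1, 0, 0, v[1])
  if (H > 1) m[-1, ] <- matrix(v[-1], H - 1, 4, byrow = TRUE)
  structure(
    list(
      harmonics = m,
      dc_offset = c(A0 = 0, C0 = 0),
      perimeter = NA_real_,
      normalized = TRUE
    ),
    class = "efa"
  )
}

#' Decompose a set of outlines into a coefficient table
#'
#' Convenience wrapper: canonicalizes (optionally), resamples, decomposes,
#' normalizes and flattens each outline, returning one row per specimen.
#'
#' @param outlines A named list of `jaw_outline`s, or a tibble with columns
#'   `taxon_id` and a list-column `outline`.
#' @param n_harmonics Harmonics H (default 12).
#' @param n_points Resampling density before decomposition (default 600).
#' @param canonicalize Apply [canonicalize_outline()] first (default TRUE).
#' @return A tibble: `taxon_id` plus 4H - 3 coefficient columns.
#' @export
efa_table <- function(outlines, n_harmonics = 12, n_points = 600,
                      canonicalize = TRUE) {
  if (is.data.frame(outlines)) {
    ids <- outlines$taxon_id
    outlines <- outlines$outline
  } else {
    ids <- names(outlines)
    if (is.null(ids)) ids <- paste0("t", seq_along(outlines))
  }
  rows <- purrr::map(outlines, function(o) {
    if (canonicalize) o <- canonicalize_outline(o)
    o <- resample_outline(o, n_points)
    flatten_efa(normalize_efa(efa_decompose(o, n_harmonics)))
  })
  dplyr::bind_cols(
    tibble::tibble(taxon_id = ids),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf(
    "<efa: %d harmonics, %s>\n", nrow(x$harmonics),
    if (isTRUE(x$normalized)) "normalized" else "unnormalized"
  ))
  invisible(x)
}
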