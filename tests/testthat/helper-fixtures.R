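# shared fixtures, built in code; heavier objects are cached per session

circle_outline <- function(n = 600, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  as_outline(data.frame(x = r * cos(th), y = r * sin(th)))
}

ellipse_outline <- function(n = 600, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  as_outline(data.frame(x = a * cos(th), y = b * sin(th)))
}

unit_square <- function() {
  as_outline(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
}

test_jaw <- function(ratio = 3.5, curvature = 0.1, taper = 0.3,
                     roughness = 0.005, seed = 2) {
  generate_jaw_outline(
    jaw_params(ratio, curvature, taper, roughness, 600), seed = seed
  )
}

rotate_outline <- function(o, phi, scale = 1) {
  as_outline(data.frame(
    x = scale * (cos(phi) * o$x - sin(phi) * o$y),
    y = scale * (sin(phi) * o$x + cos(phi) * o$y)
  ), enforce_ccw = FALSE)
}

# symmetric Hausdorff distance between two point sets (outline vertices)
hausdorff_dist <- function(a, b) {
  pa <- cbind(a$x, a$y); pb <- cbind(b$x, b$y)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

# small coefficient table + fitted space, cached (used by several files)
.fixture_env <- new.env(parent = emptyenv())

small_shape_space <- function() {
  if (is.null(.fixture_env$space)) {
    taxa <- generate_taxon_set(25, seed = 11, n_points = 300)
    coeffs <- efa_table(taxa, n_harmonics = 12, n_points = 300)
    .fixture_env$taxa <- taxa
    .fixture_env$coeffs <- coeffs
    .fixture_env$space <- fit_shape_space(coeffs)
  }
  .fixture_env$space
}

small_taxa <- function() {
  small_shape_space()
  .fixture_env$taxa
}

small_coeffs <- function() {
  small_shape_space()
  .fixture_env$coeffs
}

# independent brute-force oracle for bidirectional Pareto ranking: explicit
# dominance matrix + iterative peeling, separate from the package's code path
oracle_pareto <- function(m, maximize = c(TRUE, FALSE)) {
  mm <- as.matrix(m)
  mm[, !maximize] <- -mm[, !maximize, drop = FALSE]
  peel <- function(mm) {
    n <- nrow(mm)
    dom <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && all(mm[i, ] >= mm[j, ]) && any(mm[i, ] > mm[j, ])) {
          dom[i, j] <- TRUE
        }
      }
    }
    fronts <- integer(n)
    left <- rep(TRUE, n)
    f <- 0L
    while (any(left)) {
      f <- f + 1L
      nd <- left & !apply(dom[left, , drop = FALSE], 2, any)
      fronts[nd] <- f
      left[nd] <- FALSE
    }
    fronts
  }
  r_o <- peel(mm)
  r_s <- peel(-mm)
  denom <- r_o + r_s - 2L
  list(r_o = r_o, r_s = r_s,
       rank = ifelse(denom == 0, 0.5, (r_s - 1) / denom))
}
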