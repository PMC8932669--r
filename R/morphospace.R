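#' Fit the PCA shape space
#'
#' Centred (unscaled) principal component analysis of the free-parameter
#' coefficient matrix, one specimen per row. The fitted space supports
#' forward projection of new coefficient vectors and inverse reconstruction
#' of coefficient vectors (hence outlines) from PC coordinates.
#'
#' @param coeff_matrix A tibble/data frame with an optional `taxon_id` column
#'   and one numeric column per free parameter (e.g. from [efa_table()]), or
#'   a plain numeric matrix.
#' @return An object of class `shape_space` with elements `mean`, `loadings`
#'   (orthonormal columns), `eigenvalues`, `scores` (tibble), and
#'   `variance_explained`.
#' @export
fit_shape_space <- function(coeff_matrix) {
  ids <- NULL
  if (is.data.frame(coeff_matrix)) {
    if ("taxon_id" %in% names(coeff_matrix)) {
      ids <- coeff_matrix$taxon_id
      coeff_matrix <- dplyr::select(coeff_matrix, -"taxon_id")
    }
    coeff_matrix <- as.matrix(coeff_matrix)
  }
  storage.mode(coeff_matrix) <- "double"
  if (nrow(coeff_matrix) < 3) rlang::abort("Need at least 3 specimens.")
  if (anyNA(coeff_matrix)) rlang::abort("Coefficient matrix contains NA.")
  if (all(apply(coeff_matrix, 2, stats::sd) == 0)) {
    rlang::abort("Constant coefficient matrix: no variation to ordinate.")
  }
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(coeff_matrix)))
  pca <- stats::prcomp(coeff_matrix, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  scores <- tibble::as_tibble(pca$x)
  scores <- dplyr::bind_cols(tibble::tibble(taxon_id = ids), scores)
  structure(
    list(
      mean = pca$center,
      loadings = pca$rotation,
      eigenvalues = ev,
      scores = scores,
      variance_explained = ev / sum(ev),
      term_names = colnames(coeff_matrix)
    ),
    class = "shape_space"
  )
}

#' Project coefficient vectors into a fitted shape space
#'
#' Coordinates are `t(loadings) %*% (x - mean)`.
#'
#' @param space A fitted `shape_space`.
#' @param x A coefficient vector, or a matrix/data frame of row vectors
#'   (optionally with a `taxon_id` column).
#' @return A tibble of PC coordinates (plus `taxon_id` when supplied).
#' @export
project_shapes <- function(space, x) {
  stopifnot(inherits(space, "shape_space"))
  ids <- NULL
  if (is.data.frame(x)) {
    if ("taxon_id" %in% names(x)) {
      ids <- x$taxon_id
      x <- dplyr::select(x, -"taxon_id")
    }
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(space$mean)) {
    rlang::abort("Coefficient vector length does not match the fitted space.")
  }
  sc <- sweep(x, 2, space$mean) %*% space$loadings
  out <- tibble::as_tibble(sc)
  names(out) <- colnames(space$loadings)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(taxon_id = ids), out)
  out
}

#' Invert PC coordinates to a coefficient vector
#'
#' `mean + loadings[, 1:k] %*% scores`; unspecified higher axes are held at
#' zero, which is how theoretical shapes are built from PC1-PC2 alone.
#'
#' @param space A fitted `shape_space`.
#' @param scores Numeric vector of PC coordinates (length k <= n axes).
#' @return A named numeric coefficient vector.
#' @export
inverse_shapes <- function(space, scores) {
  stopifnot(inherits(space, "shape_space"))
  scores <- as.numeric(scores)
  k <- length(scores)
  if (k > ncol(space$loadings)) rlang::abort("Too many coordinates supplied.")
  v <- space$mean + as.numeric(space$loadings[, seq_len(k), drop = FALSE] %*% scores)
  names(v) <- space$term_names
  v
}

#' Reconstruct the outline at a morphospace location
#'
#' @param space A fitted `shape_space` over EFA free parameters.
#' @param pc1,pc2 Coordinates in the first two axes.
#' @param n_points Vertices for the reconstructed outline.
#' @return A `jaw_outline`.
#' @export
shape_at <- function(space, pc1, pc2, n_points = 300) {
  efa_reconstruct(unflatten_efa(inverse_shapes(space, c(pc1, pc2))), n_points)
}

#' Build the evenly spaced theoretical shape grid
#'
#' Axis limits are the empirical score range per axis, expanded at both ends
#' of both axes by `border_fraction` times the empirical PC1 range. At each
#' of the `n1 x n2` nodes the coefficient vector `mean + pc1*L1 + pc2*L2`
#' (higher axes zero) is reconstructed into an outline, screened for
#' self-intersection, and - when simple - standardized to unit area.
#'
#' @param space A fitted `shape_space`.
#' @param n1,n2 Grid dimensions along PC1 and PC2 (defaults 23 and 21, i.e.
#'   483 nodes).
#' @param border_fraction Border as a fraction of the empirical PC1 range
#'   (default 0.2).
#' @param n_points Vertices per theoretical outline.
#' @return An object of class `theoretical_grid`: a list with `nodes` (a
#'   tibble with `node`, `i`, `j`, `pc1`, `pc2`, `valid`, and list-column
#'   `outline`), the axis values `pc1_values`, `pc2_values`, and the
#'   generating `space`.
#' @export
build_theoretical_grid <- function(space, n1 = 23, n2 = 21,
                                   border_fraction = 0.2, n_points = 300) {
  stopifnot(inherits(space, "shape_space"))
  sc <- space$scores
  if (!all(c("PC1", "PC2") %in% names(sc))) {
    rlang::abort("The fitted space needs at least two axes.")
  }
  r1 <- range(sc$PC1); r2 <- range(sc$PC2)
  border <- border_fraction * diff(r1)
  pc1_values <- seq(r1[1] - border, r1[2] + border, length.out = n1)
  pc2_values <- seq(r2[1] - border, r2[2] + border, length.out = n2)
  nodes <- tidyr::expand_grid(j = seq_len(n2), i = seq_len(n1))
  nodes <- dplyr::mutate(
    nodes,
    node = dplyr::row_number(),
    pc1 = pc1_values[.data$i],
    pc2 = pc2_values[.data$j]
  )
  shapes <- purrr::map(seq_len(nrow(nodes)), function(k) {
    shape_at(space, nodes$pc1[k], nodes$pc2[k], n_points = n_points)
  })
  valid <- !purrr::map_lgl(shapes, detect_self_intersection)
  shapes <- purrr::map2(shapes, valid, function(s, ok) {
    if (ok) standardize_area(s, 1) else s
  })
  structure(
    list(
      nodes = dplyr::relocate(
        dplyr::mutate(nodes, valid = valid, outline = shapes),
        "node", "i", "j", "pc1", "pc2", "valid"
      ),
      pc1_values = pc1_values,
      pc2_values = pc2_values,
      space = space
    ),
    class = "theoretical_grid"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf(
    "<shape_space: %d specimens x %d traits; PC1 %.1f%%, PC2 %.1f%% of variance>\n",
    nrow(x$scores), length(x$mean),
    100 * x$variance_explained[1], 100 * x$variance_explained[2]
  ))
  invisible(x)
}

#' @export
print.theoretical_grid <- function(x, ...) {
  cat(sprintf(
    "<theoretical_grid: %d x %d = %d nodes, %d valid (simple) shapes>\n",
    length(x$pc1_values), length(x$pc2_values), nrow(x$nodes),
    sum(x$nodes$valid)
  ))
  invisible(x)
}
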