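#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted shape space
#'
#' @param x A `shape_space`.
#' @param ... Ignored.
#' @return The specimen score tibble.
#' @method tidy shape_space
#' @export
tidy.shape_space <- function(x, ...) {
  x$scores
}

#' Variance summary of a shape space
#'
#' @param x A `shape_space`.
#' @param ... Ignored.
#' @return One row per axis: `axis`, `eigenvalue`, `variance_explained`,
#'   `cumulative`.
#' @method glance shape_space
#' @export
glance.shape_space <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_explained = x$variance_explained,
    cumulative = cumsum(x$variance_explained)
  )
}

#' Tidy an adaptive landscape
#'
#' @param x An `adaptive_landscape`.
#' @param ... Ignored.
#' @return The per-node tibble (`node`, `pc1`, `pc2`, `valid`, `r_optimal`,
#'   `r_suboptimal`, `rank`).
#' @method tidy adaptive_landscape
#' @export
tidy.adaptive_landscape <- function(x, ...) {
  x$nodes
}

#' Tidy a quadratic surface fit
#'
#' @param x A `quad_surface_fit`.
#' @param ... Ignored.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy quad_surface_fit
#' @export
tidy.quad_surface_fit <- function(x, ...) {
  tibble::tibble(
    term = c("1", "u", "v", "u^2", "u*v", "v^2"),
    estimate = as.numeric(x$coefficients)
  )
}

#' Fit statistics of a quadratic surface
#'
#' @param x A `quad_surface_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: `sse`, `rmse`, `r_squared`, `adj_r_squared`,
#'   `n`.
#' @method glance quad_surface_fit
#' @export
glance.quad_surface_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, rmse = x$rmse, r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared, n = x$n
  )
}

#' Summary of a phylogenetic signal test
#'
#' @param x A `kmult_test`.
#' @param ... Ignored.
#' @return A one-row tibble: `k_mult`, `p_value`, `n_permutations`.
#' @method glance kmult_test
#' @export
glance.kmult_test <- function(x, ...) {
  tibble::tibble(
    k_mult = x$k_mult, p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}

#' Tidy an ancestral-state reconstruction
#'
#' @param x An `ancestral_states`.
#' @param ... Ignored.
#' @return A tibble with `node` plus one column per trait.
#' @method tidy ancestral_states
#' @export
tidy.ancestral_states <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(node = rownames(x$states)),
    tibble::as_tibble(x$states)
  )
}
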