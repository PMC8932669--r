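#' Goldberg Pareto front ranking
#'
#' Iterative front peeling: the non-dominated set (rank 1) is removed, the
#' non-dominated set of the remainder gets rank 2, and so on. A solution
#' dominates another when it is better *or equal* in every metric and
#' strictly better in at least one; duplicated points therefore never
#' dominate each other and share a front.
#'
#' @param points A data frame or matrix whose columns are performance
#'   metrics (default orientation: first column maximized, second
#'   minimized - rotational efficiency and stress).
#' @param maximize Logical vector, one per metric: `TRUE` to treat larger
#'   values as better. Default `c(TRUE, FALSE)`.
#' @return Integer vector of front indices (1 = Pareto optimal front).
#' @export
goldberg_rank <- function(points, maximize = c(TRUE, FALSE)) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) rlang::abort("Performance values must be finite.")
  if (length(maximize) != ncol(m)) {
    rlang::abort("`maximize` must have one entry per metric column.")
  }
  # orient all metrics as maximized
  m[, !maximize] <- -m[, !maximize, drop = FALSE]
  n <- nrow(m)
  rank_out <- integer(n)
  remaining <- seq_len(n)
  front <- 0L
  while (length(remaining) > 0) {
    front <- front + 1L
    sub <- m[remaining, , drop = FALSE]
    nd <- non_dominated(sub)
    rank_out[remaining[nd]] <- front
    remaining <- remaining[!nd]
  }
  rank_out
}

# logical index of the non-dominated rows of a maximize-oriented matrix
non_dominated <- function(m) {
  n <- nrow(m)
  if (n == 1) return(TRUE)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    if (dominated[i]) next
    geq <- rep(TRUE, n)
    gt <- rep(FALSE, n)
    for (k in seq_len(ncol(m))) {
      geq <- geq & (m[, k] >= m[i, k])
      gt <- gt | (m[, k] > m[i, k])
    }
    dominated[i] <- any(geq & gt)
  }
  !dominated
}

#' Combined bidirectional Pareto rank
#'
#' Runs Goldberg front peeling twice - once with the stated metric
#' directions (optimal ranking, R_O) and once with every direction reversed
#' (suboptimal ranking, R_S) - and combines them as
#' `rank = (R_S - 1) / (R_O + R_S - 2)`, a linear score from 0 (dominant
#' over nothing) to 1 (dominated by nothing). A point on the first front in
#' *both* directions (0/0; e.g. the extreme corners of a pure trade-off set,
#' or a singleton) is assigned 0.5: it is simultaneously undominated and
#' non-dominating, and the symmetric midpoint keeps the score bounded. This
#' degenerate rule is configurable via `degenerate_rank`.
#'
#' @inheritParams goldberg_rank
#' @param degenerate_rank Value assigned when R_O = R_S = 1 (default 0.5).
#' @return A tibble with columns `r_optimal`, `r_suboptimal`, `rank`.
#' @export
combined_pareto_rank <- function(points, maximize = c(TRUE, FALSE),
                                 degenerate_rank = 0.5) {
  r_o <- goldberg_rank(points, maximize)
  r_s <- goldberg_rank(points, !maximize)
  denom <- r_o + r_s - 2L
  rank <- ifelse(denom == 0, degenerate_rank, (r_s - 1) / denom)
  tibble::tibble(r_optimal = r_o, r_suboptimal = r_s, rank = rank)
}

#' Build the adaptive landscape over a theoretical grid
#'
#' Attaches the combined bidirectional Pareto rank of each valid grid node
#' (metrics: mean rotational efficiency maximized, mean median-VMS
#' minimized) to the grid, producing the surface whose height is functional
#' optimality.
#'
#' @param perf A performance table from [grid_performance()] (one row per
#'   valid node with `node`, `re_mean`, `vms_mean`).
#' @param grid The `theoretical_grid` the performances were measured on.
#' @param metrics Character pair naming the performance columns (default
#'   `c("re_mean", "vms_mean")`).
#' @return An object of class `adaptive_landscape`: the grid axes, a tibble
#'   `nodes` (grid nodes joined to `r_optimal`, `r_suboptimal`, `rank`;
#'   invalid nodes carry NA), and a `rank_matrix` (`n1 x n2`).
#' @export
build_adaptive_landscape <- function(perf, grid,
                                     metrics = c("re_mean", "vms_mean")) {
  stopifnot(inherits(grid, "theoretical_grid"))
  valid_nodes <- grid$nodes$node[grid$nodes$valid]
  if (!all(valid_nodes %in% perf$node)) {
    rlang::abort("`perf` is missing records for some valid grid nodes.")
  }
  perf <- perf[match(valid_nodes, perf$node), , drop = FALSE]
  pr <- combined_pareto_rank(perf[, metrics])
  nodes <- dplyr::left_join(
    dplyr::select(grid$nodes, -"outline"),
    dplyr::bind_cols(tibble::tibble(node = valid_nodes), pr),
    by = "node"
  )
  n1 <- length(grid$pc1_values); n2 <- length(grid$pc2_values)
  rank_matrix <- matrix(NA_real_, n1, n2)
  rank_matrix[cbind(nodes$i, nodes$j)] <- nodes$rank
  structure(
    list(
      nodes = nodes,
      pc1_values = grid$pc1_values,
      pc2_values = grid$pc2_values,
      rank_matrix = rank_matrix
    ),
    class = "adaptive_landscape"
  )
}

#' Interpolate optimality at morphospace coordinates
#'
#' Bilinear interpolation of the adaptive-landscape rank over the four grid
#' nodes surrounding each query point. Queries outside the grid limits, or
#' inside a cell with any geometrically invalid (self-intersecting) corner,
#' are out of domain.
#'
#' @param landscape An `adaptive_landscape`.
#' @param pc1,pc2 Numeric vectors of query coordinates.
#' @param strict If `TRUE` (default) out-of-domain queries raise an error
#'   naming the offending indices; if `FALSE` they yield `NA`.
#' @return Numeric vector of interpolated ranks in \[0, 1\].
#' @export
interpolate_optimality <- function(landscape, pc1, pc2, strict = TRUE) {
  stopifnot(inherits(landscape, "adaptive_landscape"))
  xs <- landscape$pc1_values; ys <- landscape$pc2_values
  rm <- landscape$rank_matrix
  n <- length(pc1)
  out <- rep(NA_real_, n)
  i <- findInterval(pc1, xs)
  j <- findInterval(pc2, ys)
  # clamp exact upper-edge queries into the last cell
  i[pc1 == xs[length(xs)]] <- length(xs) - 1L
  j[pc2 == ys[length(ys)]] <- length(ys) - 1L
  inside <- i >= 1 & i < length(xs) & j >= 1 & j < length(ys)
  for (k in which(inside)) {
    q <- rm[c(i[k], i[k] + 1L), c(j[k], j[k] + 1L)]
    if (anyNA(q)) next
    tx <- (pc1[k] - xs[i[k]]) / (xs[i[k] + 1L] - xs[i[k]])
    ty <- (pc2[k] - ys[j[k]]) / (ys[j[k] + 1L] - ys[j[k]])
    out[k] <- (1 - tx) * (1 - ty) * q[1, 1] + tx * (1 - ty) * q[2, 1] +
      (1 - tx) * ty * q[1, 2] + tx * ty * q[2, 2]
  }
  if (strict && anyNA(out)) {
    bad <- which(is.na(out))
    rlang::abort(sprintf(
      "Out-of-domain morphospace coordinates at indices: %s",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

#' @export
print.adaptive_landscape <- function(x, ...) {
  cat(sprintf(
    "<adaptive_landscape: %d x %d grid, %d ranked nodes, rank range [%.3g, %.3g]>\n",
    length(x$pc1_values), length(x$pc2_values), sum(!is.na(x$nodes$rank)),
    min(x$nodes$rank, na.rm = TRUE), max(x$nodes$rank, na.rm = TRUE)
  ))
  invisible(x)
}
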