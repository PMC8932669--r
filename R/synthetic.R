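#' Parameters for a synthetic jaw outline
#'
#' The synthetic jaw family spans the two axes of variation that dominate
#' lateral jaw silhouettes: elongation (length/depth ratio) and the
#' convex-to-concave transition of the dorsal margin. The blade is built from
#' a convex ventral margin and a near-straight dorsal margin, both pinched to
#' zero thickness at the posterior (joint) and anterior (bite) ends:
#'
#' * dorsal margin: `y = (1 - taper*t) * (0.15 sin(pi t)^3 - dorsal_curvature * sin(pi t))`
#' * ventral margin: `y = -(1 - taper*t) * 0.85 sin(pi t)`
#'
#' with `x = length_depth_ratio * t`, `t` in `[0, 1]` running posterior to
#' anterior. Positive `dorsal_curvature` dips the dorsal margin below the
#' posterior-anterior chord (concave), negative values bulge it above
#' (convex). `roughness` adds a smooth band-limited perturbation to each
#' margin, tapered to zero at the ends.
#'
#' Valid parameter box (generation refuses outside it, because
#' self-intersection becomes possible): `length_depth_ratio` in \[1.5, 8\],
#' `dorsal_curvature` in \[-0.5, 0.5\], `taper` in \[0, 0.8\], `roughness`
#' in \[0, 0.02\], `n_points >= 100`.
#'
#' @param length_depth_ratio Jaw length / maximum depth (dimensionless).
#' @param dorsal_curvature Negative = convex dorsal margin, positive =
#'   concave, 0 = straight.
#' @param taper Anterior thinning in \[0, 1).
#' @param roughness Amplitude of the high-frequency margin perturbation.
#' @param n_points Number of outline vertices (>= 100).
#' @return A list of class `jaw_params`.
#' @export
jaw_params <- function(length_depth_ratio = 3.5, dorsal_curvature = 0,
                       taper = 0.3, roughness = 0, n_points = 600) {
  p <- list(
    length_depth_ratio = length_depth_ratio,
    dorsal_curvature = dorsal_curvature,
    taper = taper,
    roughness = roughness,
    n_points = as.integer(n_points)
  )
  class(p) <- "jaw_params"
  p
}

validate_jaw_params <- function(params) {
  stopifnot(inherits(params, "jaw_params"))
  ok <- params$length_depth_ratio >= 1.5 && params$length_depth_ratio <= 8 &&
    abs(params$dorsal_curvature) <= 0.5 &&
    params$taper >= 0 && params$taper <= 0.8 &&
    params$roughness >= 0 && params$roughness <= 0.02 &&
    params$n_points >= 100
  if (!ok) {
    rlang::abort(paste(
      "Jaw parameters outside the valid box:",
      "ratio in [1.5, 8], |curvature| <= 0.5, taper in [0, 0.8],",
      "roughness in [0, 0.02], n_points >= 100."
    ))
  }
  invisible(params)
}

#' Generate a synthetic jaw-like outline
#'
#' Builds a closed, simple, counterclockwise outline in the canonical
#' anatomical frame (posterior joint at the origin, anterior bite tip at +x,
#' dorsal margin up). Deterministic for a fixed seed.
#'
#' @param params A [jaw_params()] object within the documented valid box.
#' @param seed Integer seed controlling the roughness perturbation.
#' @return A `jaw_outline` with `params$n_points` vertices.
#' @export
#' @examples
#' jaw <- generate_jaw_outline(jaw_params(length_depth_ratio = 4), seed = 1)
#' detect_self_intersection(jaw)
generate_jaw_outline <- function(params, seed = 1) {
  validate_jaw_params(params)
  L <- params$length_depth_ratio
  cv <- params$dorsal_curvature
  tp <- params$taper
  rg <- params$roughness

  # dense parameter sampling of both margins, then equal arc-length resampling
  nd <- max(4 * params$n_points, 1200)
  t_v <- seq(0, 1, length.out = nd %/% 2 + 1)          # ventral, posterior -> anterior
  t_d <- seq(1, 0, length.out = nd %/% 2 + 1)          # dorsal, anterior -> posterior
  pinch <- function(t) 1 - tp * t
  y_v <- -pinch(t_v) * 0.85 * sin(pi * t_v)
  y_d <- pinch(t_d) * (0.15 * sin(pi * t_d)^3 - cv * sin(pi * t_d))
  if (rg > 0) {
    pert <- withr::with_seed(seed, {
      k <- 3:8
      amp_v <- stats::rnorm(length(k)); ph_v <- stats::runif(length(k), 0, 2 * pi)
      amp_d <- stats::rnorm(length(k)); ph_d <- stats::runif(length(k), 0, 2 * pi)
      list(
        v = rowSums(sapply(seq_along(k), function(i) {
          amp_v[i] * sin(2 * pi * k[i] * t_v + ph_v[i])
        })) / sqrt(length(k)),
        d = rowSums(sapply(seq_along(k), function(i) {
          amp_d[i] * sin(2 * pi * k[i] * t_d + ph_d[i])
        })) / sqrt(length(k))
      )
    })
    y_v <- y_v - rg * abs(pert$v) * sin(pi * t_v)
    y_d <- y_d + rg * abs(pert$d) * sin(pi * t_d)
  }
  x <- c(L * t_v, L * t_d[-1][- (nd %/% 2)])
  y <- c(y_v, y_d[-1][- (nd %/% 2)])
  dense <- as_outline(data.frame(x = x, y = y))
  resample_outline(dense, params$n_points)
}

#' Generate a synthetic taxon set with outlines and stratigraphic ranges
#'
#' Draws jaw parameters from a documented distribution (log-normal
#' length/depth ratio centred near 3.5, Gaussian dorsal curvature truncated
#' to the valid box, uniform taper), assigns each taxon to one of the four
#' early gnathostome clades with probabilities proportional to the empirical
#' clade sizes (57:48:8:8), and samples range-through-compatible first/last
#' appearances inside the overall bin span.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param bins A time-bin table as returned by [devonian_bins()].
#' @param seed Integer seed.
#' @param n_points Vertices per outline.
#' @return A tibble with columns `taxon_id`, `clade`, `first_appearance`,
#'   `last_appearance`, `raw_length`, the generating parameters, and a
#'   list-column `outline`.
#' @export
generate_taxon_set <- function(n_taxa = 121, bins = devonian_bins(), seed = 1,
                               n_points = 600) {
  if (n_taxa < 2) rlang::abort("`n_taxa` must be at least 2.")
  oldest <- max(bins$older_bound)
  youngest <- min(bins$younger_bound)
  withr::with_seed(seed, {
    ratio <- pmin(pmax(stats::rlnorm(n_taxa, log(3.5), 0.22), 1.6), 7.5)
    curv <- pmin(pmax(stats::rnorm(n_taxa, 0, 0.15), -0.45), 0.45)
    taper <- stats::runif(n_taxa, 0.15, 0.55)
    rough <- stats::runif(n_taxa, 0, 0.008)
    clade <- sample(
      c("Sarcopterygii", "Placodermi", "Chondrichthyes", "Actinopterygii"),
      n_taxa, replace = TRUE, prob = c(57, 48, 8, 8) / 121
    )
    first <- stats::runif(n_taxa, youngest + 2, oldest)
    duration <- stats::rexp(n_taxa, rate = 1 / 10)
    last <- pmax(first - duration, youngest)
    raw_length <- stats::rlnorm(n_taxa, log(10), 0.4)
    seeds <- sample.int(1e6, n_taxa)
    outlines <- purrr::map(seq_len(n_taxa), function(i) {
      generate_jaw_outline(
        jaw_params(ratio[i], curv[i], taper[i], rough[i], n_points),
        seed = seeds[i]
      )
    })
    tibble::tibble(
      taxon_id = sprintf("taxon_%03d", seq_len(n_taxa)),
      clade = clade,
      first_appearance = first,
      last_appearance = last,
      raw_length = raw_length,
      length_depth_ratio = ratio,
      dorsal_curvature = curv,
      taper = taper,
      roughness = rough,
      outline = outlines
    )
  })
}

#' Simulate a time-calibrated birth-death tree
#'
#' Wraps [ape::rphylo()] (birth-death process conditioned on the number of
#' extant tips) and rescales branch lengths so the root-to-tip depth equals
#' `root_age`. Deterministic for a fixed seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in Ma (> 0).
#' @param seed Integer seed.
#' @param tip_labels Optional character vector of tip labels (length
#'   `n_tips`).
#' @return A rooted binary `phylo` object with all branch lengths > 0.
#' @export
generate_timed_tree <- function(n_tips, root_age = 100, seed = 1,
                                tip_labels = NULL) {
  if (n_tips < 2) rlang::abort("`n_tips` must be at least 2.")
  if (root_age <= 0) rlang::abort("`root_age` must be positive.")
  tree <- withr::with_seed(seed, {
    ape::rphylo(n_tips, birth = 0.1, death = 0.03)
  })
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * root_age / depth
  # guard against numerically zero branches from the simulator
  tree$edge.length <- pmax(tree$edge.length, root_age * 1e-9)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- tip_labels
  }
  tree
}

#' Simulate multivariate Brownian motion on a tree
#'
#' Gaussian increments along each branch with covariance
#' `rate_matrix * branch_length`, accumulated from the root. Returns both tip
#' and internal-node states so ancestral-state estimators can be tested
#' against the truth.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param root_state Numeric vector of root trait values (length p).
#' @param rate_matrix p x p symmetric positive semi-definite rate matrix (a
#'   single number is taken as a 1x1 matrix).
#' @param seed Integer seed.
#' @return A list with `tip_states` (n x p matrix, rownames = tip labels) and
#'   `node_states` (internal nodes x p, rownames = node numbers).
#' @export
simulate_bm_traits <- function(tree, root_state, rate_matrix, seed = 1) {
  if (is.null(tree$edge.length)) rlang::abort("Tree must have branch lengths.")
  root_state <- as.numeric(root_state)
  p <- length(root_state)
  rate_matrix <- as.matrix(rate_matrix)
  if (!isTRUE(all.equal(rate_matrix, t(rate_matrix), tolerance = 1e-8))) {
    rlang::abort("`rate_matrix` must be symmetric.")
  }
  ev <- eigen(rate_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    rlang::abort("`rate_matrix` must be positive semi-definite.")
  }
  sq <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1
  states <- matrix(NA_real_, n_tip + n_node, p)
  states[root, ] <- root_state
  edge <- tree$edge
  # preorder: reverse of postorder guarantees parents before children
  ord <- rev(ape::postorder(tree))
  z <- withr::with_seed(seed, {
    matrix(stats::rnorm(nrow(edge) * p), nrow(edge), p)
  })
  for (k in ord) {
    par <- edge[k, 1]; child <- edge[k, 2]
    states[child, ] <- states[par, ] +
      sqrt(tree$edge.length[k]) * as.numeric(sq %*% z[k, ])
  }
  tips <- states[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  nodes <- states[(n_tip + 1):(n_tip + n_node), , drop = FALSE]
  rownames(nodes) <- as.character((n_tip + 1):(n_tip + n_node))
  list(tip_states = tips, node_states = nodes)
}
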