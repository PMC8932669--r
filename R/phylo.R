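#' Read and validate a time-calibrated tree
#'
#' Parses Newick text (or a file) with [ape::read.tree()] and checks the
#' contract the comparative methods rely on: rooted topology, branch lengths
#' present and strictly positive, unique tip labels.
#'
#' @param newick Newick string, or path to a Newick file.
#' @return A validated `phylo` object.
#' @export
read_timed_tree <- function(newick) {
  tree <- if (length(newick) == 1 && !grepl("\\(", newick)) {
    ape::read.tree(file = newick)
  } else {
    ape::read.tree(text = newick)
  }
  if (is.null(tree)) rlang::abort("Could not parse Newick input.")
  validate_timed_tree(tree)
}

validate_timed_tree <- function(tree) {
  if (is.null(tree$edge.length)) {
    rlang::abort("Tree has no branch lengths; a time-calibrated tree is required.")
  }
  if (any(tree$edge.length <= 0)) {
    rlang::abort("All branch lengths must be strictly positive.")
  }
  if (anyDuplicated(tree$tip.label)) {
    rlang::abort("Tip labels must be unique.")
  }
  # a basal polytomy (e.g. a star tree) is treated as a rooted polytomy
  tree
}

# shared-path-length (phylogenetic) covariance of every node pair
tree_covariances <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  C <- matrix(depth[M], nrow(M), nrow(M))
  list(
    tips = C[seq_len(n), seq_len(n), drop = FALSE],
    nodes_tips = C[(n + 1):(n + tree$Nnode), seq_len(n), drop = FALSE]
  )
}

#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood (generalized least squares) ancestral states under
#' independent per-trait Brownian motion: the root is the GLS mean
#' `(1' C^-1 Y) / (1' C^-1 1)` and internal nodes are the conditional
#' expectations `root + C_at C^-1 (Y - root)`, where C is the shared-path
#' covariance. Traits are treated independently, which is exact for BM with
#' any trait covariance because the estimator is linear in the data.
#'
#' @param tree A validated `phylo` (see [read_timed_tree()]).
#' @param tip_matrix Numeric matrix (tips x traits) with rownames matching
#'   tip labels, or a tibble with a `taxon_id` column.
#' @return An object of class `ancestral_states`: `states` (internal nodes x
#'   traits, rownames = ape node numbers), `root` (the root state vector),
#'   and the `tree`.
#' @export
asr_bm <- function(tree, tip_matrix) {
  validate_timed_tree(tree)
  Y <- prep_tip_matrix(tree, tip_matrix)
  cv <- tree_covariances(tree)
  n <- nrow(Y)
  one <- rep(1, n)
  Cinv_Y <- solve(cv$tips, Y)
  Cinv_1 <- solve(cv$tips, one)
  root <- as.numeric(crossprod(one, Cinv_Y)) / sum(Cinv_1)
  centred <- sweep(Y, 2, root)
  anc <- cv$nodes_tips %*% solve(cv$tips, centred)
  anc <- sweep(anc, 2, root, `+`)
  rownames(anc) <- as.character((n + 1):(n + tree$Nnode))
  colnames(anc) <- colnames(Y)
  structure(
    list(states = anc, root = stats::setNames(root, colnames(Y)), tree = tree),
    class = "ancestral_states"
  )
}

prep_tip_matrix <- function(tree, tip_matrix) {
  if (is.data.frame(tip_matrix)) {
    if (!"taxon_id" %in% names(tip_matrix)) {
      rlang::abort("Data frame tip data needs a `taxon_id` column.")
    }
    ids <- tip_matrix$taxon_id
    tip_matrix <- as.matrix(dplyr::select(tip_matrix, -"taxon_id"))
    rownames(tip_matrix) <- ids
  }
  if (is.null(rownames(tip_matrix))) {
    rlang::abort("Tip data must carry taxon names (rownames or `taxon_id`).")
  }
  missing <- setdiff(tree$tip.label, rownames(tip_matrix))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Missing tip data for: %s",
                         paste(missing, collapse = ", ")))
  }
  m <- tip_matrix[tree$tip.label, , drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) rlang::abort("Tip data contain NA.")
  m
}

#' Phylomorphospace coordinates
#'
#' Tips take their empirical PC scores from the fitted shape space;
#' ancestors are projected with the same loadings (they do not influence the
#' ordination). Returns node coordinates and the tree's edges between them,
#' ready for plotting over an adaptive landscape.
#'
#' @param space A fitted `shape_space`.
#' @param tree A validated `phylo` whose tips are a subset of the specimens.
#' @param tip_matrix Tip coefficient data (as for [asr_bm()]).
#' @param ancestors Optional `ancestral_states`; computed with [asr_bm()]
#'   when omitted.
#' @return A list of class `phylomorphospace` with tibbles `vertices`
#'   (`label`, `type`, `pc1`, `pc2`) and `edges` (`pc1`, `pc2`, `pc1_end`,
#'   `pc2_end`).
#' @export
phylomorphospace <- function(space, tree, tip_matrix, ancestors = NULL) {
  stopifnot(inherits(space, "shape_space"))
  validate_timed_tree(tree)
  Y <- prep_tip_matrix(tree, tip_matrix)
  if (is.null(ancestors)) ancestors <- asr_bm(tree, Y)
  n <- length(tree$tip.label)
  tip_sc <- project_shapes(space, Y)
  anc_sc <- project_shapes(space, ancestors$states)
  vertices <- tibble::tibble(
    label = c(tree$tip.label, rownames(ancestors$states)),
    type = rep(c("tip", "ancestor"), c(n, tree$Nnode)),
    pc1 = c(tip_sc$PC1, anc_sc$PC1),
    pc2 = c(tip_sc$PC2, anc_sc$PC2)
  )
  edges <- tibble::tibble(
    pc1 = vertices$pc1[tree$edge[, 1]],
    pc2 = vertices$pc2[tree$edge[, 1]],
    pc1_end = vertices$pc1[tree$edge[, 2]],
    pc2_end = vertices$pc2[tree$edge[, 2]]
  )
  structure(
    list(vertices = vertices, edges = edges, tree = tree),
    class = "phylomorphospace"
  )
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' The multivariate generalization of Blomberg's K: the ratio of among-tip
#' to phylogenetically corrected trait variation, scaled by its Brownian
#' expectation so that K = 1 under BM on the given tree. Significance is
#' assessed by permuting tip rows and counting permutations with K at least
#' as large as observed, p = (b + 1) / (n_permutations + 1).
#'
#' @param tree A validated `phylo` with >= 4 tips.
#' @param tip_matrix Tip trait data (as for [asr_bm()]).
#' @param n_permutations Number of row permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `kmult_test`: `k_mult`, `p_value`,
#'   `n_permutations`.
#' @export
kmult <- function(tree, tip_matrix, n_permutations = 999, seed = 1) {
  validate_timed_tree(tree)
  Y <- prep_tip_matrix(tree, tip_matrix)
  n <- nrow(Y)
  if (n < 4) rlang::abort("K_mult needs at least 4 tips.")
  if (all(apply(Y, 2, stats::sd) == 0)) {
    rlang::abort("Constant tip data: K_mult is undefined.")
  }
  C <- tree_covariances(tree)$tips
  Cinv <- solve(C)
  one <- rep(1, n)
  denom_exp <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_of <- function(Ym) {
    root <- as.numeric(crossprod(one, Cinv %*% Ym)) / sum(Cinv)
    R <- sweep(Ym, 2, root)
    num <- sum(R^2)
    den <- sum(R * (Cinv %*% R))
    (num / den) / denom_exp
  }
  k_obs <- k_of(Y)
  perms <- withr::with_seed(seed, {
    replicate(n_permutations, sample.int(n))
  })
  k_perm <- apply(perms, 2, function(ix) k_of(Y[ix, , drop = FALSE]))
  p <- (sum(k_perm >= k_obs) + 1) / (n_permutations + 1)
  structure(
    list(k_mult = k_obs, p_value = p, n_permutations = n_permutations),
    class = "kmult_test"
  )
}

#' @export
print.kmult_test <- function(x, ...) {
  cat(sprintf("K_mult = %.5f, p = %.4g (%d permutations)\n",
              x$k_mult, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states: %d internal nodes x %d traits>\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}
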