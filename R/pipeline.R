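#' Run the full theoretical-morphospace pipeline on synthetic data
#'
#' Chains every stage of the analysis: synthetic taxa with jaw outlines and
#' stratigraphic ranges; elliptic Fourier decomposition; PCA morphospace;
#' evenly spaced theoretical grid with self-intersection screening and area
#' standardization; per-shape Monte-Carlo rotational efficiency and median
#' von Mises stress; quadratic performance surfaces; bidirectional Pareto
#' adaptive landscape; time-calibrated tree, ancestral reconstruction,
#' phylomorphospace and multivariate phylogenetic signal; and per-bin
#' disparity/optimality with bootstrap CIs plus trend tests.
#'
#' Defaults correspond to the full study design (121 taxa, 23 x 21 grid,
#' 2500-element meshes, 1000 replicates, 10,000 bootstraps); pass smaller
#' values for a reduced run.
#'
#' @param n_taxa Number of synthetic taxa.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param bins Time-bin table (default [devonian_bins()]).
#' @param n_harmonics EFA harmonics (default 12).
#' @param outline_points Outline resampling density (default 600).
#' @param grid_dims Grid dimensions c(n1, n2) along PC1/PC2 (default
#'   c(23, 21)).
#' @param border_fraction Morphospace border as a fraction of the PC1 range
#'   (default 0.2).
#' @param target_elements Mesh density per theoretical shape (default 2500).
#' @param n_replicates Monte-Carlo replicates per shape (default 1000).
#' @param n_boot Bootstrap replicates per bin (default 10000).
#' @param n_permutations Permutations for the phylogenetic signal test
#'   (default 999).
#' @return A list of class `jaw_pipeline` with components `taxa`, `coeffs`,
#'   `space`, `grid`, `performance`, `surface_fits`, `landscape`, `tree`,
#'   `ancestors`, `phylomorphospace`, `kmult`, `membership`,
#'   `taxon_optimality`, `disparity`, `trends`.
#' @export
run_jaw_pipeline <- function(n_taxa = 121, seed = 1, bins = devonian_bins(),
                             n_harmonics = 12, outline_points = 600,
                             grid_dims = c(23, 21), border_fraction = 0.2,
                             target_elements = 2500, n_replicates = 1000,
                             n_boot = 10000, n_permutations = 999) {
  taxa <- generate_taxon_set(n_taxa, bins, seed = seed,
                             n_points = outline_points)
  coeffs <- efa_table(taxa, n_harmonics = n_harmonics,
                      n_points = outline_points)
  space <- fit_shape_space(coeffs)
  grid <- build_theoretical_grid(space, grid_dims[1], grid_dims[2],
                                 border_fraction = border_fraction)
  perf <- grid_performance(grid, target_elements = target_elements,
                           n_replicates = n_replicates, seed = seed + 1000L)
  surface_fits <- list(
    re = fit_quadratic_surface(perf[, c("pc1", "pc2")], perf$re_mean),
    vms = fit_quadratic_surface(perf[, c("pc1", "pc2")], perf$vms_mean)
  )
  landscape <- build_adaptive_landscape(perf, grid)

  root_age <- max(bins$older_bound) + 10
  tree <- generate_timed_tree(n_taxa, root_age = root_age, seed = seed + 2L,
                              tip_labels = taxa$taxon_id)
  ancestors <- asr_bm(tree, coeffs)
  pms <- phylomorphospace(space, tree, coeffs, ancestors)
  ksig <- kmult(tree, coeffs, n_permutations = n_permutations,
                seed = seed + 3L)

  membership <- time_bin_taxa(taxa, bins)
  opt <- interpolate_optimality(landscape, space$scores$PC1,
                                space$scores$PC2, strict = FALSE)
  taxon_optimality <- tibble::tibble(
    taxon_id = space$scores$taxon_id,
    pc1 = space$scores$PC1, pc2 = space$scores$PC2,
    optimality = opt
  )
  dtt <- disparity_through_time(membership, coeffs, space$scores, landscape,
                                n_boot = n_boot, seed = seed + 4L,
                                na_action = "omit")
  trends <- trend_tests(dtt)

  structure(
    list(
      taxa = taxa, coeffs = coeffs, space = space, grid = grid,
      performance = perf, surface_fits = surface_fits,
      landscape = landscape, tree = tree, ancestors = ancestors,
      phylomorphospace = pms, kmult = ksig, membership = membership,
      taxon_optimality = taxon_optimality, disparity = dtt, trends = trends,
      seed = seed
    ),
    class = "jaw_pipeline"
  )
}

#' @export
print.jaw_pipeline <- function(x, ...) {
  cat("Theoretical-morphospace pipeline\n")
  cat(sprintf("  taxa: %d; grid: %d x %d (%d valid shapes)\n",
              nrow(x$taxa), length(x$grid$pc1_values),
              length(x$grid$pc2_values), sum(x$grid$nodes$valid)))
  cat(sprintf("  PC1 + PC2 variance: %.1f%%\n",
              100 * sum(x$space$variance_explained[1:2])))
  cat(sprintf("  K_mult = %.4f (p = %.4g)\n", x$kmult$k_mult,
              x$kmult$p_value))
  cat(sprintf("  landscape rank range: [%.3f, %.3f]\n",
              min(x$landscape$nodes$rank, na.rm = TRUE),
              max(x$landscape$nodes$rank, na.rm = TRUE)))
  cat(sprintf("  bins with data: %d\n", nrow(x$disparity)))
  invisible(x)
}
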