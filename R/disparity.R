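#' Late Silurian and Devonian stage bins
#'
#' The default time bins: one merged late Silurian bin (Ludlow + Pridoli)
#' followed by the seven Devonian stages, with ICS 2020 boundary ages in Ma.
#' Any table with columns `bin`, `older_bound`, `younger_bound` (contiguous,
#' ordered old to young) can be substituted.
#'
#' @return A tibble with columns `bin`, `older_bound`, `younger_bound`.
#' @export
devonian_bins <- function() {
  tibble::tribble(
    ~bin,            ~older_bound, ~younger_bound,
    "late Silurian",        427.4,          419.2,
    "Lochkovian",           419.2,          410.8,
    "Pragian",              410.8,          407.6,
    "Emsian",               407.6,          393.3,
    "Eifelian",             393.3,          387.7,
    "Givetian",             387.7,          382.7,
    "Frasnian",             382.7,          372.2,
    "Famennian",            372.2,          358.9
  )
}

#' Assign taxa to time bins with range-through
#'
#' A taxon is a member of every bin its stratigraphic range overlaps, and of
#' every bin between its first and last occupied bin (range-through), so
#' sampling gaps inside a range do not break the series.
#'
#' @param records A data frame with `taxon_id`, `first_appearance`,
#'   `last_appearance` (ages in Ma, first >= last).
#' @param bins A bin table (see [devonian_bins()]).
#' @return A tibble `bin` (ordered old to young), `taxon_id` membership
#'   pairs.
#' @export
time_bin_taxa <- function(records, bins = devonian_bins()) {
  if (any(records$first_appearance < records$last_appearance)) {
    rlang::abort("`first_appearance` must be >= `last_appearance` (ages run backward).")
  }
  nb <- nrow(bins)
  members <- purrr::map(seq_len(nrow(records)), function(r) {
    fa <- records$first_appearance[r]
    la <- records$last_appearance[r]
    hit <- which(fa >= bins$younger_bound & la <= bins$older_bound)
    if (length(hit) == 0) {
      rlang::abort(sprintf(
        "Taxon %s (range %.1f-%.1f Ma) falls outside every bin.",
        records$taxon_id[r], fa, la
      ))
    }
    seq(min(hit), max(hit))  # range-through
  })
  out <- tibble::tibble(
    taxon_id = rep(records$taxon_id, lengths(members)),
    bin_index = unlist(members)
  )
  out <- dplyr::mutate(
    out,
    bin = factor(bins$bin[.data$bin_index], levels = bins$bin)
  )
  dplyr::arrange(
    dplyr::select(out, "bin", "taxon_id"),
    .data$bin
  )
}

#' Disparity metrics of a trait sample
#'
#' Sum of variances: total of the per-trait sample variances (n - 1
#' denominator). Mean pairwise distance: mean Euclidean distance over all
#' unordered row pairs. Both are computed on the harmonic coefficient data,
#' not on PC scores. A single row gives sov = 0 by convention and mpd = NA.
#'
#' @param m Numeric matrix or data frame (taxa x traits; a `taxon_id` column
#'   is dropped).
#' @return A named list with `sov` and `mpd`.
#' @export
disparity_metrics <- function(m) {
  if (is.data.frame(m)) {
    m <- as.matrix(m[, setdiff(names(m), "taxon_id"), drop = FALSE])
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 1) rlang::abort("Need at least one row.")
  if (nrow(m) == 1) return(list(sov = 0, mpd = NA_real_))
  list(
    sov = sum(apply(m, 2, stats::var)),
    mpd = mean(stats::dist(m))
  )
}

#' Bootstrap summary of a row-resampled metric
#'
#' Resamples rows with replacement `n_boot` times, recomputes the metric,
#' and reports the bootstrap mean with the empirical 2.5% and 97.5%
#' percentiles as the 95% confidence interval.
#'
#' @param metric_fn Function of a matrix returning a single number.
#' @param m Matrix (rows resampled).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return A named list `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_summary <- function(metric_fn, m, n_boot = 10000, seed = 1) {
  if (is.data.frame(m)) {
    m <- as.matrix(m[, setdiff(names(m), "taxon_id"), drop = FALSE])
  }
  n <- nrow(m)
  if (n < 1) rlang::abort("Need at least one row.")
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      metric_fn(m[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  list(
    mean = mean(vals, na.rm = TRUE),
    ci_low = as.numeric(stats::quantile(vals, 0.025, na.rm = TRUE)),
    ci_high = as.numeric(stats::quantile(vals, 0.975, na.rm = TRUE))
  )
}

#' Per-bin disparity and optimality through time
#'
#' For each time bin: the number of member taxa, sum of variances and mean
#' pairwise distance on the coefficient data with bootstrap CIs, and the
#' mean interpolated optimality of the members with bootstrap CIs.
#'
#' @param membership Output of [time_bin_taxa()].
#' @param coeffs Coefficient table with `taxon_id` (e.g. [efa_table()]).
#' @param taxon_scores Tibble with `taxon_id`, `PC1`, `PC2` (e.g. the fitted
#'   space's `scores`).
#' @param landscape An `adaptive_landscape` (optional; optimality columns
#'   are omitted when `NULL`).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param na_action What to do with taxa whose coordinates cannot be
#'   interpolated on the landscape: `"error"` (default, reports the taxa) or
#'   `"omit"` (drops them from the optimality summaries with a warning).
#' @return A tibble, one row per occupied bin, ordered old to young.
#' @export
disparity_through_time <- function(membership, coeffs, taxon_scores = NULL,
                                   landscape = NULL, n_boot = 10000,
                                   seed = 1, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  cm <- as.matrix(coeffs[, setdiff(names(coeffs), "taxon_id"), drop = FALSE])
  rownames(cm) <- coeffs$taxon_id
  opt <- NULL
  if (!is.null(landscape)) {
    if (is.null(taxon_scores)) {
      rlang::abort("`taxon_scores` are required to interpolate optimality.")
    }
    vals <- interpolate_optimality(landscape, taxon_scores$PC1,
                                   taxon_scores$PC2, strict = FALSE)
    if (anyNA(vals)) {
      bad <- taxon_scores$taxon_id[is.na(vals)]
      msg <- sprintf("Out-of-domain morphospace coordinates for taxa: %s",
                     paste(bad, collapse = ", "))
      if (na_action == "error") rlang::abort(msg) else rlang::warn(msg)
    }
    opt <- stats::setNames(vals, taxon_scores$taxon_id)
  }
  bins <- levels(membership$bin)
  rows <- purrr::map(seq_along(bins), function(bi) {
    ids <- membership$taxon_id[membership$bin == bins[bi]]
    if (length(ids) == 0) return(NULL)
    sub <- cm[ids, , drop = FALSE]
    dm <- disparity_metrics(sub)
    sov_bs <- bootstrap_summary(function(x) disparity_metrics(x)$sov, sub,
                                n_boot, seed = seed + 7L * bi)
    mpd_bs <- bootstrap_summary(function(x) disparity_metrics(x)$mpd, sub,
                                n_boot, seed = seed + 7L * bi + 1L)
    row <- tibble::tibble(
      bin = bins[bi], n_taxa = length(ids),
      sov = dm$sov, sov_boot_mean = sov_bs$mean,
      sov_ci_low = sov_bs$ci_low, sov_ci_high = sov_bs$ci_high,
      mpd = dm$mpd, mpd_boot_mean = mpd_bs$mean,
      mpd_ci_low = mpd_bs$ci_low, mpd_ci_high = mpd_bs$ci_high
    )
    if (!is.null(opt)) {
      ov <- opt[ids]
      ov <- ov[!is.na(ov)]
      if (length(ov) == 0) ov <- NA_real_
      ob <- bootstrap_summary(function(x) mean(x[, 1]),
                              matrix(ov, ncol = 1), n_boot,
                              seed = seed + 7L * bi + 2L)
      row <- dplyr::bind_cols(row, tibble::tibble(
        mean_optimality = mean(ov),
        opt_boot_mean = ob$mean,
        opt_ci_low = ob$ci_low, opt_ci_high = ob$ci_high
      ))
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Mean optimality of one bin's members with bootstrap CI
#'
#' @param taxon_ids Members of the bin.
#' @param taxon_scores Tibble with `taxon_id`, `PC1`, `PC2`.
#' @param landscape An `adaptive_landscape`.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return A named list `mean`, `ci_low`, `ci_high`.
#' @export
mean_bin_optimality <- function(taxon_ids, taxon_scores, landscape,
                                n_boot = 10000, seed = 1) {
  sel <- match(taxon_ids, taxon_scores$taxon_id)
  if (anyNA(sel)) {
    rlang::abort(sprintf("No scores for taxa: %s",
                         paste(taxon_ids[is.na(sel)], collapse = ", ")))
  }
  vals <- interpolate_optimality(landscape, taxon_scores$PC1[sel],
                                 taxon_scores$PC2[sel], strict = FALSE)
  if (anyNA(vals)) {
    rlang::abort(sprintf(
      "Out-of-domain morphospace coordinates for taxa: %s",
      paste(taxon_ids[is.na(vals)], collapse = ", ")
    ))
  }
  bs <- bootstrap_summary(function(x) mean(x[, 1]), matrix(vals, ncol = 1),
                          n_boot, seed)
  c(list(point = mean(vals)), bs)
}

#' Trend and association tests on per-bin series
#'
#' Spearman rank correlation of each metric against bin order (old to
#' young), and Pearson correlation between mean optimality and each
#' disparity metric, mirroring the standard tests for directional trends in
#' disparity-through-time series.
#'
#' @param dtt A table from [disparity_through_time()] ordered old to young.
#' @return A tibble with `test`, `statistic` (rho or r), `p_value`, `n`.
#' @export
trend_tests <- function(dtt) {
  if (nrow(dtt) < 3) rlang::abort("Need at least 3 bins for trend tests.")
  ord <- seq_len(nrow(dtt))
  one <- function(name, x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rlang::abort(sprintf("Constant series in test '%s': correlation undefined.", name))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    tibble::tibble(
      test = name, statistic = as.numeric(ct$estimate),
      p_value = ct$p.value, n = length(x)
    )
  }
  out <- dplyr::bind_rows(
    one("sov_trend", ord, dtt$sov, "spearman"),
    one("mpd_trend", ord, dtt$mpd, "spearman")
  )
  if ("mean_optimality" %in% names(dtt)) {
    out <- dplyr::bind_rows(
      out,
      one("optimality_trend", ord, dtt$mean_optimality, "spearman"),
      one("optimality_vs_sov", dtt$mean_optimality, dtt$sov, "pearson"),
      one("optimality_vs_mpd", dtt$mean_optimality, dtt$mpd, "pearson")
    )
  }
  out
}
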