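test_that("time binning follows interval overlap plus range-through", {
  bins <- devonian_bins()
  # spans Pragian-Emsian boundary: member of both
  recs <- tibble::tibble(taxon_id = "x", first_appearance = 410,
                         last_appearance = 395)
  memb <- time_bin_taxa(recs, bins)
  expect_setequal(as.character(memb$bin), c("Pragian", "Emsian"))
  # entirely inside one bin
  recs2 <- tibble::tibble(taxon_id = "y", first_appearance = 390,
                          last_appearance = 389)
  expect_equal(as.character(time_bin_taxa(recs2, bins)$bin), "Eifelian")
  # endpoint-only occupation of distant bins ranges through the middle
  recs3 <- tibble::tibble(taxon_id = "z", first_appearance = 410.8,
                          last_appearance = 382.7)
  memb3 <- time_bin_taxa(recs3, bins)
  expect_true(all(c("Pragian", "Emsian", "Eifelian", "Givetian") %in%
                    as.character(memb3$bin)))
  expect_error(time_bin_taxa(
    tibble::tibble(taxon_id = "w", first_appearance = 300,
                   last_appearance = 290), bins
  ), "outside every bin")
  expect_error(time_bin_taxa(
    tibble::tibble(taxon_id = "v", first_appearance = 380,
                   last_appearance = 390), bins
  ), "backward")
})

test_that("range extension never removes a membership", {
  bins <- devonian_bins()
  base <- tibble::tibble(taxon_id = "a", first_appearance = 400,
                         last_appearance = 395)
  ext <- tibble::tibble(taxon_id = "a", first_appearance = 415,
                        last_appearance = 380)
  mb <- as.character(time_bin_taxa(base, bins)$bin)
  me <- as.character(time_bin_taxa(ext, bins)$bin)
  expect_true(all(mb %in% me))
})

test_that("disparity metrics match closed forms and a brute-force oracle", {
  expect_equal(disparity_metrics(rbind(c(1, 2), c(1, 2))),
               list(sov = 0, mpd = 0))
  dm <- disparity_metrics(matrix(c(0, 2), 2, 1))
  expect_equal(dm$sov, 2)  # sample variance of {0, 2}
  expect_equal(dm$mpd, 2)
  set.seed(13)
  m <- matrix(rnorm(20 * 45), 20, 45)
  dm2 <- disparity_metrics(m)
  # brute-force pairwise loop
  acc <- 0; cnt <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    acc <- acc + sqrt(sum((m[i, ] - m[j, ])^2)); cnt <- cnt + 1
  }
  expect_equal(dm2$mpd, acc / cnt, tolerance = 1e-12)
  expect_equal(dm2$sov, sum(diag(stats::cov(m))), tolerance = 1e-12)
  # single row: sov 0 by convention, mpd undefined
  one <- disparity_metrics(m[1, , drop = FALSE])
  expect_equal(one$sov, 0)
  expect_true(is.na(one$mpd))
})

test_that("disparity metrics transform correctly under shift and scale", {
  set.seed(14)
  m <- matrix(rnorm(15 * 10), 15, 10)
  d0 <- disparity_metrics(m)
  shifted <- sweep(m, 2, rnorm(10), `+`)
  d1 <- disparity_metrics(shifted)
  expect_equal(d1$sov, d0$sov, tolerance = 1e-12)
  expect_equal(d1$mpd, d0$mpd, tolerance = 1e-12)
  d3 <- disparity_metrics(3 * m)
  expect_equal(d3$sov, 9 * d0$sov, tolerance = 1e-12)
  expect_equal(d3$mpd, 3 * d0$mpd, tolerance = 1e-12)
})

test_that("bootstrap summaries are deterministic and collapse on constants", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  bs <- bootstrap_summary(function(x) disparity_metrics(x)$sov, m,
                          n_boot = 200, seed = 1)
  expect_equal(bs$ci_low, bs$ci_high)
  expect_equal(bs$ci_low, 0)
  set.seed(15)
  g <- matrix(rnorm(50 * 5), 50, 5)
  b1 <- bootstrap_summary(function(x) disparity_metrics(x)$sov, g, 500,
                          seed = 2)
  b2 <- bootstrap_summary(function(x) disparity_metrics(x)$sov, g, 500,
                          seed = 2)
  expect_identical(b1, b2)
  expect_equal(b1$mean, disparity_metrics(g)$sov, tolerance = 0.1)
  expect_lt(b1$ci_low, b1$ci_high)
})

test_that("mean bin optimality interpolates and bootstraps correctly", {
  sp <- small_shape_space()
  grid <- build_theoretical_grid(sp, 7, 7, n_points = 120)
  nodes <- grid$nodes[grid$nodes$valid, ]
  perf <- tibble::tibble(node = nodes$node, re_mean = -nodes$pc1,
                         vms_mean = nodes$pc2)
  ls <- build_adaptive_landscape(perf, grid)
  # a taxon exactly at a ranked node: CI width 0
  k <- which(!is.na(ls$nodes$rank))[5]
  scores <- tibble::tibble(taxon_id = "t1", PC1 = ls$nodes$pc1[k],
                           PC2 = ls$nodes$pc2[k])
  mo <- mean_bin_optimality("t1", scores, ls, n_boot = 100, seed = 1)
  expect_equal(mo$point, ls$nodes$rank[k])
  expect_equal(mo$ci_low, mo$ci_high)
  expect_error(
    mean_bin_optimality("t1",
                        tibble::tibble(taxon_id = "t1", PC1 = 999, PC2 = 0),
                        ls, n_boot = 10, seed = 1),
    "Out-of-domain"
  )
})

test_that("trend tests report the expected extremes and reject constants", {
  dtt <- tibble::tibble(
    bin = letters[1:8],
    sov = 1:8,               # strictly increasing: rho = 1
    mpd = seq(2, 16, 2),
    mean_optimality = -(1:8) # negation of sov: Pearson r = -1
  )
  tt <- trend_tests(dtt)
  expect_equal(tt$statistic[tt$test == "sov_trend"], 1)
  expect_equal(tt$statistic[tt$test == "optimality_vs_sov"], -1,
               tolerance = 1e-12)
  expect_error(trend_tests(tibble::tibble(bin = letters[1:4],
                                          sov = rep(1, 4),
                                          mpd = 1:4)),
               "Constant")
  expect_error(trend_tests(dtt[1:2, ]), "at least 3")
})

test_that("the Spearman trend test holds its size under white noise", {
  set.seed(16)
  rej <- vapply(1:1000, function(i) {
    x <- rnorm(8)
    suppressWarnings(
      stats::cor.test(seq_len(8), x, method = "spearman")$p.value
    ) <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("disparity_through_time assembles per-bin rows", {
  taxa <- small_taxa()
  coeffs <- small_coeffs()
  sp <- small_shape_space()
  memb <- time_bin_taxa(taxa)
  dtt <- disparity_through_time(memb, coeffs, n_boot = 200, seed = 3)
  expect_true(all(dtt$sov >= 0))
  expect_true(all(dtt$n_taxa >= 1))
  expect_true(all(dtt$sov_ci_low <= dtt$sov_ci_high))
  expect_equal(sum(dtt$n_taxa), nrow(memb))
})
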