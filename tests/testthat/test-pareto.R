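test_that("Goldberg fronts match hand-computed dominance", {
  # A(3,1), B(2,1), C(3,2), D(1,3) with (max RE, min VMS):
  # A dominates B, C, D; B and C are mutually non-dominated after A; etc.
  pts <- rbind(c(3, 1), c(2, 1), c(3, 2), c(1, 3))
  expect_equal(goldberg_rank(pts), c(1L, 2L, 2L, 3L))
  # mutually non-dominated cloud: all front 1
  nd <- rbind(c(1, 1), c(2, 2), c(3, 3))  # max first, min second: trade-off
  expect_equal(goldberg_rank(nd), c(1L, 1L, 1L))
  # duplicates never dominate each other
  dup <- rbind(c(2, 2), c(2, 2), c(1, 3))
  expect_equal(goldberg_rank(dup)[1], goldberg_rank(dup)[2])
  expect_error(goldberg_rank(rbind(c(1, NA))), "finite")
})

test_that("the dominance chain gets combined ranks 1, 0.5, 0", {
  pts <- rbind(c(3, 1), c(2, 2), c(1, 3))
  pr <- combined_pareto_rank(pts)
  expect_equal(pr$r_optimal, c(1L, 2L, 3L))
  expect_equal(pr$r_suboptimal, c(3L, 2L, 1L))
  expect_equal(pr$rank, c(1, 0.5, 0))
})

test_that("points on both first fronts get the degenerate 0.5", {
  expect_equal(combined_pareto_rank(rbind(c(1, 1)))$rank, 0.5)
  # pure trade-off set: every point is on both first fronts
  tr <- cbind(1:5, 1:5)
  expect_equal(combined_pareto_rank(tr)$rank, rep(0.5, 5))
  # configurable degenerate value
  expect_equal(combined_pareto_rank(rbind(c(1, 1)),
                                    degenerate_rank = 0)$rank, 0)
})

test_that("random clouds agree exactly with the brute-force oracle", {
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(3:50, 1)
    m <- cbind(runif(n), runif(n))
    if (rep %% 3 == 0) m <- round(m, 1)  # induce ties
    got <- combined_pareto_rank(m)
    ora <- oracle_pareto(m)
    expect_identical(got$r_optimal, as.integer(ora$r_o))
    expect_identical(got$r_suboptimal, as.integer(ora$r_s))
    expect_identical(got$rank, ora$rank)
  }
})

test_that("ranks are invariant to monotone transforms of either metric", {
  set.seed(11)
  m <- cbind(runif(40), runif(40))
  base <- combined_pareto_rank(m)$rank
  expect_identical(combined_pareto_rank(cbind(exp(m[, 1]), m[, 2]))$rank,
                   base)
  expect_identical(combined_pareto_rank(cbind(m[, 1], m[, 2]^3))$rank, base)
})

test_that("reversing both directions maps rank to 1 - rank", {
  set.seed(12)
  m <- cbind(runif(30), runif(30))
  a <- combined_pareto_rank(m, maximize = c(TRUE, FALSE))
  b <- combined_pareto_rank(m, maximize = c(FALSE, TRUE))
  degen <- a$r_optimal == 1 & a$r_suboptimal == 1
  expect_equal(b$rank[!degen], 1 - a$rank[!degen])
  expect_equal(b$rank[degen], a$rank[degen])
})

make_toy_landscape <- function(perf_fun = NULL) {
  sp <- small_shape_space()
  grid <- build_theoretical_grid(sp, 7, 7, n_points = 120)
  nodes <- grid$nodes[grid$nodes$valid, ]
  if (is.null(perf_fun)) {
    perf_fun <- function(pc1, pc2) list(re = 1 - pc1, vms = 1 + pc2^2 - pc1)
  }
  pf <- perf_fun(nodes$pc1, nodes$pc2)
  perf <- tibble::tibble(node = nodes$node, re_mean = pf$re,
                         vms_mean = pf$vms)
  list(grid = grid, perf = perf,
       landscape = build_adaptive_landscape(perf, grid))
}

test_that("adaptive landscapes rank valid nodes only", {
  toy <- make_toy_landscape()
  ls <- toy$landscape
  expect_true(all(is.na(ls$nodes$rank[!ls$nodes$valid])))
  rk <- ls$nodes$rank[ls$nodes$valid]
  expect_true(all(rk >= 0 & rk <= 1))
  # identical performance everywhere: all 0.5
  toy2 <- make_toy_landscape(function(pc1, pc2) {
    list(re = rep(1, length(pc1)), vms = rep(2, length(pc1)))
  })
  expect_true(all(toy2$landscape$nodes$rank[toy2$landscape$nodes$valid] == 0.5))
  # missing records are an error
  expect_error(build_adaptive_landscape(toy$perf[-1, ], toy$grid), "missing")
})

test_that("a two-point dominance chain ranks 1 and 0", {
  pr <- combined_pareto_rank(rbind(c(2, 1), c(1, 2)))
  expect_equal(pr$rank, c(1, 0))
})

test_that("masking a node reproduces the subset ranking", {
  toy <- make_toy_landscape()
  keep <- toy$perf$node[-3]
  sub_ranks <- combined_pareto_rank(
    toy$perf[toy$perf$node %in% keep, c("re_mean", "vms_mean")]
  )$rank
  grid2 <- toy$grid
  grid2$nodes$valid[grid2$nodes$node == toy$perf$node[3]] <- FALSE
  ls2 <- build_adaptive_landscape(toy$perf[-3, ], grid2)
  got <- ls2$nodes$rank[match(keep, ls2$nodes$node)]
  expect_equal(got, sub_ranks)
})

test_that("bilinear interpolation honors nodes, cell centers and the domain", {
  toy <- make_toy_landscape()
  ls <- toy$landscape
  nodes <- ls$nodes[ls$nodes$valid, ]
  # exactly at a node
  k <- which.max(nodes$rank)
  expect_equal(
    interpolate_optimality(ls, nodes$pc1[k], nodes$pc2[k]),
    nodes$rank[k]
  )
  # cell center = mean of 4 corners (find a fully valid cell)
  xs <- ls$pc1_values; ys <- ls$pc2_values
  found <- FALSE
  for (i in seq_len(length(xs) - 1)) {
    for (j in seq_len(length(ys) - 1)) {
      q <- ls$rank_matrix[c(i, i + 1), c(j, j + 1)]
      if (!anyNA(q)) {
        ctr <- interpolate_optimality(ls, mean(xs[i:(i + 1)]),
                                      mean(ys[j:(j + 1)]))
        expect_equal(ctr, mean(q))
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  # outside the grid limits
  expect_error(
    interpolate_optimality(ls, max(xs) + 1, mean(ys)),
    "Out-of-domain"
  )
  expect_equal(
    interpolate_optimality(ls, max(xs) + 1, mean(ys), strict = FALSE),
    NA_real_
  )
})
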