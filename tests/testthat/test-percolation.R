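test_that("grid validation enforces the floor and non-emptiness", {
  st <- simulate_study(n_features = 20, n_per_group = 10, n_diff_edges = 2,
                       n_null_edges = 4, seed = 71)
  expect_error(percolation_scan(st$layer, st$labels, st$net,
                                quantile_grid = numeric(0)),
               class = "diffnetx_error_empty_grid")
  expect_error(percolation_scan(st$layer, st$labels, st$net,
                                quantile_grid = c(0.30, 0.50)),
               class = "diffnetx_error_grid_below_floor")
  expect_error(percolation_scan(st$layer, st$labels, st$net,
                                quantile_grid = c(0.5, 1)),
               class = "diffnetx_error_bad_grid")
  # a lowered floor admits lower quantiles explicitly
  act <- percolation_scan(st$layer, st$labels, st$net,
                          quantile_grid = c(0.2, 0.5), floor_quantile = 0.2)
  expect_true(act$quantile %in% c(0.2, 0.5))
})

test_that("a single-element grid selects that quantile", {
  st <- simulate_study(n_features = 20, n_per_group = 10, n_diff_edges = 2,
                       n_null_edges = 4, seed = 72)
  act <- percolation_scan(st$layer, st$labels, st$net, quantile_grid = 0.5)
  expect_equal(act$quantile, 0.5)
  expect_equal(nrow(act$scan_trace), 1)
})

test_that("scan trace is well-formed and the selection is the grid argmax", {
  st <- simulate_study(seed = 73)
  act <- percolation_scan(st$layer, st$labels, st$net)
  tr <- act$scan_trace
  expect_true(all(diff(tr$quantile) > 0))
  expect_true(all(tr$quantile >= 0.35))
  expect_true(act$quantile %in% tr$quantile)
  best <- max(tr$n_significant_edges)
  expect_equal(tr$n_significant_edges[tr$quantile == act$quantile], best)
  # ties break toward the higher quantile
  expect_equal(act$quantile, max(tr$quantile[tr$n_significant_edges == best]))
  # active node counts are antitone in the threshold
  expect_true(all(diff(tr$n_active_nodes) <= 0))
})

test_that("the scan reproduces an exhaustive formula-based re-run", {
  st <- simulate_study(n_features = 40, n_per_group = 25, n_diff_edges = 4,
                       n_null_edges = 10, seed = 74)
  grid <- seq(0.35, 0.95, by = 0.1)
  act <- percolation_scan(st$layer, st$labels, st$net, quantile_grid = grid)
  oracle <- oracle_scan_counts(st$layer, st$labels, st$net, grid)
  expect_equal(act$scan_trace$n_significant_edges, oracle)
  sel_oracle <- max(grid[oracle == max(oracle)])
  expect_equal(act$quantile, sel_oracle)
})

test_that("with no signal anywhere the tie-break picks the strictest grid point", {
  set.seed(75)
  m <- matrix(rnorm(30 * 20, 5), 30, 20,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:20)))
  labels <- group_labels(setNames(rep(c("A", "B"), 10), colnames(m)))
  net <- suppressWarnings(reference_network(sprintf("f%02d", 1:10),
                                            sprintf("f%02d", 11:20)))
  act <- percolation_scan(expression_layer(m, "null"), labels, net,
                          alpha_adj = 1e-12)
  expect_equal(max(act$scan_trace$n_significant_edges), 0)
  expect_equal(act$quantile, max(act$scan_trace$quantile))
})

test_that("permutation test records one null draw per iteration, reproducibly", {
  st <- simulate_study(n_features = 20, n_per_group = 10, n_diff_edges = 2,
                       n_null_edges = 4, seed = 76)
  pt <- permutation_threshold_test(st$layer, st$labels, st$net,
                                   quantile_grid = c(0.4, 0.6),
                                   n_perm = 1, seed = 7)
  expect_equal(dim(pt$null), c(1, 2))
  pt2 <- permutation_threshold_test(st$layer, st$labels, st$net,
                                    quantile_grid = c(0.4, 0.6),
                                    n_perm = 5, seed = 99)
  pt3 <- permutation_threshold_test(st$layer, st$labels, st$net,
                                    quantile_grid = c(0.4, 0.6),
                                    n_perm = 5, seed = 99)
  expect_identical(pt2$null, pt3$null)
  expect_identical(pt2$p, pt3$p)
})

test_that("without group structure the observed counts sit inside the null", {
  set.seed(77)
  grid <- seq(0.35, 0.75, by = 0.2)
  inside <- 0L; total <- 0L
  for (run in 1:8) {
    m <- matrix(rnorm(24 * 24, 5), 24, 24,
                dimnames = list(sprintf("f%02d", 1:24),
                                sprintf("s%02d", 1:24)))
    labels <- group_labels(setNames(rep(c("A", "B"), 12), colnames(m)))
    net <- suppressWarnings(reference_network(sprintf("f%02d", 1:12),
                                              sprintf("f%02d", 13:24)))
    pt <- permutation_threshold_test(expression_layer(m, "null"), labels,
                                     net, quantile_grid = grid, n_perm = 19)
    for (j in seq_along(grid)) {
      lo <- quantile(pt$null[, j], 0.025)
      hi <- quantile(pt$null[, j], 0.975)
      obs <- pt$observed$n_significant_edges[j]
      inside <- inside + (obs >= lo && obs <= hi)
      total <- total + 1L
    }
  }
  expect_gte(inside / total, 0.9)
})
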