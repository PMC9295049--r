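test_that("region growing produces contiguous blocks at the target sizes", {
  spec <- scenario_spec(dims = c(20, 25), seed = 51)
  part <- generate_blocked_partition(spec)
  g <- lattice_graph(c(20, 25))
  expect_true(is_graph_respecting(part, g))
  sizes <- lengths(part)
  ## the law draws 12-14; occasional merged leftovers may exceed the range
  expect_gte(mean(sizes >= 12 & sizes <= 14), 0.9)
  expect_equal(sum(sizes), 500L)
})

test_that("the mean-4 law averages four vertices per block", {
  means <- vapply(1:5, function(s) {
    spec <- scenario_spec(dims = c(20, 20), block_size_law = "mean4",
                          seed = 60 + s)
    mean(lengths(generate_blocked_partition(spec)))
  }, 1)
  expect_lt(abs(mean(means) - 4), 0.5)
})

test_that("the singleton law gives the all-singletons partition", {
  spec <- scenario_spec(dims = c(5, 5), block_size_law = "singleton",
                        seed = 52)
  part <- generate_blocked_partition(spec)
  expect_length(part, 25L)
  expect_true(all(lengths(part) == 1L))
})

test_that("scenario data carry exact within-block latent means and truth", {
  spec <- scenario_spec(dims = c(10, 10), M_X = 6, M_Y = 6, seed = 53)
  sim <- simulate_scenario(spec)
  tr <- sim$truth
  memb <- partition_membership(tr$partition, 100L)
  ## latent means are block-constant by construction
  for (k in seq_along(tr$partition)) {
    expect_length(unique(tr$mu_x[tr$partition[[k]]]), 1L)
    expect_length(unique(tr$mu_y[tr$partition[[k]]]), 1L)
  }
  ## a vertex is null iff its block is unshifted
  expect_equal(!tr$null, memb %in% tr$shifted_blocks)
  expect_equal(tr$null, tr$mu_x == tr$mu_y)
  ## zero shift fraction produces an all-null data set
  spec0 <- scenario_spec(dims = c(6, 6), shift_fraction = 0, M_X = 4,
                         M_Y = 4, seed = 54)
  expect_true(all(simulate_scenario(spec0)$truth$null))
})

test_that("simulation is reproducible from its seed", {
  spec <- scenario_spec(dims = c(8, 8), M_X = 5, M_Y = 5, seed = 55)
  s1 <- simulate_scenario(spec)
  s2 <- simulate_scenario(spec)
  expect_identical(s1$data$x, s2$data$x)
  expect_identical(s1$truth, s2$truth)
})

test_that("strong shifts are recoverable by plain t-tests", {
  spec <- scenario_spec(dims = c(15, 15), shift_magnitude = 2,
                        shift_fraction = 0.3, M_X = 25, M_Y = 25, seed = 56)
  sim <- simulate_scenario(spec)
  expect_gt(sum(!sim$truth$null), 0)
  bh <- ttest_bh(sim$data, 0.05)
  tpr <- sum(bh$reject & !sim$truth$null) / sum(!sim$truth$null)
  expect_gt(tpr, 0.5)
})

test_that("non-graph-respecting truth violates contiguity but stays clustered", {
  spec <- scenario_spec(dims = c(15, 15), graph_respecting = FALSE,
                        seed = 57)
  part <- generate_blocked_partition(spec)
  g <- lattice_graph(c(15, 15))
  expect_false(is_graph_respecting(part, g))
  ## the number of blocks stays in the clustered regime (far below N)
  expect_lt(length(part), 100)
})

test_that("spatially correlated noise raises neighbour correlation", {
  spec_i <- scenario_spec(dims = c(12, 12), shift_fraction = 0, M_X = 30,
                          M_Y = 30, seed = 58)
  spec_s <- scenario_spec(dims = c(12, 12), shift_fraction = 0, M_X = 30,
                          M_Y = 30, noise = "spatial", noise_range = 2,
                          seed = 58)
  lag1 <- function(sim) {
    g <- lattice_graph(c(12, 12))
    x <- sim$data$x
    mean(vapply(seq_len(nrow(g$edges)), function(i)
      cor(x[g$edges[i, 1], ], x[g$edges[i, 2], ]), 1))
  }
  expect_lt(abs(lag1(simulate_scenario(spec_i))), 0.12)
  expect_gt(lag1(simulate_scenario(spec_s)), 0.5)
})

test_that("label permutation pools and re-splits the samples", {
  spec <- scenario_spec(dims = c(8, 8), M_X = 7, M_Y = 5,
                        shift_magnitude = 2, shift_fraction = 0.5, seed = 59)
  sim <- simulate_scenario(spec)
  perm <- permute_sample_labels(sim$data, seed = 1)
  expect_equal(ncol(perm$x), 7L)
  expect_equal(ncol(perm$y), 5L)
  ## the multiset of columns is preserved
  key <- function(m) sort(apply(round(m, 10), 2, paste, collapse = ","))
  expect_equal(key(cbind(perm$x, perm$y)),
               key(cbind(sim$data$x, sim$data$y)))
  ## permutation destroys the group signal: t statistics centred near zero
  p <- ttest_bh(perm, 0.05)
  expect_gt(mean(p$p > 0.05), 0.8)
})

test_that("voxel permutation preserves marginals and is invertible", {
  spec <- scenario_spec(dims = c(8, 8), M_X = 6, M_Y = 6, seed = 61)
  sim <- simulate_scenario(spec)
  pv <- permute_voxels(sim$data, seed = 2)
  expect_equal(sort(rowMeans(pv$data$x)), sort(rowMeans(sim$data$x)))
  expect_equal(sort(apply(pv$data$y, 1, sd)), sort(apply(sim$data$y, 1, sd)))
  ## applying the inverse permutation restores the data exactly
  inv <- order(pv$perm)
  expect_identical(pv$data$x[inv, ], sim$data$x)
  ## spatial autocorrelation of vertex means collapses
  spec_s <- scenario_spec(dims = c(12, 12), shift_fraction = 0, M_X = 20,
                          M_Y = 20, noise = "spatial", noise_range = 2,
                          seed = 62)
  sim_s <- simulate_scenario(spec_s)
  g <- lattice_graph(c(12, 12))
  ac <- function(d) {
    mu <- rowMeans(d$x)
    cor(mu[g$edges[, 1]], mu[g$edges[, 2]])
  }
  expect_gt(ac(sim_s$data), 0.4)
  expect_lt(abs(ac(permute_voxels(sim_s$data, seed = 3)$data)), 0.25)
})
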