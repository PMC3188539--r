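# The synthetic-data generator: determinism, truth bookkeeping, geometry.

test_that("specs validate their inputs", {
  expect_error(simulation_spec(), "seed")
  expect_error(simulation_spec(theta = 0.7, type2_fraction = 0.5, seed = 1),
               "exceeds 1")
})

test_that("same spec and seed give byte-identical datasets", {
  spec <- simulation_spec(n_columns = 80, seed = 7)
  s1 <- simulate_alignment(spec)
  s2 <- simulate_alignment(spec)
  expect_identical(unclass(s1$aln), unclass(s2$aln))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$coords, s2$coords)
})

test_that("gap fraction zero means no gaps; truth covers all columns", {
  spec <- simulation_spec(n_columns = 60, gap_fraction = 0, seed = 3)
  sim <- simulate_alignment(spec)
  expect_false(any(unclass(sim$aln) == "-"))
  expect_equal(nrow(sim$truth), 60L)
  expect_true(all(sim$truth$class %in% c("type1", "type2", "shared")))

  spec2 <- simulation_spec(n_columns = 60, gap_fraction = 0.1, seed = 3)
  sim2 <- simulate_alignment(spec2)
  expect_true(any(unclass(sim2$aln) == "-"))
})

test_that("type II truth plants conserved radical differences", {
  spec <- simulation_spec(n_columns = 200, theta = 0, shift_ratio = 1,
                          type2_fraction = 0.3, gap_fraction = 0, seed = 11)
  sim <- simulate_alignment(spec)
  t2 <- sim$truth$column[sim$truth$class == "type2"]
  expect_gt(length(t2), 20)
  m <- unclass(sim$aln)
  pa <- sim$partition$sequence_id[sim$partition$clade == "A"]
  pb <- sim$partition$sequence_id[sim$partition$clade == "B"]
  for (col in t2[1:10]) {
    expect_equal(length(unique(m[pa, col])), 1L)
    expect_equal(length(unique(m[pb, col])), 1L)
    expect_false(radical_group_of(m[pa[1], col]) ==
                   radical_group_of(m[pb[1], col]))
  }
})

test_that("planted coordinate clusters satisfy the contact geometry", {
  co <- simulate_coordinates(50, list(c(10, 11, 12), c(30, 33)),
                             threshold = 4)
  xyz <- as.matrix(co[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  # intra-cluster pairs within threshold
  expect_true(all(d[c(10, 11, 12), c(10, 11, 12)][upper.tri(diag(3))] <= 4))
  expect_lte(d[30, 33], 4)
  # chain neighbours at 3.8 A are genuine contacts at a 4 A threshold
  expect_equal(d[20, 21], 3.8, tolerance = 1e-9)
  # non-cluster, non-consecutive pairs are far apart
  expect_gt(d[20, 22], 4)
  expect_gt(d[10, 30], 4)   # cross-cluster
  expect_gt(d[11, 20], 4)   # cluster to chain

  expect_error(simulate_coordinates(50, list(c(1, 2), c(2, 3)), 4),
               "disjoint")
  expect_error(simulate_coordinates(50, list(1:2), threshold = 0),
               "positive")
})

test_that("poisson count simulation obeys its moments and seed", {
  x <- simulate_poisson_counts(2, rep(1, 10000), seed = 5)
  expect_lt(abs(mean(x) - 2) / 2, 0.02)
  y <- simulate_poisson_counts(2, rep(1, 10000), seed = 5)
  expect_identical(x, y)
  expect_true(all(simulate_poisson_counts(0, rep(1, 50), seed = 1) == 0))
})

test_that("shared-rate clades show correlated per-column rates", {
  spec <- simulation_spec(n_leaves = 64, tree_length = 32, n_columns = 300,
                          gamma_shape = 0.5, theta = 0, shift_ratio = 1,
                          type2_fraction = 0, gap_fraction = 0, seed = 13)
  sim <- simulate_alignment(spec)
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition,
                              model = "fitch")
  r <- rate_correlation(relative_rates(counts), "A", "B")
  expect_gt(r, 0.5)
})

test_that("quartet fixtures plant detectable clustered shifts", {
  sim <- simulate_quartet_fixture(n_sites = 10, planted = TRUE, seed = 2,
                                  n_columns = 150)
  expect_true(sim$expect_significant)
  expect_length(sim$planted_e1, 10L)
  expect_length(intersect(sim$planted_e1, sim$planted_e2), 0L)
  expect_setequal(sim$truth$column[sim$truth$class == "type1"],
                  c(sim$planted_e1, sim$planted_e2))
  # perfect calls on the planted sites reject the null decisively
  g <- build_contact_graph(sim$structmap,
                           c(sim$planted_e1, sim$planted_e2), threshold = 4)
  tst <- clustering_permutation_test(sim$planted_e1, sim$planted_e2, g,
                                     n_perm = 10000, seed = 2)
  expect_lt(tst$p_value, 0.01)

  # the planted rate shifts are visible in the counts
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
  rr <- relative_rates(counts)
  wide <- tidyr::pivot_wider(rr, names_from = "clade",
                             values_from = "rate")
  contrast <- abs(log((wide$A + 0.05) / (wide$B + 0.05)))
  expect_gt(mean(contrast[sim$planted_e1]), mean(contrast[-sim$planted_e1]))
})

test_that("datasets export to standard text formats and read back", {
  spec <- simulation_spec(n_columns = 40, seed = 9)
  sim <- simulate_alignment(spec)
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  aln <- read_alignment(paths$alignment, "fasta")
  expect_identical(unclass(aln), unclass(sim$aln))
  trA <- read_tree(paths$tree_A)
  expect_equal(tree_length(trA), tree_length(sim$trees$A), tolerance = 1e-6)
  part <- read_clade_map(paths$clade_map)
  expect_equal(part, sim$partition)
  co <- read_structure(paths$structure, "A")
  expect_equal(nrow(co), nrow(sim$coords))
  expect_equal(co$x, sim$coords$x, tolerance = 1e-3)
})
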