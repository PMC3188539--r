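# Contact graph, quartet site selection, clustering statistics and the
# edge-permutation test.

mk_map <- function(xyz, columns = seq_len(nrow(xyz))) {
  sm <- tibble::tibble(
    column = columns, chain = "A", resno = seq_len(nrow(xyz)), insert = "",
    aa_aln = "A", aa_struct = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  class(sm) <- c("structure_map", class(sm))
  sm
}

test_that("contact edges follow the distance threshold", {
  sm <- mk_map(cbind(c(0, 3.8, 10), 0, 0))
  g <- build_contact_graph(sm, 1:3, threshold = 4)
  e <- contact_edges(g)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$column_i, e$column_j), c(1L, 2L))

  g0 <- build_contact_graph(sm, 1:3, threshold = 0)
  expect_equal(nrow(contact_edges(g0)), 0L)

  expect_warning(build_contact_graph(sm, 1:4, threshold = 4), "unmapped")
})

test_that("contact graph equals a brute-force all-pairs scan", {
  set.seed(8)
  for (rep in 1:5) {
    xyz <- matrix(runif(3 * 30, 0, 20), ncol = 3)
    sm <- mk_map(xyz)
    g <- build_contact_graph(sm, 1:30, threshold = 6)
    got <- contact_edges(g)
    d <- as.matrix(dist(xyz))
    want <- which(upper.tri(d) & d <= 6, arr.ind = TRUE)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$column_i, got$column_j),
                    paste(want[, 1], want[, 2]))
  }
})

test_that("quartet site selection drops shared top sites symmetrically", {
  po <- function(cols, p) tibble::tibble(column = cols, posterior = p)
  p1 <- po(1:10, seq(1, 0.1, length.out = 10))
  p2 <- po(c(1, 2, 11:18), c(0.95, 0.9, seq(0.5, 0.1, length.out = 8)))
  sel <- select_quartet_sites(p1, p2, n = 4)
  # top-4 lists {1,2,3,4} and {1,2,11,12} share sites 1 and 2
  expect_equal(sel$n_common, 2L)
  expect_equal(sel$sites_e1, c(3L, 4L))
  expect_equal(sel$sites_e2, c(11L, 12L))
  expect_length(intersect(sel$sites_e1, sel$sites_e2), 0)

  # disjoint top lists keep all n per edge
  p3 <- po(11:20, seq(1, 0.1, length.out = 10))
  sel2 <- select_quartet_sites(p1, p3, n = 4)
  expect_equal(length(sel2$sites_e1), 4L)
  expect_equal(sel2$n_common, 0L)

  # identical rankings leave an empty pool
  expect_error(select_quartet_sites(p1, p1, n = 4), "identical")
  # too few callable sites
  expect_error(select_quartet_sites(p1, p2, n = 25), "smaller n")
})

test_that("clustering and consecutive statistics count same-edge pairs", {
  sm <- mk_map(cbind(c(0, 3.8, 100, 103.8, 200, 300), 0, 0),
               columns = c(1L, 2L, 5L, 6L, 9L, 12L))
  g <- build_contact_graph(sm, c(1, 2, 5, 6, 9, 12), threshold = 4)
  s <- clustering_statistic(c(1, 2), c(5, 9), g)
  expect_equal(as.integer(s), 1L)
  expect_equal(attr(s, "per_edge"), c(e1 = 1, e2 = 0))
  expect_equal(as.integer(clustering_statistic(c(1, 9), c(2, 12), g)), 0L)
  expect_error(clustering_statistic(c(1, 2), c(2, 5), g), "disjoint")

  cs <- consecutive_statistic(c(1, 2), c(5, 9), sm)
  expect_equal(as.integer(cs), 1L)
  expect_equal(as.integer(consecutive_statistic(c(1, 9), c(5, 12), sm)), 0L)
})

test_that("exact permutation p-value matches hand enumeration", {
  sm <- mk_map(cbind(c(0, 3.8, 100, 103.8), 0, 0),
               columns = c(1L, 2L, 5L, 6L))
  g <- build_contact_graph(sm, c(1, 2, 5, 6), threshold = 4)
  # observed assignment groups the two contact pairs: S = 2,
  # exact null: 2 of the 6 labelled equipartitions reach S >= 2
  res <- clustering_permutation_test(c(1, 2), c(5, 6), g)
  expect_equal(res$mode, "exact")
  expect_equal(res$statistic, 2L)
  expect_equal(res$p_value, 1 / 3)

  # S = 0 gives p = 1 in exact mode
  res0 <- clustering_permutation_test(c(1, 5), c(2, 6), g)
  expect_equal(res0$statistic, 0L)
  expect_equal(res0$p_value, 1)
})

test_that("Monte-Carlo p agrees with exact p within binomial error", {
  set.seed(31)
  xyz <- matrix(runif(36, 0, 15), ncol = 3)
  sm <- mk_map(xyz)
  g <- build_contact_graph(sm, 1:12, threshold = 8)
  e1 <- c(1:6); e2 <- c(7:12)
  exact <- clustering_permutation_test(e1, e2, g, exact_threshold = 12)
  mc <- clustering_permutation_test(e1, e2, g, n_perm = 20000, seed = 9,
                                    exact_threshold = 0)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / mc$n_perm)
  expect_equal(mc$mode, "monte-carlo")
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / mc$n_perm)

  # same seed reproduces the Monte-Carlo draw exactly
  mc2 <- clustering_permutation_test(e1, e2, g, n_perm = 20000, seed = 9,
                                     exact_threshold = 0)
  expect_identical(mc$p_value, mc2$p_value)
  expect_identical(mc$null_stats, mc2$null_stats)
})
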