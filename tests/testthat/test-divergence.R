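# Type I mixture model, posteriors, type II rules, site classification.

mk_counts <- function(xa, xb, ta, tb) {
  dplyr::bind_rows(
    tibble::tibble(column = seq_along(xa), clade = "A",
                   raw_count = xa, corrected_count = xa, tree_length = ta),
    tibble::tibble(column = seq_along(xb), clade = "B",
                   raw_count = xb, corrected_count = xb, tree_length = tb)
  )
}

test_that("site likelihood kernels match closed forms and quadrature", {
  # integral of Poisson(0; lambda) * Exponential(lambda; 1) d lambda = 1/2
  expect_equal(exp(lscscan:::ll_margin(0, 1, 1, 1)), 0.5, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    alpha <- runif(1, 0.3, 3); beta <- runif(1, 0.3, 3)
    ta <- runif(1, 1, 10); tb <- runif(1, 1, 10)
    xa <- rpois(1, 3); xb <- rpois(1, 3)
    num0 <- stats::integrate(function(l) {
      dpois(xa, l * ta) * dpois(xb, l * tb) * dgamma(l, alpha, beta)
    }, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(exp(lscscan:::ll_shared(xa, xb, ta, tb, alpha, beta)),
                 num0, tolerance = 1e-6)
    num1 <- stats::integrate(function(l) {
      dpois(xa, l * ta) * dgamma(l, alpha, beta)
    }, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(exp(lscscan:::ll_margin(xa, ta, alpha, beta)),
                 num1, tolerance = 1e-6)
  }
})

test_that("the ML point beats the theta boundaries", {
  set.seed(21)
  g <- standard_fixture(21)
  sim <- simulate_alignment(g)
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
  fit <- fit_type_I(counts, "A", "B")
  nll <- function(theta) {
    lscscan:::mixture_negloglik(
      c(stats::qlogis(min(max(theta, 1e-12), 1 - 1e-12)),
        log(fit$alpha), log(fit$beta)),
      xa = fit$xa, xb = fit$xb, ta = fit$ta, tb = fit$tb)
  }
  expect_lte(-fit$log_likelihood, nll(1e-9) + 1e-6)
  expect_lte(-fit$log_likelihood, nll(1 - 1e-9) + 1e-6)
})

test_that("theta is near zero when clades share all rates", {
  hits <- 0L
  for (s in 1:20) {
    spec <- simulation_spec(theta = 0, shift_ratio = 1, type2_fraction = 0,
                            gap_fraction = 0, n_columns = 300, seed = s)
    sim <- simulate_alignment(spec)
    counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
    fit <- fit_type_I(counts, "A", "B")
    if (fit$theta < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("posteriors are probabilities with sensible direction", {
  xa <- c(0L, 0L, 10L, 3L)
  xb <- c(0L, 12L, 0L, 3L)
  fit <- fit_type_I(mk_counts(rep(xa, 10), rep(xb, 10), 5, 5), "A", "B")
  po <- type_I_posteriors(fit)
  expect_true(all(po$posterior >= 0 & po$posterior <= 1))
  # no-evidence column stays below the call cutoff
  expect_lt(po$posterior[1], 0.9)
  # xA = 0, xB large at equal t: A is the slow clade
  expect_equal(po$slow_clade[2], "A")
  expect_equal(po$fast_clade[2], "B")
  expect_equal(po$slow_clade[3], "B")
})

test_that("type II calls need a radical fixed difference and conservation", {
  aln <- aln_of(a1 = "KDK", a2 = "KDK", a3 = "KDK", a4 = "KDK",
                b1 = "DED", b2 = "DED", b3 = "DED", b4 = "DEW")
  trees <- list(A = quartet_tree(paste0("a", 1:4), bl = 0.3),
                B = quartet_tree(paste0("b", 1:4), bl = 0.3))
  part <- tibble::tibble(sequence_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                         clade = rep(c("A", "B"), each = 4))
  counts <- clade_site_counts(aln, trees, part, model = "fitch",
                              correction = "identity")
  anc_a <- reconstruct_ancestral_states(aln, trees$A, "fitch")
  anc_b <- reconstruct_ancestral_states(aln, trees$B, "fitch")
  t2 <- classify_type_II(anc_a, anc_b, counts, "A", "B")
  # column 1: K vs D, both conserved -> type II (positive vs negative)
  expect_true(t2$calls$type_ii[1])
  # column 2: D vs E, same radical group -> not type II
  expect_false(t2$calls$type_ii[2])
  # column 3: K vs D but clade B varies (D,D,D,W) -> conservation fails
  expect_false(t2$calls$type_ii[3])
  # theta_II = proportion of type II among columns conserved in both clades
  expect_equal(t2$theta$theta, 1 / 2)
  expect_equal(t2$theta$kind, "typeII")
})

test_that("site classes follow the precedence and type 0 definition", {
  aln <- aln_of(a1 = "KAK", a2 = "KAK", a3 = "KAK", a4 = "KAK",
                b1 = "DAK", b2 = "DAK", b3 = "DAK", b4 = "DAK")
  trees <- list(A = quartet_tree(paste0("a", 1:4), bl = 0.3),
                B = quartet_tree(paste0("b", 1:4), bl = 0.3))
  part <- tibble::tibble(sequence_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                         clade = rep(c("A", "B"), each = 4))
  counts <- clade_site_counts(aln, trees, part, model = "fitch",
                              correction = "identity")
  anc_a <- reconstruct_ancestral_states(aln, trees$A, "fitch")
  anc_b <- reconstruct_ancestral_states(aln, trees$B, "fitch")
  t2 <- classify_type_II(anc_a, anc_b, counts, "A", "B")
  po <- tibble::tibble(column = 1:3, posterior = c(0.95, 0.1, 0.1),
                       slow_clade = "A", fast_clade = "B")
  calls <- classify_sites(aln, part, po, t2, counts, "A", "B")
  # column 1 triggers both type I (posterior .95) and type II: type II wins
  expect_equal(as.character(calls$class[1]), "typeII")
  # column 2: invariant, same residue both clades -> type 0
  expect_equal(as.character(calls$class[2]), "type0")
  # column 3: invariant but classed none? identical consensus K -> type 0
  expect_equal(as.character(calls$class[3]), "type0")
  expect_true(all(calls$posterior >= 0 & calls$posterior <= 1))
})

test_that("high posterior without radical difference is type I", {
  spec <- standard_fixture(31)
  sim <- simulate_alignment(spec)
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
  fit <- fit_type_I(counts, "A", "B")
  po <- type_I_posteriors(fit)
  anc_a <- reconstruct_ancestral_states(sim$aln, sim$trees$A)
  anc_b <- reconstruct_ancestral_states(sim$aln, sim$trees$B)
  t2 <- classify_type_II(anc_a, anc_b, counts, "A", "B")
  calls <- classify_sites(sim$aln, sim$partition, po, t2, counts, "A", "B")
  called_I <- calls$column[calls$class == "typeI"]
  expect_true(length(called_I) > 0)
  expect_true(all(po$posterior[match(called_I, po$column)] > 0.9))
  # type I calls carry an ordered direction
  expect_true(all(!is.na(calls$slow_clade[calls$class == "typeI"])))
})

test_that("pairwise theta table covers all pairs with values in [0, 1]", {
  spec <- simulation_spec(clades = c("A", "B", "C"), n_columns = 120,
                          theta = 0.3, type2_fraction = 0.05,
                          gap_fraction = 0, seed = 17)
  sim <- simulate_alignment(spec)
  tt <- pairwise_theta_table(sim$aln, sim$trees, sim$partition)
  expect_equal(nrow(tt), 3L)
  expect_true(all(tt$theta_type1 >= 0 & tt$theta_type1 <= 1, na.rm = TRUE))
  expect_true(all(tt$theta_type2 >= 0 & tt$theta_type2 <= 1, na.rm = TRUE))
  m <- theta_matrix(tt)
  expect_true(all(is.na(diag(m))))
  expect_equal(m["A", "B"], tt$theta_type1[tt$clade_a == "A" &
                                           tt$clade_b == "B"])
  expect_equal(m["B", "A"], tt$theta_type2[tt$clade_a == "A" &
                                           tt$clade_b == "B"])
})

test_that("tidy and glance summarise a fit", {
  g <- standard_fixture(3)
  sim <- simulate_alignment(g)
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
  fit <- fit_type_I(counts, "A", "B")
  td <- generics::tidy(fit)
  expect_equal(td$term, c("theta", "gamma_shape", "gamma_rate"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 500L)
})
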