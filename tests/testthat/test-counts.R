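# Ancestral reconstruction, substitution counting, correction, rates.

test_that("unanimous columns reconstruct unanimously under both models", {
  aln <- aln_of(a = "AK", b = "AK", c = "AK", d = "AD")
  tr <- quartet_tree()
  for (model in c("fitch", "marginal-ml")) {
    anc <- reconstruct_ancestral_states(aln, tr, model)
    expect_true(all(anc$node_states[, 1] == lscscan:::aa_encode("A")))
  }
})

test_that("Fitch on the K/K vs D/D quartet infers one change", {
  aln <- aln_of(a = "K", b = "K", c = "D", d = "D")
  tr <- quartet_tree()
  anc <- reconstruct_ancestral_states(aln, tr, "fitch")
  m <- count_substitutions(aln, tr, anc)
  expect_equal(m, 1L)
  # root state is one of K or D
  expect_true(anc$root_state[1] %in% c("K", "D"))
})

test_that("gapped leaves force at least one substitution each", {
  aln <- aln_of(a = "A", b = "A", c = "-", d = "-")
  tr <- quartet_tree()
  for (model in c("fitch", "marginal-ml")) {
    anc <- reconstruct_ancestral_states(aln, tr, model)
    m <- count_substitutions(aln, tr, anc)
    expect_gte(m, 2L)
  }
  # property over random gapped columns
  set.seed(41)
  n_col <- 300L
  rows <- vapply(1:6, function(i) {
    paste(sample(c(lscscan:::AA20, "-"), n_col, replace = TRUE,
                 prob = c(rep(0.04, 20), 0.2)), collapse = "")
  }, "")
  names(rows) <- paste0("t", 1:6)
  aln2 <- new_msa(rows)
  tr6 <- ape::rtree(6, tip.label = paste0("t", 1:6))
  anc2 <- reconstruct_ancestral_states(aln2, tr6, "fitch")
  m2 <- count_substitutions(aln2, tr6, anc2)
  g <- unclass(aln2)
  n_gaps <- colSums(matrix(g %in% c("-", "X"), nrow = nrow(g)))
  expect_true(all(m2 >= n_gaps))
})

test_that("columns gapped in every leaf count one change per leaf", {
  aln <- aln_of(a = "-A", b = "-A", c = "-A", d = "-A")
  tr <- quartet_tree()
  anc <- reconstruct_ancestral_states(aln, tr, "fitch")
  expect_true(anc$uninformative[1])
  expect_false(anc$uninformative[2])
  m <- count_substitutions(aln, tr, anc)
  expect_equal(m, c(4L, 0L))
})

test_that("Fitch-mode counts equal the exhaustive minimum-change oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    chars <- sample(c("K", "D", "A", "S", "-"), n, replace = TRUE)
    names(chars) <- tr$tip.label
    aln <- new_msa(stats::setNames(chars, names(chars)))
    anc <- reconstruct_ancestral_states(aln, tr, "fitch")
    m <- count_substitutions(aln, tr, anc)
    expect_equal(m, exhaustive_min_changes(tr, chars),
                 info = paste("replicate", rep))
  }
})

test_that("multiple-hit correction is zero at zero, monotone, identity-able", {
  tr <- quartet_tree(bl = 0.5)
  m <- 0:6
  x <- correct_counts(m, tr)
  expect_equal(x[1], 0)
  expect_true(all(diff(x) > 0))
  expect_true(all(x[-1] >= m[-1]))  # correction inflates observed changes
  expect_equal(correct_counts(m, tr, mode = "identity"), as.numeric(m))
})

test_that("corrected counts recover lambda * t on simulated columns", {
  # 200 replicate columns at rate 1 on a tree of length 5
  spec <- simulation_spec(n_leaves = 8, tree_length = 5, n_columns = 200,
                          gamma_shape = 1e6,  # essentially constant rate 1
                          theta = 0, shift_ratio = 1, type2_fraction = 0,
                          gap_fraction = 0, seed = 99)
  sim <- simulate_alignment(spec)
  counts <- clade_site_counts(sim$aln, sim$trees, sim$partition,
                              model = "marginal-ml")
  mean_x <- mean(counts$corrected_count[counts$clade == "A"])
  expect_lt(abs(mean_x - 5) / 5, 0.10)
})

test_that("clade_site_counts covers clades and reflects rate differences", {
  aln <- aln_of(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA", a4 = "AAAA",
                b1 = "AAAA", b2 = "AAAA", b3 = "AAAA", b4 = "AAAA")
  trees <- list(
    A = quartet_tree(paste0("a", 1:4)),
    B = quartet_tree(paste0("b", 1:4))
  )
  part <- tibble::tibble(sequence_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                         clade = rep(c("A", "B"), each = 4))
  counts <- clade_site_counts(aln, trees, part)
  expect_equal(nrow(counts), 8L)
  expect_true(all(counts$raw_count == 0L))
  # posterior-expected corrected counts on constant columns stay near zero
  expect_true(all(counts$corrected_count < 0.2))
  cf <- clade_site_counts(aln, trees, part, model = "fitch")
  expect_true(all(cf$corrected_count == 0))
  expect_equal(unique(counts$tree_length), 6)

  # synthetic fast clade accumulates more corrected substitutions
  spec <- simulation_spec(n_leaves = 8, tree_length = c(4, 16),
                          n_columns = 150, theta = 0, shift_ratio = 1,
                          type2_fraction = 0, gap_fraction = 0, seed = 5)
  sim <- simulate_alignment(spec)
  cs <- clade_site_counts(sim$aln, sim$trees, sim$partition)
  mA <- mean(cs$corrected_count[cs$clade == "A"])
  mB <- mean(cs$corrected_count[cs$clade == "B"])
  expect_gt(mB, mA)

  part_bad <- part
  part_bad$sequence_id[1] <- "zz"
  expect_error(clade_site_counts(aln, trees, part_bad, "fitch"), "zz")
})

test_that("relative rates normalise to mean one and correlate as expected", {
  counts <- tibble::tibble(
    column = rep(1:3, 2),
    clade = rep(c("A", "B"), each = 3),
    raw_count = c(2L, 2L, 2L, 0L, 2L, 4L),
    corrected_count = c(2, 2, 2, 0, 2, 4),
    tree_length = 5
  )
  rates <- relative_rates(counts)
  expect_equal(rates$rate[rates$clade == "A"], c(1, 1, 1))
  expect_equal(rates$rate[rates$clade == "B"], c(0, 1, 2))
  expect_equal(mean(rates$rate[rates$clade == "B"]), 1)

  # identical vectors -> 1; zero variance -> error
  counts2 <- counts
  counts2$corrected_count <- rep(c(1, 2, 3), 2)
  expect_equal(rate_correlation(relative_rates(counts2), "A", "B"), 1)
  counts3 <- counts2
  counts3$corrected_count[4:6] <- c(3, 2, 1)
  expect_equal(rate_correlation(relative_rates(counts3), "A", "B"), -1)
  expect_error(rate_correlation(rates, "A", "A2"))

  # matches the textbook formula on a 5-point fixture
  xa <- c(0, 1, 3, 2, 5); xb <- c(1, 0, 2, 4, 4)
  counts5 <- tibble::tibble(
    column = rep(1:5, 2), clade = rep(c("A", "B"), each = 5),
    raw_count = c(xa, xb), corrected_count = c(xa, xb), tree_length = 1
  )
  expect_equal(rate_correlation(relative_rates(counts5), "A", "B"),
               sum((xa - mean(xa)) * (xb - mean(xb))) /
                 sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2)))

  counts_zero <- counts
  counts_zero$corrected_count[1:3] <- 0
  expect_error(relative_rates(counts_zero), "all-zero")
})
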