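# Synthetic datasets with known rate-shift structure: alignments evolved
# under the equal-exchangeability Poisson amino-acid model (the same model
# the counting machinery assumes), clade trees, and 3D coordinates with
# planted contact clusters. Every downstream module is testable against the
# recorded truth without external data.

#' Specify a simulation
#'
#' Defaults describe the standard two-clade benchmark: two balanced 16-leaf
#' clades of total tree length 8 (about 0.27 substitutions/site per branch,
#' the per-branch scale of the subfamily trees this method targets), 500
#' columns, gamma site rates with shape 0.5 (strong among-site variation),
#' half the columns with an independently redrawn, 8-fold amplified rate in
#' every clade after the first (type I truth), a 5% admixture of radically
#' fixed (type II) columns, and 2% gaps inserted as contiguous per-sequence
#' blocks.
#'
#' @param clades Clade labels.
#' @param n_leaves Leaves per clade (balanced tree; one value or per clade).
#' @param tree_length Total tree length per clade (substitutions/site).
#' @param n_columns Alignment columns.
#' @param gamma_shape Shape of the gamma distribution of site rates
#'   (rate parameter set so the mean rate is 1).
#' @param theta Fraction of columns whose rate shifts in every clade after
#'   the first (type I truth).
#' @param shift_ratio Multiplicative rate shift applied to type I columns
#'   (up or down with equal probability).
#' @param type2_fraction Fraction of columns conserved within clades but
#'   fixed for residues from different radical groups.
#' @param gap_fraction Fraction of each sequence hidden by one contiguous
#'   gap block.
#' @param planted_clusters Optional list of integer column sets to co-locate
#'   in the synthetic structure.
#' @param contact_threshold Contact distance the planted clusters must
#'   satisfy (angstroms).
#' @param seed Mandatory integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(clades = c("A", "B"),
                            n_leaves = 16L,
                            tree_length = 8,
                            n_columns = 500L,
                            gamma_shape = 0.5,
                            theta = 0.5,
                            shift_ratio = 8,
                            type2_fraction = 0.05,
                            gap_fraction = 0.02,
                            planted_clusters = list(),
                            contact_threshold = 4.0,
                            seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (theta + type2_fraction > 1) {
    stop("theta + type2_fraction exceeds 1", call. = FALSE)
  }
  stopifnot(theta >= 0, theta <= 1, type2_fraction >= 0,
            gap_fraction >= 0, gap_fraction < 1,
            gamma_shape > 0, shift_ratio >= 1, n_columns >= 1)
  n_leaves <- rep_len(n_leaves, length(clades))
  tree_length <- rep_len(tree_length, length(clades))
  structure(
    list(clades = clades, n_leaves = n_leaves, tree_length = tree_length,
         n_columns = as.integer(n_columns), gamma_shape = gamma_shape,
         theta = theta, shift_ratio = shift_ratio,
         type2_fraction = type2_fraction, gap_fraction = gap_fraction,
         planted_clusters = planted_clusters,
         contact_threshold = contact_threshold, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# Balanced clade tree with n leaves scaled to total length.
balanced_clade_tree <- function(clade, n, total_length) {
  tr <- if (log2(n) %% 1 == 0) {
    ape::stree(n, type = "balanced")
  } else {
    ape::stree(n, type = "left")
  }
  tr$tip.label <- paste0(clade, "_", seq_len(n))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$edge.length <- tr$edge.length * total_length / sum(tr$edge.length)
  tr
}

# Evolve one clade: root states (integer 1..20) given per column, per-column
# rates given; returns tips x columns integer matrix.
evolve_clade <- function(tree, root_states, rates) {
  kappa <- 20 / 19
  topo <- node_children(tree)
  nt <- topo$n_tip
  n_nodes <- max(c(topo$parents, topo$edge))
  C <- length(root_states)
  states <- matrix(0L, n_nodes, C)
  root <- topo$parents[length(topo$parents)]
  states[root, ] <- root_states
  # preorder: reverse postorder
  blen <- rep(NA_real_, n_nodes)
  blen[topo$edge[, 2]] <- topo$edge.length
  for (i in rev(seq_along(topo$parents))) {
    p <- topo$parents[i]
    for (c_ in topo$children[[i]]) {
      keep <- stats::runif(C) < exp(-kappa * rates * blen[c_])
      st <- states[p, ]
      redraw <- !keep
      st[redraw] <- sample.int(20L, sum(redraw), replace = TRUE)
      states[c_, ] <- st
    }
  }
  out <- states[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate an alignment with planted rate-shift structure
#'
#' Per column, a rate lambda ~ Gamma(shape, shape) (mean 1) is drawn and
#' shared by all clades. With probability `theta` the column is type I: every
#' clade after the first redraws an independent rate, multiplied or divided
#' by `shift_ratio` with equal probability. A `type2_fraction` of columns is
#' fully conserved within each clade but fixed for residues from different
#' radical groups between clades. Residues evolve along each clade tree under
#' the equal-exchangeability Poisson model from a shared family root state;
#' gaps are inserted as one contiguous block per sequence.
#'
#' @param spec A [simulation_spec()].
#' @return Object of class `lsc_sim`: list with `aln` (an `msa`), `trees`
#'   (named list), `partition` (tibble), `coords` (synthetic
#'   `residue_coords`), `structmap`, `truth` (tibble: `column`, `class`,
#'   plus true per-clade rates), and the `spec`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  C <- spec$n_columns
  K <- length(spec$clades)
  trees <- Map(balanced_clade_tree, spec$clades, spec$n_leaves,
               spec$tree_length)
  names(trees) <- spec$clades

  classes <- sample(c("type1", "type2", "shared"), C, replace = TRUE,
                    prob = c(spec$theta, spec$type2_fraction,
                             1 - spec$theta - spec$type2_fraction))
  base_rate <- stats::rgamma(C, shape = spec$gamma_shape,
                             rate = spec$gamma_shape)
  rates <- matrix(base_rate, nrow = K, ncol = C, byrow = TRUE,
                  dimnames = list(spec$clades, NULL))
  is1 <- classes == "type1"
  if (any(is1) && K >= 2) {
    # type I truth: every clade after the first redraws an independent rate
    # from the same gamma, amplified by the shift factor (up or down with
    # equal probability; 1 = pure redraw)
    for (k in 2:K) {
      redraw <- stats::rgamma(sum(is1), shape = spec$gamma_shape,
                              rate = spec$gamma_shape)
      sgn <- sample(c(-1, 1), sum(is1), replace = TRUE)
      rates[k, is1] <- redraw * spec$shift_ratio^sgn
    }
  }
  is2 <- classes == "type2"
  rates[, is2] <- 0

  root_states <- sample.int(20L, C, replace = TRUE)
  groups <- radical_groups()
  type2_roots <- matrix(0L, nrow = K, ncol = sum(is2))
  if (any(is2)) {
    for (j in seq_len(sum(is2))) {
      gs <- if (K <= length(groups)) {
        sample(names(groups), K)
      } else {
        rep_len(sample(names(groups)), K)  # > 4 clades: groups must repeat
      }
      type2_roots[, j] <- vapply(gs, function(g) {
        aa_encode(sample(groups[[g]], 1))
      }, integer(1))
    }
  }

  tip_mats <- lapply(seq_len(K), function(k) {
    rs <- root_states
    if (any(is2)) rs[is2] <- type2_roots[k, ]
    evolve_clade(trees[[k]], rs, rates[k, ])
  })
  tips <- do.call(rbind, tip_mats)
  chars <- matrix(aa_decode(tips), nrow = nrow(tips),
                  dimnames = list(rownames(tips), NULL))

  # contiguous gap block per sequence
  if (spec$gap_fraction > 0) {
    block <- max(1L, round(spec$gap_fraction * C))
    for (i in seq_len(nrow(chars))) {
      start <- sample.int(C - block + 1L, 1L)
      chars[i, start:(start + block - 1L)] <- "-"
    }
  }
  aln <- new_msa(chars)
  partition <- tibble::tibble(
    sequence_id = rownames(chars),
    clade = rep(spec$clades, vapply(tip_mats, nrow, integer(1)))
  )
  truth <- tibble::tibble(column = seq_len(C), class = classes)
  for (k in seq_len(K)) truth[[paste0("rate_", spec$clades[k])]] <- rates[k, ]

  ref_id <- rownames(chars)[1]
  ref_row <- chars[1, ]
  n_res <- sum(ref_row != "-")
  coords <- simulate_coordinates(n_res, spec$planted_clusters,
                                 spec$contact_threshold,
                                 aa = ref_row[ref_row != "-"])
  structmap <- map_alignment_to_structure(aln, ref_id, coords)

  structure(
    list(aln = aln, trees = trees, partition = partition, coords = coords,
         structmap = structmap, truth = truth, ref_id = ref_id, spec = spec),
    class = "lsc_sim"
  )
}

#' @export
print.lsc_sim <- function(x, ...) {
  cat("<lsc_sim> ", nrow(x$aln), " sequences x ", ncol(x$aln),
      " columns; clades: ", paste(x$spec$clades, collapse = ", "),
      "; seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate residue coordinates with planted contact clusters
#'
#' Residues lie on a straight backbone-like chain with consecutive spacing
#' 3.8 angstroms, so chain neighbours are within a 4-angstrom threshold
#' (real signal, mirroring the consecutive-pair statistic) while all other
#' pairs are far apart. Residues of each planted cluster (given as residue
#' indices along the chain) are repositioned into a tight, well-separated
#' blob so that all intra-cluster pairs fall within `threshold` and no
#' cross-cluster or cluster-to-chain pair does.
#'
#' @param n_residues Chain length.
#' @param planted_clusters List of disjoint integer index sets.
#' @param threshold Contact distance the clusters must satisfy.
#' @param aa One-letter residue types (default all alanine).
#' @return A `residue_coords` tibble (synthetic; chain "A").
#' @export
simulate_coordinates <- function(n_residues, planted_clusters = list(),
                                 threshold = 4.0, aa = NULL) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (length(planted_clusters) > 1L) {
    for (i in seq_along(planted_clusters)) {
      for (j in seq_along(planted_clusters)) {
        if (j > i && length(intersect(planted_clusters[[i]],
                                      planted_clusters[[j]]))) {
          stop("planted clusters must be disjoint", call. = FALSE)
        }
      }
    }
  }
  x <- 3.8 * seq_len(n_residues)
  y <- rep(0, n_residues)
  z <- rep(0, n_residues)
  for (ci in seq_along(planted_clusters)) {
    idx <- planted_clusters[[ci]]
    if (any(idx < 1L | idx > n_residues)) {
      stop("planted cluster indices outside the chain", call. = FALSE)
    }
    k <- length(idx)
    spacing <- if (k > 1L) 0.9 * threshold / (k - 1L) else 0
    if (spacing < 1e-3 && k > 1L) {
      stop("cluster of ", k, " residues is geometrically infeasible at ",
           "threshold ", threshold, call. = FALSE)
    }
    # tight line segment of total extent 0.9 * threshold, far off the chain
    x[idx] <- spacing * (seq_len(k) - 1L)
    y[idx] <- 100 * ci
    z[idx] <- 100
  }
  out <- tibble::tibble(
    chain = "A",
    resno = seq_len(n_residues),
    insert = "",
    aa = if (is.null(aa)) rep("A", n_residues) else aa,
    x = x, y = y, z = z
  )
  class(out) <- c("residue_coords", class(out))
  attr(out, "atom_mode") <- "CA"
  out
}

#' Simulate a quartet fixture for the clustering test
#'
#' Four clades; type I columns for the (A,B) edge are planted inside one
#' spatial cluster and those for the (C,D) edge inside another (`planted =
#' TRUE`), or scattered along the chain (`planted = FALSE`). With planting
#' on and accurate site calls, the clustering permutation test should
#' reject; with scattering it should not. The expected outcome is recorded.
#'
#' @param n_sites Planted type I columns per edge (default 12).
#' @param planted Co-locate the planted sites in space? (default TRUE)
#' @param seed Integer seed.
#' @param n_columns,n_leaves,tree_length,gamma_shape,shift_ratio
#'   Generator conditions (see [simulation_spec()]); gaps are disabled so
#'   every column maps to the structure.
#' @return An `lsc_sim` with extra elements `planted_e1`, `planted_e2`
#'   (column sets) and `expect_significant`.
#' @export
simulate_quartet_fixture <- function(n_sites = 12L, planted = TRUE, seed,
                                     n_columns = 300L, n_leaves = 16L,
                                     tree_length = 16, gamma_shape = 0.5,
                                     shift_ratio = 8) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  C <- as.integer(n_columns)
  clades <- c("A", "B", "C", "D")
  if (planted) {
    s1 <- 1:n_sites + 9L                      # contiguous blocks, apart
    s2 <- 1:n_sites + 9L + n_sites + 30L
  } else {
    cols <- sample.int(C, 2L * n_sites)
    s1 <- sort(cols[seq_len(n_sites)])
    s2 <- sort(cols[n_sites + seq_len(n_sites)])
  }

  spec <- simulation_spec(clades = clades, n_leaves = n_leaves,
                          tree_length = tree_length, n_columns = C,
                          gamma_shape = gamma_shape, theta = 0,
                          shift_ratio = shift_ratio, type2_fraction = 0,
                          gap_fraction = 0,
                          planted_clusters = if (planted) list(s1, s2)
                                             else list(),
                          seed = seed)
  sim <- simulate_alignment(spec)

  # impose the rate shifts: s1 shifts between A and B, s2 between C and D
  base <- sim$truth[[paste0("rate_", "A")]]
  rates <- sapply(clades, function(cl) sim$truth[[paste0("rate_", cl)]])
  rates[, ] <- base  # theta = 0: all clades share the base rate
  rates[s1, "B"] <- base[s1] * shift_ratio^(sample(c(-1, 1), length(s1),
                                                   replace = TRUE))
  rates[s2, "D"] <- base[s2] * shift_ratio^(sample(c(-1, 1), length(s2),
                                                   replace = TRUE))
  root_states <- sample.int(20L, C, replace = TRUE)
  tip_mats <- lapply(clades, function(cl) {
    evolve_clade(sim$trees[[cl]], root_states, rates[, cl])
  })
  tips <- do.call(rbind, tip_mats)
  chars <- matrix(aa_decode(tips), nrow = nrow(tips),
                  dimnames = list(rownames(tips), NULL))
  sim$aln <- new_msa(chars)
  sim$truth$class <- "shared"
  sim$truth$class[c(s1, s2)] <- "type1"
  for (cl in clades) sim$truth[[paste0("rate_", cl)]] <- rates[, cl]
  # refresh coordinate residue types to the re-evolved reference row
  ref_row <- chars[sim$ref_id, ]
  sim$coords$aa <- ref_row[ref_row != "-"]
  sim$structmap <- map_alignment_to_structure(sim$aln, sim$ref_id, sim$coords)
  sim$planted_e1 <- s1
  sim$planted_e2 <- s2
  sim$expect_significant <- planted
  sim
}

#' Simulate Poisson substitution totals
#'
#' @param lambda Positive rate.
#' @param t Vector of positive tree lengths.
#' @param seed Optional integer seed.
#' @return Integer counts, independent Poisson with means `lambda * t`.
#' @export
simulate_poisson_counts <- function(lambda, t, seed = NULL) {
  stopifnot(lambda >= 0, all(t >= 0))
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(t), lambda * t)
}

#' Write a synthetic dataset to standard files
#'
#' Emits FASTA alignment, one Newick per clade, a TSV clade map, a PDB of the
#' synthetic coordinates, and the truth table.
#'
#' @param sim An `lsc_sim`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(alignment = file.path(dir, "alignment.fasta"),
                clade_map = file.path(dir, "clades.tsv"),
                structure = file.path(dir, "structure.pdb"),
                truth = file.path(dir, "truth.tsv"))
  write_alignment(sim$aln, paths$alignment)
  utils::write.table(as.data.frame(sim$partition), paths$clade_map,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cl in names(sim$trees)) {
    p <- file.path(dir, paste0("tree_", cl, ".nwk"))
    write_tree(sim$trees[[cl]], p)
    paths[[paste0("tree_", cl)]] <- p
  }
  co <- sim$coords
  bio3d::write.pdb(file = paths$structure,
                   xyz = as.numeric(t(as.matrix(co[, c("x", "y", "z")]))),
                   resno = co$resno,
                   resid = bio3d::aa123(co$aa),
                   chain = co$chain,
                   elety = rep("CA", nrow(co)))
  utils::write.table(as.data.frame(sim$truth), paths$truth,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
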