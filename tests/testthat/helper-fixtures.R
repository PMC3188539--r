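# Shared fixtures and independent oracles used across the test files.

# Alignment from named sequences.
aln_of <- function(...) new_msa(c(...))

# Quartet tree ((a,b),(c,d)) with unit branch lengths.
quartet_tree <- function(labels = c("a", "b", "c", "d"), bl = 1) {
  txt <- sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                 labels[1], bl, labels[2], bl, bl,
                 labels[3], bl, labels[4], bl, bl)
  ape::read.tree(text = txt)
}

# Exhaustive minimum-change oracle: minimum over all assignments of observed
# amino-acid states to internal nodes of the number of differing edges, a
# gapped leaf always counting one change. Feasible for trees with <= 6 leaves.
exhaustive_min_changes <- function(tree, leaf_chars) {
  nt <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- leaf_chars[tree$tip.label]
  obs <- sort(unique(states[states %in% lscscan:::AA20]))
  if (length(obs) == 0L) obs <- "A"
  gap_cost <- sum(!(states %in% lscscan:::AA20))
  grid <- expand.grid(rep(list(obs), n_int), stringsAsFactors = FALSE)
  edge <- tree$edge
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- unlist(grid[g, ], use.names = FALSE)
    node_state <- function(v) {
      if (v <= nt) states[v] else assign[v - nt]
    }
    cost <- 0L
    for (e in seq_len(nrow(edge))) {
      p <- node_state(edge[e, 1]); c_ <- node_state(edge[e, 2])
      if (!(c_ %in% lscscan:::AA20)) next  # gap edges counted once below
      if (p != c_) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best + gap_cost
}

# Brute-force connected components by floodfill over an edge list.
floodfill_components <- function(vertices, edges) {
  comp <- stats::setNames(seq_along(vertices), vertices)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- as.character(edges[k, 1]); b <- as.character(edges[k, 2])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(vertices, comp)
}

# Minimal hand-written PDB text: CA atoms for a chain, optionally two models.
toy_pdb <- function(path, resnames, xyz, chain = "A", two_models = FALSE) {
  atom_line <- function(i, serial, model_shift = 0) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resnames[i], chain, i,
            xyz[i, 1] + model_shift, xyz[i, 2], xyz[i, 3])
  }
  n <- length(resnames)
  lines <- character(0)
  if (two_models) lines <- c(lines, "MODEL        1")
  lines <- c(lines, vapply(seq_len(n), function(i) atom_line(i, i), ""))
  if (two_models) {
    lines <- c(lines, "ENDMDL", "MODEL        2",
               vapply(seq_len(n), function(i) atom_line(i, n + i, 500), ""),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Standard two-clade benchmark used by the recovery tests.
standard_fixture <- function(seed) {
  simulation_spec(theta = 0.5, shift_ratio = 8, type2_fraction = 0,
                  gap_fraction = 0, seed = seed)
}
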