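# Ancestral amino-acid state reconstruction, vectorised over alignment
# columns. Two models:
#   * "fitch"       -- minimum-change assignment (Hartigan's generalisation,
#                      exact on multifurcations), ties broken lexicographically;
#   * "marginal-ml" -- marginal maximum-likelihood states under the
#                      equal-exchangeability (Poisson) amino-acid model with
#                      the tree's branch lengths.
# Gapped leaves carry no information (full state set / flat likelihood);
# ancestors always receive amino-acid states, never gaps.

FULL_MASK <- bitwShiftL(1L, 20L) - 1L  # all 20 residues

# Split the alignment rows for the tree's tips into an integer state matrix
# (tips x columns; 0 = gap/unknown), rows ordered as tree$tip.label.
tip_state_matrix <- function(aln, tree) {
  tips <- tree$tip.label
  missing <- setdiff(tips, msa_ids(aln))
  if (length(missing)) {
    stop("tree leaves absent from alignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- unclass(aln)[tips, , drop = FALSE]
  st <- matrix(aa_encode(m), nrow = nrow(m))
  rownames(st) <- tips
  st
}

# Children lists per internal node, postorder over internal nodes.
node_children <- function(tree) {
  nt <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(ord$edge[, 1])    # postorder: children before parents
  ch <- split(ord$edge[, 2], factor(ord$edge[, 1], levels = parents))
  list(parents = parents, children = ch, n_tip = nt,
       edge = tree$edge, edge.length = tree$edge.length)
}

# Hartigan/Fitch upward pass on bitmask state sets.
# Returns list(vu = matrix (n_nodes x C) of bitmasks).
fitch_up <- function(tip_states, topo) {
  nt <- topo$n_tip
  n_node <- nt + max(1L, topo$parents[length(topo$parents)] - nt)
  C <- ncol(tip_states)
  vu <- matrix(0L, nrow = max(topo$parents), ncol = C)
  leaf_mask <- matrix(FULL_MASK, nrow = nt, ncol = C)
  nz <- tip_states > 0L
  leaf_mask[nz] <- bitwShiftL(1L, tip_states[nz] - 1L)
  vu[seq_len(nt), ] <- leaf_mask

  bits <- bitwShiftL(1L, 0:19)
  for (i in seq_along(topo$parents)) {
    p <- topo$parents[i]
    ch <- topo$children[[i]]
    if (length(ch) == 2L) {
      a <- vu[ch[1L], ]; b <- vu[ch[2L], ]
      inter <- bitwAnd(a, b)
      un <- bitwOr(a, b)
      vu[p, ] <- ifelse(inter != 0L, inter, un)
    } else {
      # per-state child counts; VU = states attaining the max count
      cnt <- matrix(0L, nrow = 20L, ncol = C)
      for (c_ in ch) {
        row <- vu[c_, ]
        for (s in 1:20) {
          cnt[s, ] <- cnt[s, ] + (bitwAnd(row, bits[s]) != 0L)
        }
      }
      mx <- apply(cnt, 2, max)
      sel <- sweep(cnt, 2, mx, "==")
      out <- integer(C)
      for (s in 1:20) out <- bitwOr(out, ifelse(sel[s, ], bits[s], 0L))
      vu[p, ] <- out
    }
  }
  vu
}

# Backtrack single minimum-change states from VU sets: root takes the
# lexicographically smallest member; a child keeps its parent's state when
# possible, otherwise its smallest member.
lowest_bit_state <- function(mask) {
  out <- integer(length(mask))
  remaining <- mask != 0L
  for (s in 1:20) {
    hit <- remaining & (bitwAnd(mask, bitwShiftL(1L, s - 1L)) != 0L)
    out[hit] <- s
    remaining <- remaining & !hit
    if (!any(remaining)) break
  }
  out
}

fitch_backtrack <- function(vu, topo) {
  nt <- topo$n_tip
  C <- ncol(vu)
  root <- topo$parents[length(topo$parents)]
  states <- matrix(0L, nrow = nrow(vu), ncol = C)
  states[root, ] <- lowest_bit_state(vu[root, ])
  # preorder: reverse postorder of internal nodes
  for (i in rev(seq_along(topo$parents))) {
    p <- topo$parents[i]
    for (c_ in topo$children[[i]]) {
      if (c_ <= nt) next
      pb <- bitwShiftL(1L, states[p, ] - 1L)
      keep <- bitwAnd(vu[c_, ], pb) != 0L
      st <- lowest_bit_state(vu[c_, ])
      st[keep] <- states[p, keep]
      states[c_, ] <- st
    }
  }
  states[(nt + 1L):nrow(vu), , drop = FALSE]
}

# Marginal-ML reconstruction under the 20-state equal-rates model.
# P(t) = e^{-kt} I + (1 - e^{-kt}) J/20, k = 20/19 so that branch lengths are
# expected substitutions per site. Besides max-marginal states, computes the
# posterior expected number of visibly changed edges per column (gapped leaf
# edges count 1, per the gap rule).
marginal_ml_states <- function(tip_states, topo, rates = NULL) {
  nt <- topo$n_tip
  C <- ncol(tip_states)
  kappa <- 20 / 19
  if (is.null(rates)) rates <- rep(1, C)
  n_nodes <- max(c(topo$parents, topo$edge))
  # branch length of the edge above each node
  blen <- rep(NA_real_, n_nodes)
  blen[topo$edge[, 2]] <- topo$edge.length
  # per-column transition weight for the edge above node v
  edge_e <- function(v) exp(-kappa * blen[v] * rates)
  up <- vector("list", n_nodes)    # up message: likelihood of subtree below node
  for (tip in seq_len(nt)) {
    L <- matrix(1, nrow = 20L, ncol = C)
    obs <- tip_states[tip, ] > 0L
    if (any(obs)) {
      L[, obs] <- 0
      L[cbind(tip_states[tip, obs], which(obs))] <- 1
    }
    up[[tip]] <- L
  }
  msg_to_parent <- function(L, e) {
    sw <- colSums(L) / 20
    rep(e, each = 20L) * L + rep((1 - e) * sw, each = 20L)
  }
  msgs <- vector("list", n_nodes)  # message from node to its parent
  for (i in seq_along(topo$parents)) {
    p <- topo$parents[i]
    L <- matrix(1, nrow = 20L, ncol = C)
    for (c_ in topo$children[[i]]) {
      msgs[[c_]] <- msg_to_parent(up[[c_]], edge_e(c_))
      L <- L * msgs[[c_]]
    }
    sc <- apply(L, 2, max)
    sc[sc == 0] <- 1
    L <- sweep(L, 2, sc, "/")
    up[[p]] <- L
  }
  root <- topo$parents[length(topo$parents)]
  down <- vector("list", n_nodes)  # message from above, incl. prior
  down[[root]] <- matrix(1 / 20, nrow = 20L, ncol = C)
  internal <- rev(topo$parents)
  states <- matrix(0L, nrow = n_nodes, ncol = C)
  expected_changes <- numeric(C)
  for (p in internal) {
    i <- match(p, topo$parents)
    tot <- up[[p]] * down[[p]]
    states[p, ] <- max.col(t(tot), ties.method = "first")
    for (c_ in topo$children[[i]]) {
      W <- tot / msgs[[c_]]
      W[!is.finite(W)] <- 0
      e <- edge_e(c_)
      if (c_ <= nt) {
        # leaf edge: P(parent state = leaf state | data); gap counts 1
        gapped <- tip_states[c_, ] == 0L
        s1 <- numeric(C)
        obs <- which(!gapped)
        if (length(obs)) s1[obs] <- W[cbind(tip_states[c_, obs], obs)]
        s2 <- colSums(W)
        psame <- (e + (1 - e) / 20) * s1 /
          (e * s1 + (1 - e) / 20 * s2)
        psame[gapped] <- 0
        psame[!is.finite(psame)] <- 1
        expected_changes <- expected_changes + (1 - psame)
      } else {
        uc <- up[[c_]]
        s1 <- colSums(W * uc)
        s2 <- colSums(W)
        s3 <- colSums(uc)
        psame <- (e + (1 - e) / 20) * s1 /
          (e * s1 + (1 - e) / 20 * s2 * s3)
        psame[!is.finite(psame)] <- 1
        expected_changes <- expected_changes + (1 - psame)
        D <- msg_to_parent(W, e)
        sc <- apply(D, 2, max)
        sc[sc == 0] <- 1
        down[[c_]] <- sweep(D, 2, sc, "/")
      }
    }
  }
  list(states = states[(nt + 1L):n_nodes, , drop = FALSE],
       expected_changes = expected_changes)
}

#' Reconstruct ancestral amino-acid states
#'
#' Assigns one amino-acid state (never a gap) to every internal node at every
#' alignment column. `"fitch"` gives a minimum-change assignment; ties are
#' broken by lexicographic amino-acid order, so results are deterministic.
#' `"marginal-ml"` uses marginal posteriors under the equal-exchangeability
#' Poisson amino-acid model with the tree's branch lengths; gapped leaves are
#' treated as missing data. Columns in which every leaf is gapped are flagged
#' uninformative and their ancestors are set to the most common residue of
#' the whole sub-alignment.
#'
#' @param aln An `msa` object.
#' @param tree An `ape::phylo` whose tips appear in `aln`.
#' @param model `"marginal-ml"` (default) or `"fitch"`.
#' @param rates Optional per-column relative rates used to scale branch
#'   lengths in the marginal-ML model (default: rate 1 everywhere). Used by
#'   the rate-aware second counting pass; ignored for `"fitch"`.
#' @return Object of class `ancestral_states`: list with `node_states`
#'   (internal nodes x columns, integer codes into the 20-residue alphabet),
#'   `leaf_states`, `root_state` (character per column), `expected_changes`
#'   (marginal-ML only: posterior expected number of changed edges per
#'   column, the basis of the default multiple-hit correction),
#'   `uninformative` (logical per column), `model`, and the `tree`.
#' @export
reconstruct_ancestral_states <- function(aln, tree,
                                         model = c("marginal-ml", "fitch"),
                                         rates = NULL) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  st <- tip_state_matrix(aln, tree)
  topo <- node_children(tree)
  nt <- topo$n_tip

  expected_changes <- NULL
  anc <- if (model == "fitch") {
    vu <- fitch_up(st, topo)
    fitch_backtrack(vu, topo)
  } else {
    ml <- marginal_ml_states(st, topo, rates = rates)
    expected_changes <- ml$expected_changes
    ml$states
  }

  uninformative <- colSums(st > 0L) == 0L
  if (any(uninformative)) {
    tab <- tabulate(st[st > 0L], nbins = 20L)
    common <- if (sum(tab) > 0L) which.max(tab) else 1L
    anc[, uninformative] <- common
  }
  root_row <- topo$parents[length(topo$parents)] - nt
  structure(
    list(
      node_states = anc,
      leaf_states = st,
      root_state = aa_decode(anc[root_row, ]),
      expected_changes = expected_changes,
      uninformative = uninformative,
      model = model,
      tree = tree
    ),
    class = "ancestral_states"
  )
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("<ancestral_states> model=", x$model, ", ",
      nrow(x$node_states), " internal nodes x ",
      ncol(x$node_states), " columns\n", sep = "")
  invisible(x)
}
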