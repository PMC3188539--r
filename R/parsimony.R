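# Exhaustive maximum parsimony over LSC characters: every unrooted binary
# topology on up to 9 taxa is generated exactly once by stepwise addition and
# scored with bit-encoded Fitch operations (characters scored in parallel as
# bitmask vectors).

# Enumerate unrooted binary topologies as parent vectors rooted at tip 1:
# tips 1..n, internal nodes n+1..2n-2; parent[v] = 0 for the root tip.
# Taxon k is inserted on every existing edge (edge = non-root node v).
enumerate_parent_vectors <- function(n, visit) {
  stopifnot(n >= 3L)
  n_nodes <- 2L * n - 2L
  parent <- integer(n_nodes)
  i1 <- n + 1L
  parent[i1] <- 1L
  parent[2L] <- i1
  parent[3L] <- i1
  count <- 0L
  recurse <- function(k, insertable) {
    if (k > n) {
      count <<- count + 1L
      visit(parent)
      return(invisible(NULL))
    }
    m <- n + (k - 2L)
    for (v in insertable) {
      old <- parent[v]
      parent[m] <<- old
      parent[v] <<- m
      parent[k] <<- m
      recurse(k + 1L, c(insertable, k, m))
      parent[v] <<- old
    }
    parent[m] <<- 0L
    parent[k] <<- 0L
    invisible(NULL)
  }
  recurse(4L, c(2L, 3L, i1))
  count
}

# Parent vector -> unrooted Newick with a basal trifurcation:
# (tip1, child1-of-rootchild, child2-of-rootchild);
parent_vec_to_newick <- function(parent, labels) {
  n_nodes <- length(parent)
  n <- (n_nodes + 2L) %/% 2L
  kids <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)[-1L]) {
    p <- parent[v]
    if (p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  sub <- function(v) {
    if (v <= n) return(labels[v])
    ch <- vapply(kids[[v]], sub, character(1))
    paste0("(", paste(ch, collapse = ","), ")")
  }
  rc <- kids[[1L]][1L]
  ch <- vapply(kids[[rc]], sub, character(1))
  paste0("(", labels[1L], ",", paste(ch, collapse = ","), ");")
}

# Fitch score of one parent-vector tree for bit-encoded characters.
# tip_masks: n_tip x n_char integer matrix (missing = full mask).
fitch_score_parent <- function(parent, n_tip, tip_masks) {
  n_nodes <- length(parent)
  kids <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)[-1L]) {
    p <- parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  sets <- vector("list", n_nodes)
  changes <- integer(ncol(tip_masks))
  # iterative postorder from the root tip's single child
  rc <- kids[[1L]][1L]
  stack <- rc
  post <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(v, post)
    if (v > n_tip) stack <- c(stack, kids[[v]])
  }
  for (v in post) {
    if (v <= n_tip) {
      sets[[v]] <- tip_masks[v, ]
    } else {
      ch <- kids[[v]]
      a <- sets[[ch[1L]]]
      b <- sets[[ch[2L]]]
      inter <- bitwAnd(a, b)
      empty <- inter == 0L
      changes <- changes + empty
      sets[[v]] <- ifelse(empty, bitwOr(a, b), inter)
    }
  }
  root_set <- sets[[rc]]
  changes + (bitwAnd(tip_masks[1L, ], root_set) == 0L)
}

#' Enumerate unrooted binary topologies
#'
#' Generates each of the (2n-5)!! distinct unrooted binary topologies on the
#' given taxa exactly once.
#'
#' @param n_taxa Number of taxa, between 3 and 9.
#' @param labels Optional taxon labels (default `t1..tn`).
#' @param collect If `TRUE` (default for n <= 7), return the topologies as an
#'   `ape::multiPhylo`; otherwise only count them.
#' @return If `collect`, a `multiPhylo` with attribute `"count"`; otherwise
#'   the integer count.
#' @export
#' @examples
#' length(enumerate_topologies(4))  # 3
enumerate_topologies <- function(n_taxa, labels = NULL,
                                 collect = n_taxa <= 7L) {
  if (n_taxa < 3L || n_taxa > 9L) {
    stop("exhaustive enumeration supports 3..9 taxa ",
         "(heuristic search is out of scope)", call. = FALSE)
  }
  labels <- labels %||% paste0("t", seq_len(n_taxa))
  if (collect) {
    nwk <- character(0)
    cnt <- enumerate_parent_vectors(n_taxa, function(p) {
      nwk[length(nwk) + 1L] <<- parent_vec_to_newick(p, labels)
    })
    trees <- ape::read.tree(text = nwk)
    if (inherits(trees, "phylo")) trees <- c(trees)  # n = 3: single tree
    attr(trees, "count") <- cnt
    trees
  } else {
    enumerate_parent_vectors(n_taxa, function(p) NULL)
  }
}

# Encode one character (vector named by taxa, NA = missing) as bitmasks in
# the order of `taxa`. Returns list(masks, n_states).
encode_character <- function(states, taxa) {
  x <- states[taxa]
  x[x %in% c("?", "")] <- NA
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) > 30L) stop("more than 30 states in one character",
                              call. = FALSE)
  full <- bitwShiftL(1L, length(lev)) - 1L
  if (full == 0L) full <- 1L
  m <- ifelse(is.na(x), full, bitwShiftL(1L, match(x, lev) - 1L))
  list(masks = as.integer(m), n_states = length(lev))
}

# character_matrix tibble (or matrix with rownames) -> tip mask matrix.
character_masks <- function(cm) {
  if (tibble::is_tibble(cm) || is.data.frame(cm)) {
    taxa <- cm$clade
    chars <- cm[, setdiff(names(cm), "clade"), drop = FALSE]
    char_list <- lapply(chars, function(col) stats::setNames(col, taxa))
  } else {
    taxa <- rownames(cm)
    char_list <- lapply(seq_len(ncol(cm)),
                        function(j) stats::setNames(cm[, j], taxa))
    names(char_list) <- colnames(cm)
  }
  enc <- lapply(char_list, encode_character, taxa = taxa)
  masks <- vapply(enc, `[[`, integer(length(taxa)), "masks")
  if (is.null(dim(masks))) masks <- matrix(masks, nrow = length(taxa))
  list(taxa = taxa, masks = masks,
       n_states = vapply(enc, `[[`, integer(1), "n_states"),
       char_names = names(char_list))
}

#' Fitch parsimony score of a topology
#'
#' Minimum number of unordered state changes needed to explain each
#' character on the topology; missing states are wildcards. Exact on
#' multifurcating trees (Hartigan's generalisation).
#'
#' @param tree An `ape::phylo` (branch lengths ignored).
#' @param cm A [character_matrix()] tibble, or a matrix of states with taxa
#'   as row names (`NA` = missing).
#' @return Integer total score with attribute `"per_character"`.
#' @export
fitch_score <- function(tree, cm) {
  cm_enc <- character_masks(cm)
  if (!setequal(tree$tip.label, cm_enc$taxa)) {
    stop("tree tips do not match the character matrix taxa", call. = FALSE)
  }
  masks <- cm_enc$masks[match(tree$tip.label, cm_enc$taxa), , drop = FALSE]
  topo <- node_children(tree)
  nC <- ncol(masks)
  full_by_char <- apply(masks, 2, function(col) Reduce(bitwOr, col))
  vu <- matrix(0L, nrow = max(topo$parents), ncol = nC)
  vu[seq_len(topo$n_tip), ] <- masks
  changes <- integer(nC)
  bits <- bitwShiftL(1L, 0:29)
  for (i in seq_along(topo$parents)) {
    p <- topo$parents[i]
    ch <- topo$children[[i]]
    if (length(ch) == 2L) {
      a <- vu[ch[1L], ]; b <- vu[ch[2L], ]
      inter <- bitwAnd(a, b)
      empty <- inter == 0L
      changes <- changes + empty
      vu[p, ] <- ifelse(empty, bitwOr(a, b), inter)
    } else {
      nst <- max(ceiling(log2(max(full_by_char) + 1)), 1L)
      cnt <- matrix(0L, nrow = nst, ncol = nC)
      for (c_ in ch) {
        row <- vu[c_, ]
        for (s in seq_len(nst)) {
          cnt[s, ] <- cnt[s, ] + (bitwAnd(row, bits[s]) != 0L)
        }
      }
      mx <- apply(cnt, 2, max)
      changes <- changes + (length(ch) - mx)
      sel <- sweep(cnt, 2, mx, "==")
      out <- integer(nC)
      for (s in seq_len(nst)) out <- bitwOr(out, ifelse(sel[s, ], bits[s], 0L))
      vu[p, ] <- out
    }
  }
  per_char <- stats::setNames(as.integer(changes), cm_enc$char_names)
  structure(sum(per_char), per_character = per_char)
}

#' Exhaustive maximum-parsimony search over LSC characters
#'
#' Scores every unrooted binary topology on the matrix's taxa and returns all
#' topologies attaining the minimum score (parsimony is unrooted; trees are
#' reported unrooted).
#'
#' @param cm A [character_matrix()] tibble or a state matrix with taxa row
#'   names (`NA`/`"?"` = missing).
#' @return Object of class `parsimony_result`: `best_score`, `trees`
#'   (`multiPhylo` of optimal topologies), `per_character` (score breakdown
#'   on the first optimal tree), `n_topologies`, `lower_bound`.
#' @export
mp_search <- function(cm) {
  enc <- character_masks(cm)
  n <- length(enc$taxa)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (n > 9L) {
    stop("exhaustive search limited to 9 taxa", call. = FALSE)
  }
  masks <- enc$masks
  best <- Inf
  best_nwk <- character(0)
  cnt <- enumerate_parent_vectors(n, function(p) {
    sc <- sum(fitch_score_parent(p, n, masks))
    if (sc < best) {
      best <<- sc
      best_nwk <<- parent_vec_to_newick(p, enc$taxa)
    } else if (sc == best) {
      best_nwk[length(best_nwk) + 1L] <<- parent_vec_to_newick(p, enc$taxa)
    }
  })
  trees <- ape::read.tree(text = best_nwk)
  if (inherits(trees, "phylo")) trees <- c(trees)
  per_char <- attr(fitch_score(trees[[1]], cm), "per_character")
  lower <- sum(pmax(enc$n_states - 1L, 0L))
  structure(
    list(best_score = as.integer(best),
         trees = trees,
         per_character = per_char,
         n_topologies = cnt,
         lower_bound = as.integer(lower)),
    class = "parsimony_result"
  )
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> best score ", x$best_score, " (lower bound ",
      x$lower_bound, "); ", length(x$trees), " optimal topolog",
      if (length(x$trees) == 1L) "y" else "ies", " of ", x$n_topologies,
      "\n", sep = "")
  invisible(x)
}
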