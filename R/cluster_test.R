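# Quartet permutation test: do rate-shift (type I) sites on two independent
# edges of a quartet co-locate in the reference structure?

#' Select top type I sites for the two edges of a quartet
#'
#' Ranks columns by posterior probability of a type I transition along each
#' edge, takes the top `n` per edge, and discards sites common to both top
#' lists, leaving disjoint sets of equal size n' = n - |common|.
#'
#' @param posteriors_ab,posteriors_cd [type_I_posteriors()] tables for the
#'   (A,B) and (C,D) edges.
#' @param n Sites per edge before removal of common sites (default 25).
#' @return List with `sites_e1`, `sites_e2` (integer columns), `n_common`.
#' @export
select_quartet_sites <- function(posteriors_ab, posteriors_cd, n = 25L) {
  stopifnot(n >= 2L)
  top_n_sites <- function(post, label) {
    if (nrow(post) < n) {
      stop("edge ", label, " has only ", nrow(post), " callable sites; ",
           "choose a smaller n (clades with small tree lengths are unlikely ",
           "to exhibit ", n, " type I sites)", call. = FALSE)
    }
    ord <- order(-post$posterior, post$column)
    post$column[ord][seq_len(n)]
  }
  t1 <- top_n_sites(posteriors_ab, "(A,B)")
  t2 <- top_n_sites(posteriors_cd, "(C,D)")
  common <- intersect(t1, t2)
  s1 <- setdiff(t1, common)
  s2 <- setdiff(t2, common)
  if (length(s1) == 0L || length(s2) == 0L) {
    stop("top site lists are identical; the permutation pool is empty",
         call. = FALSE)
  }
  list(sites_e1 = sort(s1), sites_e2 = sort(s2), n_common = length(common))
}

#' Spatial clustering statistic
#'
#' S = number of within-set pairs that are contact-graph edges, summed over
#' the two site sets. Large S means rate shifts on the same edge tend to
#' involve residues that are neighbours in the structure.
#'
#' @param sites_e1,sites_e2 Disjoint integer column sets.
#' @param graph A [build_contact_graph()] result.
#' @return Integer statistic, with attribute `"per_edge"` (the two
#'   contributions).
#' @export
clustering_statistic <- function(sites_e1, sites_e2, graph) {
  if (length(intersect(sites_e1, sites_e2))) {
    stop("site sets must be disjoint", call. = FALSE)
  }
  adj <- contact_adjacency(graph)
  count_pairs <- function(s) {
    idx <- match(as.character(s), rownames(adj))
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2L) return(0L)
    sum(adj[idx, idx]) / 2L
  }
  p1 <- count_pairs(sites_e1)
  p2 <- count_pairs(sites_e2)
  structure(as.integer(p1 + p2), per_edge = c(e1 = p1, e2 = p2))
}

#' Consecutive-pair statistic
#'
#' Counts within-set pairs whose residues are adjacent along the chain
#' (consecutive rows of the structure map). Used to gauge how much of the
#' clustering signal is mere sequence adjacency.
#'
#' @param sites_e1,sites_e2 Disjoint integer column sets.
#' @param structmap A [map_alignment_to_structure()] result.
#' @return Integer statistic with attribute `"per_edge"`.
#' @export
consecutive_statistic <- function(sites_e1, sites_e2, structmap) {
  pos <- stats::setNames(seq_len(nrow(structmap)),
                         as.character(structmap$column))
  count_adjacent <- function(s) {
    p <- pos[as.character(s)]
    p <- sort(p[!is.na(p)])
    if (length(p) < 2L) return(0L)
    sum(diff(p) == 1L)
  }
  p1 <- count_adjacent(sites_e1)
  p2 <- count_adjacent(sites_e2)
  structure(as.integer(p1 + p2), per_edge = c(e1 = p1, e2 = p2))
}

#' Permutation test for spatial clustering of type I sites
#'
#' Conditions on the observed 2n' typed sites and permutes only their edge
#' assignments: null draws are random equipartitions of the pooled sites
#' into two labelled groups of size n'. When the pool size is at most
#' `exact_threshold` all C(2n', n') assignments are enumerated and the exact
#' upper-tail proportion is reported; otherwise Monte-Carlo sampling with the
#' plus-one correction p = (1 + #\{S_perm >= S_obs\}) / (1 + n_perm) is used.
#'
#' @param sites_e1,sites_e2 Equal-size disjoint column sets
#'   (see [select_quartet_sites()]).
#' @param graph A [build_contact_graph()] result.
#' @param n_perm Monte-Carlo draws (default 100000).
#' @param seed Integer seed for the Monte-Carlo mode.
#' @param exact_threshold Pool size at or below which enumeration replaces
#'   sampling (default 12).
#' @return Object of class `cluster_test`: `statistic`, `p_value`, `mode`,
#'   `per_edge`, `pool_size`, `n_perm`, `seed`, and the null draws
#'   (`null_stats`). Has a [generics::tidy()] method and an
#'   [ggplot2::autoplot()] method.
#' @export
clustering_permutation_test <- function(sites_e1, sites_e2, graph,
                                        n_perm = 1e5, seed = NULL,
                                        exact_threshold = 12L) {
  stopifnot(length(sites_e1) == length(sites_e2), n_perm >= 1)
  obs <- clustering_statistic(sites_e1, sites_e2, graph)
  pool <- c(sites_e1, sites_e2)
  k <- length(sites_e1)
  adj <- contact_adjacency(graph)
  idx <- match(as.character(pool), rownames(adj))
  # pairs unmapped to the structure never contribute
  sub <- matrix(FALSE, length(pool), length(pool))
  ok <- !is.na(idx)
  sub[ok, ok] <- adj[idx[ok], idx[ok], drop = FALSE]
  stat_of <- function(sel) {
    (sum(sub[sel, sel]) + sum(sub[-sel, -sel])) / 2L
  }

  if (length(pool) <= exact_threshold) {
    assignments <- utils::combn(length(pool), k, simplify = FALSE)
    null_stats <- vapply(assignments, stat_of, numeric(1))
    p <- mean(null_stats >= obs)
    mode <- "exact"
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      stat_of(sample.int(length(pool), k))
    }, numeric(1))
    p <- (1 + sum(null_stats >= obs)) / (1 + n_perm)
    mode <- "monte-carlo"
  }
  structure(
    list(statistic = as.integer(obs),
         p_value = p,
         mode = mode,
         per_edge = attr(obs, "per_edge"),
         pool_size = length(pool),
         n_perm = if (mode == "monte-carlo") n_perm else length(null_stats),
         seed = seed,
         null_stats = null_stats),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> S = ", x$statistic,
      " (edges: ", paste(x$per_edge, collapse = " + "), ")",
      sprintf("; p = %.4g (%s, pool %d)\n", x$p_value, x$mode, x$pool_size),
      sep = "")
  invisible(x)
}
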