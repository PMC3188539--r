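# Latent structural characters: connected components of typed columns on the
# contact graph, their per-clade profiles, and character-state assignment.

#' Find latent structural characters
#'
#' An LSC is a maximal connected subgraph of the typed-column contact graph
#' with at least two members, at least one of which is type I or type II.
#' When `site_calls` covers several clade pairs, a column's class is its
#' strongest call across pairs (typeII > typeI > type0). LSCs are numbered by
#' their smallest member column, so the ordering is deterministic.
#'
#' @param site_calls A [classify_sites()] table (one or several clade pairs).
#' @param graph A [build_contact_graph()] result whose vertices cover the
#'   typed columns.
#' @return Tibble with one row per LSC member: `lsc` (integer id), `column`,
#'   `class`, `resno`, `chain`, `aa_struct`.
#' @export
find_lscs <- function(site_calls, graph) {
  strength <- c(typeII = 3L, typeI = 2L, type0 = 1L, none = 0L)
  calls <- site_calls |>
    dplyr::mutate(.s = strength[as.character(.data$class)]) |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(.s = max(.data$.s), .groups = "drop") |>
    dplyr::filter(.data$.s > 0L) |>
    dplyr::mutate(class = names(strength)[match(.data$.s, strength)])

  vn <- as.integer(igraph::V(graph$graph)$name)
  typed <- intersect(calls$column, vn)
  if (length(typed) == 0L) {
    return(tibble::tibble(lsc = integer(), column = integer(),
                          class = character(), resno = integer(),
                          chain = character(), aa_struct = character()))
  }
  sub <- igraph::induced_subgraph(graph$graph,
                                  match(typed, vn))
  comp <- igraph::components(sub)
  memb <- split(as.integer(igraph::V(sub)$name), comp$membership)

  keep <- Filter(function(cols) {
    if (length(cols) < 2L) return(FALSE)
    cls <- calls$class[match(cols, calls$column)]
    any(cls %in% c("typeI", "typeII"))
  }, memb)
  if (length(keep) == 0L) {
    return(tibble::tibble(lsc = integer(), column = integer(),
                          class = character(), resno = integer(),
                          chain = character(), aa_struct = character()))
  }
  keep <- keep[order(vapply(keep, min, numeric(1)))]
  rows <- lapply(seq_along(keep), function(i) {
    cols <- sort(keep[[i]])
    sm <- graph$structmap[match(cols, graph$structmap$column), ]
    tibble::tibble(
      lsc = i,
      column = cols,
      class = calls$class[match(cols, calls$column)],
      resno = sm$resno,
      chain = sm$chain,
      aa_struct = sm$aa_struct
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-clade consensus profiles of LSC members
#'
#' @param lscs A [find_lscs()] table.
#' @param aln An `msa` object.
#' @param partition Clade map tibble.
#' @return Tibble with `lsc`, `clade`, `column`, `consensus`, `frequency`
#'   (consensus residue frequency among clade rows), `gap_fraction`.
#' @export
lsc_state_profiles <- function(lscs, aln, partition) {
  clades <- sort(unique(partition$clade))
  rows <- lapply(clades, function(cl) {
    cons <- consensus_residues(aln, clade_leaves(partition, cl))
    tibble::tibble(
      lsc = lscs$lsc,
      clade = cl,
      column = lscs$column,
      consensus = cons$residue[lscs$column],
      frequency = cons$frequency[lscs$column],
      gap_fraction = cons$gap_fraction[lscs$column]
    )
  })
  dplyr::bind_rows(rows)
}

#' Assign per-clade character states for one LSC
#'
#' Default rule: two clades share a state iff (1) their conservation status
#' (consensus frequency at or above `freq_threshold` vs below) matches at
#' every member column, and (2) wherever both are conserved the consensus
#' residues fall in the same radical property group. States are the resulting
#' equivalence classes, labelled 1, 2, ... in order of first appearance over
#' alphabetically sorted clades. If the similarity relation is intransitive
#' the function falls back to single-linkage grouping and flags the
#' character. A clade whose member columns are all gapped gets a missing
#' state (`NA`). A manual `override` (named vector clade -> state) replaces
#' the rule entirely, so published assignments can be encoded verbatim.
#'
#' @param profiles A [lsc_state_profiles()] table.
#' @param lsc_id Which LSC to assign.
#' @param freq_threshold Consensus frequency defining "conserved"
#'   (default 0.7).
#' @param override Optional named vector of states.
#' @return Tibble with `lsc`, `clade`, `state` (integer, `NA` = missing) and
#'   attribute `"intransitive"`.
#' @export
assign_states <- function(profiles, lsc_id, freq_threshold = 0.7,
                          override = NULL) {
  pf <- profiles[profiles$lsc == lsc_id, ]
  clades <- sort(unique(pf$clade))
  if (!is.null(override)) {
    return(tibble::tibble(lsc = lsc_id, clade = clades,
                          state = as.integer(override[clades])))
  }
  per_clade <- lapply(clades, function(cl) {
    p <- pf[pf$clade == cl, ]
    p <- p[order(p$column), ]
    list(
      missing = all(p$gap_fraction >= 1),
      conserved = !is.na(p$consensus) & p$frequency >= freq_threshold,
      group = radical_group_of(p$consensus)
    )
  })
  names(per_clade) <- clades

  similar <- function(a, b) {
    if (a$missing || b$missing) return(FALSE)
    if (!identical(a$conserved, b$conserved)) return(FALSE)
    both <- a$conserved & b$conserved
    all(a$group[both] == b$group[both])
  }
  n <- length(clades)
  sim <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) sim[i, j] <- sim[j, i] <- similar(per_clade[[i]],
                                                   per_clade[[j]])
    }
  }
  diag(sim) <- TRUE

  # check transitivity; fall back to single linkage if violated
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  intransitive <- FALSE
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (!all(sim[idx, idx])) intransitive <- TRUE
  }

  state <- integer(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    if (per_clade[[i]]$missing) { state[i] <- NA_integer_; next }
    prev <- match(comp[i], seen)
    if (is.na(prev)) {
      seen <- c(seen, comp[i])
      prev <- length(seen)
    }
    state[i] <- prev
  }
  out <- tibble::tibble(lsc = lsc_id, clade = clades, state = state)
  attr(out, "intransitive") <- intransitive
  if (intransitive) {
    warning("LSC ", lsc_id, ": intransitive similarity; ",
            "single-linkage grouping used", call. = FALSE)
  }
  out
}

#' Character matrix over all LSCs
#'
#' Applies [assign_states()] to every LSC and assembles the clade x character
#' state table used for parsimony.
#'
#' @param profiles A [lsc_state_profiles()] table.
#' @param freq_threshold Passed to [assign_states()].
#' @param overrides Optional named list `lsc id -> named state vector`.
#' @return Tibble with `clade` plus one integer column per LSC
#'   (`lsc1`, `lsc2`, ...; `NA` = missing state).
#' @export
character_matrix <- function(profiles, freq_threshold = 0.7,
                             overrides = NULL) {
  ids <- sort(unique(profiles$lsc))
  cols <- lapply(ids, function(id) {
    ov <- overrides[[as.character(id)]]
    assign_states(profiles, id, freq_threshold = freq_threshold,
                  override = ov)
  })
  out <- tibble::tibble(clade = sort(unique(profiles$clade)))
  for (i in seq_along(ids)) {
    st <- cols[[i]]
    out[[paste0("lsc", ids[i])]] <-
      st$state[match(out$clade, st$clade)]
  }
  out
}

#' Write a character matrix as TSV ("?" for missing)
#' @param cm A [character_matrix()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(cm, path) {
  df <- as.data.frame(cm)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "?", as.character(df[[j]]))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
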