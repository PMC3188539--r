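# Residue contact graph over structure-mapped alignment columns.

#' Build a contact graph over typed alignment columns
#'
#' Vertices are the typed columns that map to structure residues; an edge
#' joins two columns whose representative atoms lie within `threshold`
#' angstroms (default 4, alpha-carbons). With `atom_mode = "min"` (available
#' when the structure was read in that mode) the minimum distance over all
#' atoms of the two residues is used instead.
#'
#' @param structmap A [map_alignment_to_structure()] result.
#' @param typed_columns Integer vector of alignment columns to use as
#'   vertices. Unmapped columns are dropped with a warning (gapped in the
#'   reference row).
#' @param threshold Contact distance in angstroms (default 4.0).
#' @param atom_mode `"representative"` (default: whatever atom the structure
#'   was read with) or `"min"`.
#' @return Object of class `contact_graph`: list with the `igraph` graph
#'   (vertex names are column indices), `threshold`, `atom_mode`, and the
#'   structure map rows used.
#' @export
build_contact_graph <- function(structmap, typed_columns, threshold = 4.0,
                                atom_mode = c("representative", "min")) {
  atom_mode <- match.arg(atom_mode)
  typed_columns <- sort(unique(as.integer(typed_columns)))
  mapped <- structmap$column
  lost <- setdiff(typed_columns, mapped)
  if (length(lost)) {
    warning(length(lost), " typed column(s) unmapped to the structure ",
            "and dropped", call. = FALSE)
    typed_columns <- intersect(typed_columns, mapped)
  }
  rows <- structmap[match(typed_columns, structmap$column), ]
  n <- nrow(rows)
  if (atom_mode == "min") {
    atoms <- attr(structmap, "atoms")
    if (is.null(atoms)) {
      stop("structure was not read with atom_mode = 'min'", call. = FALSE)
    }
    d <- matrix(Inf, n, n)
    key <- paste(rows$resno, rows$insert)
    akey <- paste(atoms$resno, atoms$insert)
    coords <- lapply(key, function(k) {
      as.matrix(atoms[akey == k, c("x", "y", "z")])
    })
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        dd <- pairwise_min_dist(coords[[i]], coords[[j]])
        d[i, j] <- dd; d[j, i] <- dd
      }
    }
  } else {
    d <- as.matrix(stats::dist(rows[, c("x", "y", "z")]))
  }
  adj <- d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(typed_columns)
  structure(
    list(graph = g, threshold = threshold, atom_mode = atom_mode,
         structmap = rows),
    class = "contact_graph"
  )
}

pairwise_min_dist <- function(a, b) {
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> ", igraph::vcount(x$graph), " vertices, ",
      igraph::ecount(x$graph), " edges; threshold ", x$threshold,
      " A (", x$atom_mode, ")\n", sep = "")
  invisible(x)
}

#' Contact edges as a tibble
#'
#' @param graph A [build_contact_graph()] result.
#' @return Tibble with columns `column_i`, `column_j` (`column_i < column_j`).
#' @export
contact_edges <- function(graph) {
  e <- igraph::as_edgelist(graph$graph)
  if (nrow(e) == 0L) {
    return(tibble::tibble(column_i = integer(), column_j = integer()))
  }
  i <- as.integer(e[, 1]); j <- as.integer(e[, 2])
  tibble::tibble(column_i = pmin(i, j), column_j = pmax(i, j)) |>
    dplyr::arrange(.data$column_i, .data$column_j)
}

# Dense logical adjacency over the graph's columns (names kept).
contact_adjacency <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph$graph, sparse = FALSE) > 0
  dimnames(a) <- list(igraph::V(graph$graph)$name,
                      igraph::V(graph$graph)$name)
  a
}
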