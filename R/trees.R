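# Tree input and validation. Trees are ape::phylo; branch lengths are
# expected substitutions per site and are required by the counting and
# rate-uniformity machinery.

#' Read a Newick tree with branch lengths
#'
#' @param path Newick file.
#' @return An `ape::phylo` with validated non-negative branch lengths.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  validate_tree(tr)
}

#' Validate a phylogenetic tree for counting
#'
#' @param tr An `ape::phylo`.
#' @return `tr`, invisibly returned after checks.
#' @export
validate_tree <- function(tr) {
  if (is.null(tr)) stop("could not parse tree", call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree has missing branch lengths (lengths are required)",
         call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  tr
}

#' Total tree length
#'
#' @param tr An `ape::phylo` with branch lengths.
#' @return Sum of branch lengths (substitutions per site).
#' @export
tree_length <- function(tr) sum(validate_tree(tr)$edge.length)

#' Write a tree to Newick
#' @param tr An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}
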