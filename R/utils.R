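# Shared constants and small helpers.

# Canonical amino-acid alphabet, lexicographic one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters that are not one of the 20 standard residues; normalised to "X"
# on read and treated as gaps when counting substitutions.
AA_AMBIGUOUS <- c("B", "Z", "J", "U", "O", "X")

#' Radical amino-acid property groups
#'
#' The four property groups used to decide whether a fixed difference between
#' two clades is *radical*: charge positive (K, R, H), charge negative (D, E),
#' hydrophilic (S, T, N, Q, C, G, P) and hydrophobic (A, I, L, M, F, W, V, Y).
#' The groups are disjoint and cover all 20 residues.
#'
#' @return Named list of four character vectors.
#' @export
#' @examples
#' radical_groups()
radical_groups <- function() {
  list(
    positive    = c("K", "R", "H"),
    negative    = c("D", "E"),
    hydrophilic = c("S", "T", "N", "Q", "C", "G", "P"),
    hydrophobic = c("A", "I", "L", "M", "F", "W", "V", "Y")
  )
}

#' Radical group membership of residues
#'
#' @param aa Character vector of one-letter residue codes.
#' @return Character vector of group names (`NA` for gaps/unknown letters).
#' @export
#' @examples
#' radical_group_of(c("K", "D", "A", "-"))
radical_group_of <- function(aa) {
  groups <- radical_groups()
  lookup <- stats::setNames(
    rep(names(groups), lengths(groups)),
    unlist(groups, use.names = FALSE)
  )
  out <- unname(lookup[toupper(aa)])
  out
}

# Encode residues as integers 1..20; gap / unknown -> 0L.
aa_encode <- function(ch) {
  idx <- match(ch, AA20)
  idx[is.na(idx)] <- 0L
  idx
}

aa_decode <- function(idx) {
  out <- rep(NA_character_, length(idx))
  ok <- idx >= 1L & idx <= 20L
  out[ok] <- AA20[idx[ok]]
  out
}

# log(sum(exp(x))) along rows of a two-column matrix, stable.
log_add <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# Area under the ROC curve for scores against binary truth (rank statistic).
auroc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- scores[truth]
  neg <- scores[!truth]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
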