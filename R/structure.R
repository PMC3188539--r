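# Reference-structure input and alignment-column-to-residue mapping.

#' Read residue coordinates from a PDB file
#'
#' Parses a single chain of the first model and returns one representative
#' coordinate per resolved residue. Alternate locations are resolved to the
#' highest-occupancy atom. With `atom_mode = "CB"` glycines fall back to CA.
#' With `atom_mode = "min"` the representative coordinate is the CA, but all
#' heavy-atom coordinates are retained (attribute `"atoms"`) so contact
#' detection can use the minimum inter-atomic distance.
#'
#' @param path PDB file.
#' @param chain Chain identifier (single character).
#' @param atom_mode One of `"CA"`, `"CB"`, `"min"`.
#' @return Tibble of class `residue_coords` with columns `chain`, `resno`,
#'   `insert`, `aa` (one-letter), `x`, `y`, `z`, in chain order.
#' @export
read_structure <- function(path, chain, atom_mode = c("CA", "CB", "min")) {
  atom_mode <- match.arg(atom_mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not present in ", path,
                           call. = FALSE)
  # resolve altloc: keep highest occupancy per (resno, insert, atom name),
  # then restore chain (file) order
  at$insert[is.na(at$insert)] <- ""
  at$.ord <- seq_len(nrow(at))
  key <- paste(at$resno, at$insert, at$elety)
  at <- at[order(key, -at$o, at$.ord), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  at <- at[order(at$.ord), , drop = FALSE]

  res_key <- paste(at$resno, at$insert)
  res_order <- unique(res_key)
  want <- switch(atom_mode, CA = "CA", CB = "CB", min = "CA")

  rows <- lapply(res_order, function(k) {
    sub <- at[res_key == k, , drop = FALSE]
    rep_atom <- sub[sub$elety == want, , drop = FALSE]
    if (nrow(rep_atom) == 0L && atom_mode == "CB") {
      rep_atom <- sub[sub$elety == "CA", , drop = FALSE]  # glycine fallback
    }
    if (nrow(rep_atom) == 0L) return(NULL)
    rep_atom[1L, c("chain", "resno", "insert", "resid", "x", "y", "z")]
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " residue(s) lacking a ", want,
            " atom were skipped", call. = FALSE)
  }
  df <- do.call(rbind, rows[!dropped])
  if (is.null(df) || nrow(df) == 0L) {
    stop("no residues with a ", want, " atom in chain '", chain, "'",
         call. = FALSE)
  }
  out <- tibble::tibble(
    chain = df$chain,
    resno = as.integer(df$resno),
    insert = df$insert,
    aa = unname(bio3d::aa321(df$resid)),
    x = df$x, y = df$y, z = df$z
  )
  if (any(!is.finite(c(out$x, out$y, out$z)))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  class(out) <- c("residue_coords", class(out))
  if (atom_mode == "min") {
    attr(out, "atoms") <- tibble::tibble(
      resno = as.integer(at$resno), insert = at$insert,
      x = at$x, y = at$y, z = at$z
    )
  }
  attr(out, "atom_mode") <- atom_mode
  out
}

#' Map alignment columns to structure residues
#'
#' The k-th non-gap column of the reference row maps to the k-th residue
#' record; gap columns stay unmapped. If the ungapped reference row and the
#' structure sequence differ in length, every offset of the shorter within
#' the longer is scanned and the offset with the fewest residue mismatches is
#' used. Residue identity mismatches are tolerated up to `max_mismatch`
#' (crystallised constructs often differ from database sequences) and
#' reported via a message.
#'
#' @param aln An `msa` object.
#' @param ref_id Sequence id of the reference row.
#' @param coords A [read_structure()] result.
#' @param max_mismatch Tolerated mismatch fraction over the aligned overlap
#'   (default 0.05).
#' @return Tibble of class `structure_map` with columns `column`, `chain`,
#'   `resno`, `insert`, `aa_aln`, `aa_struct`, `x`, `y`, `z`. Injective on
#'   mapped columns; column and residue order increase together.
#' @export
map_alignment_to_structure <- function(aln, ref_id, coords,
                                       max_mismatch = 0.05) {
  if (!ref_id %in% msa_ids(aln)) {
    stop("reference id '", ref_id, "' not in alignment", call. = FALSE)
  }
  row <- unclass(aln)[ref_id, ]
  nongap_cols <- which(!(row %in% c("-", "X")))
  if (length(nongap_cols) == 0L) {
    stop("reference row is entirely gaps", call. = FALSE)
  }
  u <- row[nongap_cols]          # ungapped reference residues
  r <- coords$aa                 # structure residues, chain order
  nu <- length(u); nr <- length(r)

  # scan offsets of the shorter sequence within the longer
  if (nu <= nr) {
    offsets <- 0:(nr - nu)
    mism <- vapply(offsets, function(o) sum(u != r[(1:nu) + o]), integer(1))
    best <- offsets[which.min(mism)]
    ref_idx <- seq_len(nu); res_idx <- ref_idx + best
  } else {
    offsets <- 0:(nu - nr)
    mism <- vapply(offsets, function(o) sum(u[(1:nr) + o] != r), integer(1))
    best <- offsets[which.min(mism)]
    res_idx <- seq_len(nr); ref_idx <- res_idx + best
  }
  frac <- min(mism) / length(res_idx)
  if (frac > max_mismatch) {
    stop("reference row and structure sequence disagree at ",
         round(100 * frac, 1), "% of overlapping positions\n",
         "alignment: ", paste(u, collapse = ""), "\n",
         "structure: ", paste(r, collapse = ""), call. = FALSE)
  }
  if (min(mism) > 0) {
    message(min(mism), " residue identity mismatch(es) between alignment ",
            "reference row and structure (tolerated)")
  }
  out <- tibble::tibble(
    column = nongap_cols[ref_idx],
    chain = coords$chain[res_idx],
    resno = coords$resno[res_idx],
    insert = coords$insert[res_idx],
    aa_aln = u[ref_idx],
    aa_struct = coords$aa[res_idx],
    x = coords$x[res_idx], y = coords$y[res_idx], z = coords$z[res_idx]
  )
  class(out) <- c("structure_map", class(out))
  attr(out, "atoms") <- attr(coords, "atoms")
  attr(out, "atom_mode") <- attr(coords, "atom_mode")
  out
}
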