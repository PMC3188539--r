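# Multiple sequence alignment container and readers.

#' Construct a protein multiple sequence alignment
#'
#' The alignment is stored as a character matrix (one row per sequence, one
#' column per aligned position; columns are 1-based throughout). Residues are
#' upper-cased; `.` is converted to the gap symbol `-`; ambiguous letters
#' (B, Z, J, U, O) are normalised to `X`, which is treated as a gap when
#' substitutions are counted.
#'
#' @param seqs Named character vector of (gapped) sequences, or a character
#'   matrix with row names.
#' @return An object of class `msa`.
#' @export
#' @examples
#' new_msa(c(a = "AC-D", b = "ACED"))
new_msa <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
    ids <- rownames(m)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[lens != stats::median(lens)]
      stop("alignment rows have unequal lengths; offending id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- ids
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- toupper(m)
  m[m == "."] <- "-"
  m[m %in% AA_AMBIGUOUS] <- "X"
  bad <- !(m %in% c(AA20, "-", "X"))
  if (any(bad)) {
    stop("unexpected characters in alignment: ",
         paste(unique(m[bad]), collapse = " "), call. = FALSE)
  }
  structure(m, class = c("msa", "matrix"))
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An `msa` object.
#' @return Integer column count.
#' @export
n_cols <- function(aln) ncol(aln)

#' Sequence ids of an alignment
#' @param aln An `msa` object.
#' @return Character vector of ids.
#' @export
msa_ids <- function(aln) rownames(aln)

#' Read a protein multiple sequence alignment
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return An [new_msa()] object; columns indexed 1-based.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    seqs <- stats::setNames(unlist(lapply(recs, as.character)), names(recs))
  } else {
    a <- seqinr::read.alignment(path, format = "clustal")
    seqs <- stats::setNames(unlist(a$seq), a$nam)
  }
  new_msa(toupper(seqs))
}

#' Write an alignment to FASTA
#'
#' @param aln An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Read a leaf-to-clade map
#'
#' Tab-separated file with columns `sequence_id` and `clade` (header required).
#'
#' @param path File path.
#' @return Tibble with columns `sequence_id`, `clade`.
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "clade") %in% names(df))) {
    stop("clade map needs columns 'sequence_id' and 'clade'", call. = FALSE)
  }
  tibble::as_tibble(df[, c("sequence_id", "clade")])
}

#' Validate a clade partition against an alignment
#'
#' @param partition Tibble with `sequence_id`, `clade`.
#' @param aln An `msa` object.
#' @param min_clade_size Minimum leaves per clade (default 4).
#' @return `partition`, invisibly, or an error.
#' @export
validate_partition <- function(partition, aln, min_clade_size = 4L) {
  missing <- setdiff(partition$sequence_id, msa_ids(aln))
  if (length(missing)) {
    stop("clade map leaves absent from alignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sizes <- table(partition$clade)
  small <- names(sizes)[sizes < min_clade_size]
  if (length(small)) {
    stop("clades below the size floor (", min_clade_size, "): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  invisible(partition)
}

# Leaf ids of one clade.
clade_leaves <- function(partition, clade) {
  partition$sequence_id[partition$clade == clade]
}
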