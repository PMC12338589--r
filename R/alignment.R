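#' Amino-acid alignment as a character matrix
#'
#' Alignments are stored as plain character matrices: one row per sequence
#' (rownames are the sequence ids), one column per site, single upper-case
#' residue characters with "-" for gaps. Non-standard residue codes
#' (B, Z, X, U, O, J) carry no usable frequency information and are treated
#' as gaps by all column statistics.
#'
#' @param x named character vector of equal-length residue strings, or a
#'   character matrix already in row/site layout.
#' @return character matrix of class `aa_alignment`.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    n <- nchar(x)
    if (length(unique(n)) != 1L) stop("all rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (anyDuplicated(rownames(m))) stop("duplicated row ids")
  class(m) <- c("aa_alignment", class(m))
  m
}

#' @rdname as_alignment
#' @param path FASTA file path.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  as_alignment(stats::setNames(as.character(s), names(s)))
}

#' @rdname as_alignment
#' @param aln an `aa_alignment`.
#' @export
write_alignment <- function(aln, path) {
  s <- Biostrings::AAStringSet(apply(unclass(aln), 1, paste, collapse = ""))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Shannon information content of an alignment column
#'
#' Information is the difference between the maximum attainable entropy over
#' the 20 amino acids, log2(20), and the Shannon entropy of the column's
#' residue frequency distribution. Frequencies are taken over non-gap
#' residues only (no pseudocounts; 0*log(0) is 0); a column that is pure
#' apart from gaps therefore scores the full log2(20) ~ 4.3219 bits, and an
#' all-gap column is defined to carry 0 bits.
#'
#' @param column character vector of single residue characters.
#' @return information content in bits.
#' @examples
#' column_information(rep("A", 10))            # 4.3219
#' column_information(c(rep("A", 5), rep("W", 5)))  # 3.3219
#' @export
column_information <- function(column) {
  if (length(column) == 0L) stop("empty column")
  res <- toupper(column)
  res <- res[res %in% AA20]
  if (length(res) == 0L) return(0)
  p <- table(res) / length(res)
  h <- -sum(p * log2(p))
  log2(20) - h
}

#' Trim alignment columns by information content
#'
#' Keeps exactly the columns whose Shannon information content strictly
#' exceeds `min_bits`, preserving column order and the full row set. The
#' pipeline trims at 0.15 bits before tree reconstruction and at 0.2 bits
#' for profile construction.
#'
#' @param aln an `aa_alignment`.
#' @param min_bits non-negative threshold in bits (default 0.15).
#' @return trimmed `aa_alignment`; a zero-column alignment (with a warning)
#'   when no column passes.
#' @export
trim_alignment <- function(aln, min_bits = 0.15) {
  stopifnot(min_bits >= 0)
  m <- unclass(aln)
  info <- apply(m, 2, column_information)
  keep <- info > min_bits
  if (!any(keep)) warning("no columns exceed ", min_bits, " bits")
  out <- m[, keep, drop = FALSE]
  class(out) <- c("aa_alignment", class(out))
  attr(out, "column_information") <- info[keep]
  out
}
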