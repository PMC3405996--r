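#' Construct an aligned sequence set
#'
#' A light container for aligned nucleotide sequences: a character matrix of
#' single upper-case characters over `A,C,G,T,-,N`, one row per sequence, with
#' unique row labels. All downstream distance, classification and phylogeny
#' functions consume this class.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix of single characters (rows = sequences).
#' @param labels unique sequence identifiers; defaults to names of `seqs`.
#' @return an object of class `alignment`: a character matrix with row names.
#' @examples
#' aln <- alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nchar_alignment(aln)
#' @export
alignment <- function(seqs, labels = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(labels)) labels <- rownames(m)
  } else {
    if (is.null(labels)) labels <- names(seqs)
    if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("all sequences must have equal (aligned) length")
    m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  }
  m[] <- toupper(m)
  if (anyDuplicated(labels)) stop("sequence labels must be unique")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("unsupported alignment characters: ", paste(bad, collapse = ", "))
  rownames(m) <- labels
  class(m) <- c("alignment", class(m))
  m
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 8)
  for (lb in show) {
    s <- paste(x[lb, seq_len(min(ncol(x), 50))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", lb, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 8) cat(sprintf("  ... and %d more\n", nrow(x) - 8))
  invisible(x)
}

#' Number of alignment columns
#' @param aln an [alignment()].
#' @return integer site count.
#' @export
nchar_alignment <- function(aln) ncol(aln)

#' Extract sequences as strings
#' @param aln an [alignment()].
#' @return named character vector of sequence strings.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()]; all sequences must have equal
#' length.
#'
#' @param path FASTA file path.
#' @return an [alignment()].
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  chars <- lapply(as.character(dna), toupper)
  if (length(unique(lengths(chars))) != 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  alignment(do.call(rbind, chars), labels = names(dna))
}

#' Write an alignment to FASTA
#' @param aln an [alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- alignment_strings(aln)
  out <- character(2L * length(ss))
  out[c(TRUE, FALSE)] <- paste0(">", names(ss))
  out[c(FALSE, TRUE)] <- ss
  writeLines(out, path)
  invisible(path)
}
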