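#' Read a reference FASTA
#'
#' Sequence names are taken from the header line up to the first whitespace
#' and sequences are uppercased.
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a reference FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}
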