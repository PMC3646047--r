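`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#' @param x single nucleotide string
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# collapse character vector
cc <- function(x) paste0(x, collapse = "")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Write a data frame as a tab-separated file
#' @param x data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file of nucleotide sequences
#' @param path FASTA file
#' @return named character vector
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a FASTA file of protein sequences
#' @param path FASTA file
#' @return named character vector
#' @export
read_fasta_protein <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @param type "dna" or "protein"
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
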