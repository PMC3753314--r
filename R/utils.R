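#' @useDynLib ampdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils write.table read.delim combn
NULL

#' Reverse complement of nucleotide strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N and IUPAC
#'   ambiguity codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalise sequences on ingest: uppercase, RNA U -> T
clean_bases <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# deterministic ordering used everywhere: descending reads, then
# lexicographic sequence
order_by_abundance <- function(reads, seqs) {
  order(-reads, seqs, method = "radix")
}

write_tsv <- function(df, file) {
  write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
}
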