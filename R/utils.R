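`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x A single nucleotide string.
#' @return The reverse complement, as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the file.
#' @export
tirmap_extdata <- function(file) {
  p <- system.file("extdata", file, package = "tirmap", mustWork = TRUE)
  p
}

# uppercase and basic alphabet sanity; IUPAC ambiguity codes are kept and
# later scored as mismatches by the aligners
clean_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(which(bad), collapse = ", "))
  }
  x
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
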