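## Small shared helpers: all coordinates in the package are 1-based and
## intervals on graph nodes are half-open [a, b).

GAP <- "-"
DNA_CHARS <- c("A", "C", "G", "T", "N")

#' Remove gap characters from a gapped sequence
#'
#' @param x character vector of (possibly gapped) sequences.
#' @return character vector with all `-` characters removed.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Read a reference that may be a plain string, a DNAStringSet, or a FASTA
## path; returns a named character vector of sequences.
load_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fna|fa\\.gz|fasta\\.gz)$", x, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (is(x, "XStringSet")) {
    out <- as.character(x)
    ## FASTA descriptions: keep the first word as the sequence name
    if (!is.null(names(out))) names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x)) return(toupper(x))
  stop("cannot interpret sequence input of class ", class(x)[1L])
}

check_alphabet <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(DNA_CHARS, collapse = "")), x)
  if (any(bad)) {
    stop("unsupported allele: ", what, " contains characters outside {A,C,G,T,N}: ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  invisible(x)
}

#' Write sequences to FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] that accepts named
#' character vectors (gapped rows allowed).
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
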