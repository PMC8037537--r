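#' Sequence utilities
#'
#' The package works on the RNA alphabet (ACGU) internally. FASTA input in DNA
#' convention (T) is transparently mapped to U on read.
#'
#' @name seq-utils
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA sequences (ACGU).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_rna("GAGGUAG")
revcomp_rna <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A")[chars]
    if (anyNA(comp)) stop("non-ACGU character in sequence: ", s)
    paste(rev(unname(comp)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Complement (no reversal) of an RNA string
#' @noRd
comp_rna <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")[chars]
  paste(unname(comp), collapse = "")
}

#' Draw a random RNA sequence from a base composition
#' @noRd
random_rna <- function(len, composition = rep(0.25, 4L)) {
  if (len <= 0L) return("")
  paste(sample(RNA_BASES, len, replace = TRUE, prob = composition), collapse = "")
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U. Rejects characters outside ACGU unless
#' `allow_iupac` is TRUE (used for motif patterns).
#' @param x character vector.
#' @param allow_iupac keep IUPAC degeneracy codes.
#' @return character vector on the RNA alphabet.
#' @export
as_rna <- function(x, allow_iupac = FALSE) {
  out <- chartr("t", "u", tolower(x))
  out <- toupper(out)
  ok_chars <- if (allow_iupac) "^[ACGURYSWKMBDHVN]*$" else "^[ACGU]*$"
  bad <- !grepl(ok_chars, out)
  if (any(bad)) {
    stop("sequence contains characters outside the ",
         if (allow_iupac) "IUPAC RNA" else "ACGU",
         " alphabet: ", out[which(bad)[1L]])
  }
  out
}

#' Read a FASTA file as named RNA character vector
#'
#' DNA-convention files (T) are mapped to U on read.
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as_rna(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (RNA alphabet).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_rna <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains
rbind_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# integer encoding A=0 C=1 G=2 U=3, used by the C++ kernels
seq_to_int <- function(s) {
  if (nchar(s) == 0L) return(integer(0L))
  m <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_BASES)
  if (anyNA(m)) stop("non-ACGU character in sequence: ", s)
  m - 1L
}
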