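#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of ACGTN sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
reverse_strings <- function(x) {
  if (length(x) == 0L) return(character(0))
  reverse_strings_cpp(x)
}

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

# Validate that a sequence uses only the given alphabet; errors name the
# first offending position (1-based).
#' @noRd
check_alphabet <- function(seq, alphabet = c("A", "C", "G", "T", "N"),
                           what = "sequence") {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% alphabet)
  if (length(bad) > 0L) {
    stop2(sprintf("invalid character '%s' in %s at position %d",
                  ch[bad[1]], what, bad[1]))
  }
  invisible(TRUE)
}

# Hamming distances between each observed string and a set of same-width
# reference strings. Returns an integer matrix length(obs) x length(refs).
#' @noRd
hamming_matrix <- function(obs, refs) {
  w <- nchar(refs[1])
  n <- length(obs)
  d <- matrix(0L, n, length(refs))
  for (p in seq_len(w)) {
    oc <- substr(obs, p, p)
    for (k in seq_along(refs)) {
      d[, k] <- d[, k] + (oc != substr(refs[k], p, p))
    }
  }
  d
}

#' @noRd
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
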