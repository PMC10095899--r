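# Minimal paired-end FASTQ layer (4-line records, Phred+33). The plate
# index travels in the standard Illumina header comment `1:N:0:INDEX`;
# a separate index FASTQ is also accepted.

#' Read a FASTQ file
#'
#' Plain or gzip-compressed four-line FASTQ. The header is split into the
#' read id and the comment; an Illumina-style comment `R:F:C:INDEX` yields
#' the `index_seq` column.
#'
#' @param path FASTQ file (`.gz` handled transparently).
#' @return data.frame: `read_id`, `seq`, `qual`, `comment`, `index_seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop2(sprintf("%s: truncated FASTQ (%d lines, not a multiple of 4)",
                  path, length(lines)))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@"))
    stop2(sprintf("%s: malformed FASTQ header line", path))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0L)
    stop2(sprintf("%s: record %d: sequence and quality lengths differ",
                  path, bad[1]))
  hdr <- sub("^@", "", hdr)
  sp <- regexpr(" ", hdr, fixed = TRUE)
  read_id <- ifelse(sp > 0L, substr(hdr, 1L, sp - 1L), hdr)
  comment <- ifelse(sp > 0L, substr(hdr, sp + 1L, nchar(hdr)), "")
  index_seq <- ifelse(grepl("^[0-9]+:[YN]:[0-9]+:[ACGTN+]+$", comment),
                      sub("^.*:", "", comment), NA_character_)
  data.frame(read_id = read_id, seq = seq, qual = qual, comment = comment,
             index_seq = index_seq, stringsAsFactors = FALSE)
}

#' Read paired FASTQ files into a pair table
#'
#' @param r1,r2 Mate 1 / mate 2 FASTQ paths.
#' @param index_fastq Optional companion index-read FASTQ whose sequences
#'   override any header-derived index.
#' @return data.frame: `read_id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   `index_seq`.
#' @export
read_fastq_pairs <- function(r1, r2, index_fastq = NULL) {
  a <- read_fastq(r1)
  b <- read_fastq(r2)
  if (nrow(a) != nrow(b) || !all(a$read_id == b$read_id))
    stop2("mate files are not in matching order")
  idx <- a$index_seq
  if (!is.null(index_fastq)) {
    i <- read_fastq(index_fastq)
    if (nrow(i) != nrow(a)) stop2("index FASTQ length mismatch")
    idx <- i$seq
  }
  data.frame(read_id = a$read_id, seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual, index_seq = idx,
             stringsAsFactors = FALSE)
}

#' @noRd
write_fastq_records <- function(ids, seqs, quals, comments, path) {
  hdr <- ifelse(nzchar(comments), paste0("@", ids, " ", comments),
                paste0("@", ids))
  out <- as.vector(rbind(hdr, seqs, "+", quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write a pair table to R1/R2 FASTQ files
#'
#' The plate index is written into the Illumina header comment
#' (`1:N:0:INDEX` / `2:N:0:INDEX`). Records are exact copies of the
#' in-memory pairs; nothing is trimmed.
#'
#' @param pairs Pair data.frame.
#' @param r1,r2 Output paths (`.gz` for compressed output).
#' @return Invisibly, `c(r1, r2)`.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  idx <- ifelse(is.na(pairs$index_seq), "N", pairs$index_seq)
  write_fastq_records(pairs$read_id, pairs$seq1, pairs$qual1,
                      paste0("1:N:0:", idx), r1)
  write_fastq_records(pairs$read_id, pairs$seq2, pairs$qual2,
                      paste0("2:N:0:", idx), r2)
  invisible(c(r1, r2))
}
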