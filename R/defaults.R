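# Default design constants for a synthetic 211-bp amplicon screen.
#
# The reference amplicon is synthetic: a fixed random backbone carrying the
# two published ICS1 guide protospacers (pEF016, pEF017) with NGG PAMs, laid
# out so the two blunt cut sites fall 72 bp apart -- the geometry of a
# two-site single-amplicon screen. Primer and index sequences are likewise
# synthetic stand-ins (the original oligo table is not public) and are
# validated by the same rules any user-supplied design must pass.

.SYNTHETIC_AMPLICON <- paste0(
  "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTC",
  "AATCAATTGCTCCGATTTGC", "TGG",          # pEF016 protospacer + PAM, cut at 57
  "CCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATA",
  "TTCTCTCGTCGCAGTGACGT", "AGG",          # pEF017 protospacer + PAM, cut at 129
  "TTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTC"
)

# Published guide protospacers, kept as package fixtures.
#' Example guide protospacer sequences
#'
#' Two 20-nt SpCas9 protospacers used as fixtures throughout the package;
#' both are embedded in [default_reference()] adjacent to NGG PAMs.
#' @return Named character vector of length 2.
#' @export
example_guides <- function() {
  c(pEF016 = "AATCAATTGCTCCGATTTGC",
    pEF017 = "TTCTCTCGTCGCAGTGACGT")
}

#' Construct an amplicon reference
#'
#' @param name Reference name.
#' @param seq Uppercase ACGT amplicon sequence (typically 200-300 bp).
#' @param target_windows Two-column matrix of 0-based half-open intervals
#'   around the expected cut sites.
#' @return An `amplicon_reference` object.
#' @export
amplicon_reference <- function(name, seq, target_windows) {
  seq <- toupper(seq)
  check_alphabet(seq, c("A", "C", "G", "T"), "amplicon sequence")
  tw <- matrix(as.integer(target_windows), ncol = 2)
  if (any(tw[, 1] < 0L) || any(tw[, 2] > nchar(seq)) || any(tw[, 1] >= tw[, 2]))
    stop2("target windows must be non-empty 0-based half-open intervals inside the amplicon")
  structure(list(name = name, seq = seq, target_windows = tw),
            class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s: %d bp, %d target window(s)\n",
              x$name, nchar(x$seq), nrow(x$target_windows)))
  invisible(x)
}

#' Default synthetic amplicon reference
#'
#' A synthetic 211-bp amplicon carrying the two [example_guides()]
#' protospacers with NGG PAMs; the blunt cut sites (3 bp 5' of each PAM)
#' sit at 0-based positions 57 and 129, i.e. 72 bp apart. Target windows
#' extend 10 bp to each side of each cut site.
#'
#' @return An [amplicon_reference()].
#' @export
default_reference <- function() {
  amplicon_reference(
    name = "AMP01_synthetic",
    seq = .SYNTHETIC_AMPLICON,
    target_windows = rbind(c(47L, 67L), c(119L, 139L))
  )
}

#' Construct frameshift primers
#'
#' A frameshift primer is the first-PCR oligo seen from the read's side:
#' 0-8 frameshifting bases followed by the locus-specific priming sequence
#' (and, towards the fragment end, a partial TruSeq adapter which never
#' appears at the start of a read and is kept only for bookkeeping).
#'
#' @param id Primer labels.
#' @param side `"forward"` or `"reverse"` (recycled).
#' @param frameshift Frameshifting bases, `""` for none.
#' @param locus_seq Locus-specific priming sequence (read-facing).
#' @param adapter_stub Optional partial adapter sequence.
#' @return data.frame with one row per primer.
#' @export
frameshift_primer <- function(id, side, frameshift, locus_seq,
                              adapter_stub = "") {
  side <- match.arg(side, c("forward", "reverse"))
  stopifnot(length(id) == length(frameshift))
  for (f in frameshift[nzchar(frameshift)]) check_alphabet(f, what = "frameshift")
  if (any(nchar(frameshift) > 8L))
    stop2("frameshift length must be 0-8 bases")
  data.frame(id = id, side = side, frameshift = frameshift,
             locus_seq = locus_seq, adapter_stub = adapter_stub,
             stringsAsFactors = FALSE)
}

# TruSeq adapter halves (public Illumina sequences), bookkeeping only.
.TRUSEQ_R1 <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
.TRUSEQ_R2 <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"

#' Default frameshift primer sets
#'
#' Four forward and four reverse primers with frameshift lengths 0-3
#' (one full codon-register cycle per side, 16 combinations). The
#' frameshifting bases were chosen so that the 9-base read prefixes of each
#' side are single-substitution collision-free against the default
#' reference's priming sequences.
#'
#' @param ref An [amplicon_reference()]; priming sequences are its first and
#'   last 20 bases.
#' @return List with data.frames `fwd` and `rev`.
#' @export
default_frameshift_primers <- function(ref = default_reference()) {
  n <- nchar(ref$seq)
  fwd_locus <- substr(ref$seq, 1L, 20L)
  rev_locus <- revcomp(substr(ref$seq, n - 19L, n))
  list(
    fwd = frameshift_primer(
      id = sprintf("FSF-%d", 0:3), side = "forward",
      frameshift = c("", "G", "TC", "ACT"),
      locus_seq = fwd_locus, adapter_stub = .TRUSEQ_R1),
    rev = frameshift_primer(
      id = sprintf("FSR-%d", 0:3), side = "reverse",
      frameshift = c("", "C", "AG", "GTA"),
      locus_seq = rev_locus, adapter_stub = .TRUSEQ_R2)
  )
}

#' Generate a set of plate index sequences
#'
#' Deterministic lexicographic-greedy code: 8-base indices with pairwise
#' Hamming distance >= 3, so primary demultiplexing with one allowed
#' mismatch can never be ambiguous. The first call is memoised.
#'
#' @param n Number of indices (default 96, the dual-index plate standard).
#' @param width Index length in bases.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return data.frame with columns `id`, `seq`.
#' @export
default_plate_indices <- function(n = 96L, width = 8L, min_dist = 3L) {
  key <- sprintf("idx_%d_%d_%d", n, width, min_dist)
  if (!is.null(.crispgeno_env[[key]])) return(.crispgeno_env[[key]])
  bases <- c("A", "C", "G", "T")
  acc <- matrix(integer(0), ncol = width)
  i <- 0L
  while (nrow(acc) < n && i < 4^width) {
    v <- integer(width); x <- i
    for (p in width:1) { v[p] <- x %% 4L; x <- x %/% 4L }
    ok <- nrow(acc) == 0L ||
      all(rowSums(acc != matrix(v, nrow(acc), width, byrow = TRUE)) >= min_dist)
    if (ok) acc <- rbind(acc, v)
    i <- i + 1L
  }
  if (nrow(acc) < n)
    stop2(sprintf("cannot build %d indices of width %d at distance %d", n, width, min_dist))
  out <- data.frame(
    id = sprintf("IDX%02d", seq_len(n)),
    seq = apply(acc, 1, function(r) paste(bases[r + 1L], collapse = "")),
    stringsAsFactors = FALSE)
  .crispgeno_env[[key]] <- out
  out
}
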