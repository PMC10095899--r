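# Shared fixtures and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_naive <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force PAM-site oracle: position-by-position window scan on both
# strands, entirely independent of the package's vectorized implementation.
naive_pam_scan <- function(seq, both_strands = TRUE) {
  L <- nchar(seq)
  out <- data.frame(protospacer = character(0), strand = character(0),
                    protospacer_start = integer(0), pam = character(0),
                    cut_site = integer(0), stringsAsFactors = FALSE)
  scan1 <- function(s) {
    hits <- list()
    for (i in seq_len(nchar(s) - 22L)) {           # 1-based protospacer start
      pam <- substr(s, i + 20L, i + 22L)
      if (substr(pam, 2L, 3L) == "GG")
        hits[[length(hits) + 1L]] <- c(i - 1L, substr(s, i, i + 19L), pam)
    }
    hits
  }
  for (h in scan1(seq)) {
    s0 <- as.integer(h[1])
    out <- rbind(out, data.frame(protospacer = h[2], strand = "+",
                                 protospacer_start = s0, pam = h[3],
                                 cut_site = s0 + 17L))
  }
  if (both_strands) {
    for (h in scan1(rc_naive(seq))) {
      s0 <- as.integer(h[1])
      out <- rbind(out, data.frame(protospacer = h[2], strand = "-",
                                   protospacer_start = L - s0 - 20L,
                                   pam = h[3],
                                   cut_site = L - s0 - 20L + 3L))
    }
  }
  out <- out[order(out$protospacer_start, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# Exhaustive-shift indel normalization oracle: enumerate every placement
# (with, for insertions, the rotated allele that placement implies) whose
# full alternate sequence equals the observed one; return the leftmost.
exhaustive_leftmost <- function(ref_seq, type, pos0, allele) {
  n <- nchar(ref_seq)
  if (type == "DEL") {
    alt_of <- function(p)
      paste0(substr(ref_seq, 1, p), substr(ref_seq, p + allele + 1, n))
    target <- alt_of(pos0)
    cand <- 0:(n - allele)
    return(min(cand[vapply(cand, function(p) alt_of(p) == target, NA)]))
  }
  L <- nchar(allele)
  target <- paste0(substr(ref_seq, 1, pos0 + 1), allele,
                   substr(ref_seq, pos0 + 2, n))
  ok <- vapply(0:(n - 1), function(p) {
    ins_p <- substr(target, p + 2, p + 1 + L)
    paste0(substr(ref_seq, 1, p + 1), ins_p, substr(ref_seq, p + 2, n)) ==
      target
  }, NA)
  min((0:(n - 1))[ok])
}

# Small complete design shared by demux/genotype tests.
small_design <- function(n_samples = 6L, n_plates = 2L) {
  ref <- default_reference()
  tab <- default_barcode_table(ref)
  sheet <- make_sample_sheet(n_samples, tab, default_plate_indices(n_plates))
  list(ref = ref, tab = tab, sheet = sheet,
       indices = default_plate_indices(n_plates))
}

# Substitute one base (to a different base) at `pos` of column `col`.
poke_base <- function(pairs, row, col, pos) {
  x <- pairs[[col]][row]
  b <- substr(x, pos, pos)
  nb <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
  substring(x, pos, pos) <- nb
  pairs[[col]][row] <- x
  pairs
}

biostrings_glocal_score <- function(read, refseq, p = align_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = p$match, mismatch = p$mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    read, refseq, type = "global-local", substitutionMatrix = mat,
    gapOpening = p$gap_open, gapExtension = p$gap_ext))
}
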