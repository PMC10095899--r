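# Guide-site selection and two-level barcode architecture.

# Scan one strand (given as a plain string) for 20-mer protospacers 5' of an
# NGG PAM. Returns 0-based protospacer starts in that strand's coordinates.
#' @noRd
scan_one_strand <- function(seq) {
  L <- nchar(seq)
  if (L < 23L) return(integer(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  # PAM starts p (1-based) need GG at p+1, p+2 and a full 20-mer before p
  p <- which(ch == "G")
  p <- p[p >= 22L & p <= L - 1L]
  p <- p[ch[p + 1L] == "G"] - 1L          # p now = PAM N position
  p <- p[p >= 21L]
  sort(p) - 21L                            # 0-based protospacer start
}

#' Scan a sequence for SpCas9 target sites (NGG PAM)
#'
#' Finds every 20-mer immediately 5' of an NGG protospacer-adjacent motif.
#' Reverse-strand sites are reported with the protospacer and PAM in their
#' own (reverse-complement) orientation but with coordinates on the plus
#' strand; `protospacer_start` is the 0-based plus-strand offset of the
#' protospacer's leftmost base. `cut_site` is the 0-based position of the
#' blunt cut boundary, modeled 3 bp 5' of the PAM (between protospacer
#' positions 17 and 18) -- standard SpCas9 biology, stated here as an
#' assumption.
#'
#' @param sequence Nucleotide string (ACGTN).
#' @param both_strands Scan the reverse strand too? Default TRUE.
#' @return data.frame with columns `protospacer`, `strand`,
#'   `protospacer_start`, `pam`, `cut_site`, sorted by start then strand.
#'   Sequences shorter than 23 nt yield zero rows.
#' @export
scan_pam_sites <- function(sequence, both_strands = TRUE) {
  sequence <- toupper(sequence)
  check_alphabet(sequence, what = "sequence")
  L <- nchar(sequence)
  empty <- data.frame(protospacer = character(0), strand = character(0),
                      protospacer_start = integer(0), pam = character(0),
                      cut_site = integer(0), stringsAsFactors = FALSE)
  if (L < 23L) return(empty)

  site_df <- function(seq, starts, strand) {
    if (length(starts) == 0L) return(empty)
    proto <- substring(seq, starts + 1L, starts + 20L)
    pam <- substring(seq, starts + 21L, starts + 23L)
    if (strand == "+") {
      data.frame(protospacer = proto, strand = "+",
                 protospacer_start = starts, pam = pam,
                 cut_site = starts + 17L, stringsAsFactors = FALSE)
    } else {
      data.frame(protospacer = proto, strand = "-",
                 protospacer_start = L - starts - 20L, pam = pam,
                 cut_site = L - starts - 20L + 3L, stringsAsFactors = FALSE)
    }
  }

  out <- site_df(sequence, scan_one_strand(sequence), "+")
  if (both_strands) {
    rcseq <- revcomp(sequence)
    out <- rbind(out, site_df(rcseq, scan_one_strand(rcseq), "-"))
  }
  out <- out[order(out$protospacer_start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find target sites invariant across haplotypes
#'
#' Scans the first haplotype for PAM sites and keeps only those whose full
#' protospacer+PAM window is identical, and free of gaps and ambiguity
#' characters, in every haplotype of the alignment. This restricts guide
#' selection to sequence without variation among accessions.
#'
#' @param haplotypes Character vector (>= 2) of equal-length aligned
#'   sequences; `-` marks alignment gaps.
#' @param both_strands Scan both strands? Default TRUE.
#' @return data.frame as [scan_pam_sites()], in alignment coordinates.
#' @export
find_conserved_targets <- function(haplotypes, both_strands = TRUE) {
  if (length(haplotypes) < 2L)
    stop2("need at least 2 haplotypes")
  haplotypes <- toupper(haplotypes)
  if (length(unique(nchar(haplotypes))) != 1L)
    stop2("haplotypes must have equal (aligned) length")
  for (h in haplotypes) check_alphabet(h, c("A", "C", "G", "T", "N", "-"),
                                       "haplotype")
  L <- nchar(haplotypes[1])
  sites <- scan_pam_sites(gsub("-", "N", haplotypes[1], fixed = TRUE),
                          both_strands = both_strands)
  if (nrow(sites) == 0L) return(sites)
  ws <- ifelse(sites$strand == "+", sites$protospacer_start,
               sites$protospacer_start - 3L)
  we <- ws + 23L
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    win <- substring(haplotypes, ws[i] + 1L, we[i])
    keep[i] <- length(unique(win)) == 1L && grepl("^[ACGT]+$", win[1])
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the secondary-barcode table
#'
#' For every (forward, reverse) primer combination, records the first `k`
#' bases each mate will show: the frameshifting bases followed by the start
#' of the locus priming sequence. These k-base prefixes are the 'secondary'
#' barcodes of exact-match demultiplexing. Construction fails if two primers
#' on the same side share a k-prefix.
#'
#' @param fwd_primers,rev_primers data.frames from [frameshift_primer()].
#' @param k Prefix length, default 9.
#' @return A `barcode_table`: data.frame of entries with attribute `k`.
#' @export
build_barcode_table <- function(fwd_primers, rev_primers, k = 9L) {
  k <- as.integer(k)
  if (!all(fwd_primers$side == "forward") || !all(rev_primers$side == "reverse"))
    stop2("primers passed on the wrong side")
  prefix_of <- function(p) {
    full <- paste0(p$frameshift, p$locus_seq)
    short <- nchar(full) < k
    if (any(short))
      stop2(sprintf("primer(s) %s: frameshift + locus sequence shorter than k = %d",
                    paste(p$id[short], collapse = ", "), k))
    substr(full, 1L, k)
  }
  fp <- prefix_of(fwd_primers)
  rp <- prefix_of(rev_primers)
  report_collisions <- function(prefix, ids, side) {
    dup <- prefix[duplicated(prefix)]
    if (length(dup) > 0L) {
      who <- vapply(unique(dup), function(d)
        paste(ids[prefix == d], collapse = "/"), "")
      stop2(sprintf("%s primer prefix collision at k=%d: %s",
                    side, k, paste(sprintf("%s (%s)", unique(dup), who),
                                   collapse = "; ")))
    }
  }
  report_collisions(fp, fwd_primers$id, "forward")
  report_collisions(rp, rev_primers$id, "reverse")
  grid <- expand.grid(fi = seq_len(nrow(fwd_primers)),
                      ri = seq_len(nrow(rev_primers)))
  grid <- grid[order(grid$fi, grid$ri), ]
  entries <- data.frame(
    fwd_primer_id = fwd_primers$id[grid$fi],
    rev_primer_id = rev_primers$id[grid$ri],
    fwd_prefix9 = fp[grid$fi],
    rev_prefix9 = rp[grid$ri],
    fwd_fs_len = nchar(fwd_primers$frameshift)[grid$fi],
    rev_fs_len = nchar(rev_primers$frameshift)[grid$ri],
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(entries, k = k, class = c("barcode_table", "data.frame"))
}

#' Validate a barcode table
#'
#' Reports duplicate prefixes (there must be none for exact-match
#' demultiplexing to be well-defined) and, optionally, same-side prefix
#' pairs at Hamming distance 1. A table with no distance-1 pairs is
#' substitution-robust: one sequencing error in a prefix can only make a
#' read unassignable, never re-assign it to another sample.
#'
#' @param table A `barcode_table`.
#' @param require_substitution_robust Also report Hamming-distance-1 pairs?
#' @return List with `n_entries`, `duplicates`, `near_collisions`, `pass`.
#' @export
validate_barcode_table <- function(table, require_substitution_robust = FALSE) {
  if (nrow(table) == 0L) stop2("empty barcode table")
  sides <- list(
    forward = unique(data.frame(id = table$fwd_primer_id,
                                prefix = table$fwd_prefix9)),
    reverse = unique(data.frame(id = table$rev_primer_id,
                                prefix = table$rev_prefix9)))
  dup <- data.frame(side = character(0), prefix = character(0),
                    ids = character(0))
  near <- data.frame(side = character(0), id1 = character(0),
                     id2 = character(0), prefix1 = character(0),
                     prefix2 = character(0))
  for (s in names(sides)) {
    u <- sides[[s]]
    dups <- unique(u$prefix[duplicated(u$prefix)])
    for (d in dups)
      dup <- rbind(dup, data.frame(side = s, prefix = d,
                                   ids = paste(u$id[u$prefix == d],
                                               collapse = "/")))
    if (require_substitution_robust && nrow(u) > 1L) {
      for (a in seq_len(nrow(u) - 1L)) for (b in (a + 1L):nrow(u)) {
        if (hamming(u$prefix[a], u$prefix[b]) == 1L)
          near <- rbind(near, data.frame(side = s, id1 = u$id[a],
                                         id2 = u$id[b],
                                         prefix1 = u$prefix[a],
                                         prefix2 = u$prefix[b]))
      }
    }
  }
  list(n_entries = nrow(table), duplicates = dup, near_collisions = near,
       pass = nrow(dup) == 0L &&
         (!require_substitution_robust || nrow(near) == 0L))
}

#' Assign samples to barcode/index combinations
#'
#' Fills all primer combinations of one plate index before advancing to the
#' next index; deterministic in its inputs. Well coordinates (A1..H12,
#' column-major) are attached when a plate holds at most 96 combinations.
#'
#' @param n_samples Number of samples.
#' @param table A `barcode_table`.
#' @param indices data.frame of plate indices (`id`, `seq`).
#' @param sample_ids Optional explicit sample names (length `n_samples`).
#' @return data.frame, one row per sample: `sample_id`, `plate_index_id`,
#'   `index_seq`, `fwd_primer_id`, `rev_primer_id`, `fwd_prefix9`,
#'   `rev_prefix9`, `well`.
#' @export
make_sample_sheet <- function(n_samples, table, indices, sample_ids = NULL) {
  n_samples <- as.integer(n_samples)
  cap <- nrow(table) * nrow(indices)
  if (n_samples > cap)
    stop2(sprintf("%d samples exceed capacity: %d combinations x %d indices = %d",
                  n_samples, nrow(table), nrow(indices), cap))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  if (length(sample_ids) != n_samples || anyDuplicated(sample_ids))
    stop2("sample_ids must be unique and of length n_samples")
  if (n_samples == 0L) {
    return(data.frame(sample_id = character(0), plate_index_id = character(0),
                      index_seq = character(0), fwd_primer_id = character(0),
                      rev_primer_id = character(0), fwd_prefix9 = character(0),
                      rev_prefix9 = character(0), well = character(0)))
  }
  i <- seq_len(n_samples) - 1L
  idx_i <- i %/% nrow(table) + 1L
  combo_i <- i %% nrow(table) + 1L
  well <- if (nrow(table) <= 96L) {
    sprintf("%s%d", LETTERS[(combo_i - 1L) %% 8L + 1L],
            (combo_i - 1L) %/% 8L + 1L)
  } else NA_character_
  data.frame(
    sample_id = sample_ids,
    plate_index_id = indices$id[idx_i],
    index_seq = indices$seq[idx_i],
    fwd_primer_id = table$fwd_primer_id[combo_i],
    rev_primer_id = table$rev_primer_id[combo_i],
    fwd_prefix9 = table$fwd_prefix9[combo_i],
    rev_prefix9 = table$rev_prefix9[combo_i],
    well = well,
    stringsAsFactors = FALSE)
}

#' Default barcode table and sample sheet helpers
#'
#' `default_barcode_table()` builds the 16-combination table from
#' [default_frameshift_primers()] and asserts it is substitution-robust.
#'
#' @param ref An [amplicon_reference()].
#' @param k Prefix length.
#' @return A `barcode_table`.
#' @export
default_barcode_table <- function(ref = default_reference(), k = 9L) {
  pr <- default_frameshift_primers(ref)
  tab <- build_barcode_table(pr$fwd, pr$rev, k = k)
  v <- validate_barcode_table(tab, require_substitution_robust = TRUE)
  if (!v$pass) stop2("default barcode table failed validation")
  tab
}

#' Write / read a sample sheet as TSV
#'
#' Columns: `sample_id  plate_index_id  index_seq  fwd_primer_id
#' rev_primer_id  fwd_prefix9  rev_prefix9  well`.
#'
#' @param sheet data.frame from [make_sample_sheet()].
#' @param path File path.
#' @return The path (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write / read a barcode table as TSV
#'
#' @param table A `barcode_table`.
#' @param path File path.
#' @return The path (write) or the table (read).
#' @export
write_barcode_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(df, k = nchar(df$fwd_prefix9[1]),
            class = c("barcode_table", "data.frame"))
}
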