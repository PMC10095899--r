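# Per-sample genotyping: prefix trimming, banded glocal alignment, pileup,
# frequency-threshold variant calling with indel left-alignment, and
# zygosity classification.

#' Alignment scoring parameters
#'
#' Defaults (match +2, mismatch -4, gap open 6, gap extend 1, band 32) are
#' chosen for indel sensitivity on short amplicons. A gap of length L costs
#' `gap_open + L * gap_ext`. Reads scoring below `floor_frac` times the
#' perfect-match score are marked unalignable.
#'
#' @param match,mismatch Per-base scores (mismatch negative).
#' @param gap_open,gap_ext Positive gap penalties.
#' @param band Half-width of the DP band around candidate diagonals; a band
#'   of at least reference + read length runs the full matrix.
#' @param floor_frac Alignment acceptance floor as a fraction of the
#'   perfect score.
#' @return List of parameters.
#' @export
align_params <- function(match = 2L, mismatch = -4L, gap_open = 6L,
                         gap_ext = 1L, band = 32L, floor_frac = 0.4) {
  stopifnot(match > 0L, mismatch < 0L, gap_open >= 0L, gap_ext >= 0L,
            band >= 1L, floor_frac >= 0, floor_frac <= 1)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
       band = as.integer(band), floor_frac = floor_frac)
}

#' Genotyping thresholds
#'
#' The zygosity bands are package choices (the calling thresholds of the
#' original external toolchain are not specified anywhere): homozygous at
#' alternate-allele frequency >= 0.85, heterozygous within [0.35, 0.65],
#' anything else with support above `min_af` is mixed/chimeric. The depth
#' floor of 20 is 2% of the 1,000x coverage aim.
#'
#' @param min_depth Minimum site depth for a call.
#' @param min_af Minimum alternate-allele frequency.
#' @param min_alt_count Minimum supporting reads.
#' @param min_base_qual Pileup base-quality cutoff (Phred).
#' @param hom_af Homozygous AF threshold.
#' @param het_band Heterozygous AF interval, length 2.
#' @param depth_floor Mean target-window depth below which a sample is
#'   `low_coverage`.
#' @return List of thresholds.
#' @export
genotype_params <- function(min_depth = 20L, min_af = 0.10,
                            min_alt_count = 5L, min_base_qual = 20L,
                            hom_af = 0.85, het_band = c(0.35, 0.65),
                            depth_floor = 20) {
  stopifnot(min_depth > 0L, min_af > 0, min_alt_count > 0L,
            length(het_band) == 2L, het_band[1] < het_band[2],
            het_band[2] < hom_af)
  list(min_depth = as.integer(min_depth), min_af = min_af,
       min_alt_count = as.integer(min_alt_count),
       min_base_qual = as.integer(min_base_qual), hom_af = hom_af,
       het_band = het_band, depth_floor = depth_floor)
}

#' Trim frameshift bases from a sample's read pairs
#'
#' Removes exactly the frameshifting bases (never the locus priming bases)
#' from the 5' end of each mate, with qualities trimmed in register. Reads
#' no longer than their frameshift are discarded and counted.
#'
#' @param pairs Pair data.frame for one sample.
#' @param fwd_fs_len,rev_fs_len Frameshift lengths for this sample's primer
#'   combination (see the `barcode_table` columns of the same name).
#' @return List: `pairs` (trimmed), `n_discarded`.
#' @export
trim_prefix <- function(pairs, fwd_fs_len, rev_fs_len) {
  short <- nchar(pairs$seq1) <= fwd_fs_len | nchar(pairs$seq2) <= rev_fs_len
  if (any(short)) pairs <- pairs[!short, , drop = FALSE]
  pairs$seq1 <- substr(pairs$seq1, fwd_fs_len + 1L, nchar(pairs$seq1))
  pairs$qual1 <- substr(pairs$qual1, fwd_fs_len + 1L, nchar(pairs$qual1))
  pairs$seq2 <- substr(pairs$seq2, rev_fs_len + 1L, nchar(pairs$seq2))
  pairs$qual2 <- substr(pairs$qual2, rev_fs_len + 1L, nchar(pairs$qual2))
  list(pairs = pairs, n_discarded = sum(short))
}

#' Align reads to an amplicon reference
#'
#' Banded glocal (global in the read, local in the reference) affine-gap
#' alignment. Band placement is seeded from exact 16-mer matches with the
#' amplicon ends as fallback anchors; several candidate diagonals are
#' tried and the best-scoring alignment kept. Boundary insertions are
#' reported as soft clips.
#'
#' @param seqs Character vector of reads, already in reference orientation.
#' @param ref An [amplicon_reference()].
#' @param params [align_params()].
#' @return data.frame: `score`, `ref_start` (0-based; NA if unalignable),
#'   `cigar`, `aligned`.
#' @export
align_reads <- function(seqs, ref, params = align_params()) {
  res <- align_reads_cpp(seqs, ref$seq, params$match, params$mismatch,
                         params$gap_open, params$gap_ext, params$band,
                         params$floor_frac)
  data.frame(score = res$score, ref_start = res$ref_start,
             cigar = res$cigar, aligned = res$aligned,
             stringsAsFactors = FALSE)
}

#' Align a sample's trimmed read pairs
#'
#' Mate 2 is reverse-complemented (standard forward/reverse amplicon
#' orientation) before alignment, with its quality string reversed in
#' register.
#'
#' @param pairs Trimmed pair data.frame.
#' @param ref An [amplicon_reference()].
#' @param params [align_params()].
#' @return List: `alignments` (data.frame with `read_id`, `mate`, `seq`,
#'   `qual`, `score`, `ref_start`, `cigar`, `aligned`), `n_unalignable`.
#' @export
align_sample <- function(pairs, ref, params = align_params()) {
  seqs <- c(pairs$seq1, revcomp(pairs$seq2))
  quals <- c(pairs$qual1, reverse_strings(pairs$qual2))
  aln <- align_reads(seqs, ref, params)
  alignments <- data.frame(
    read_id = rep(pairs$read_id, 2L),
    mate = rep(c(1L, 2L), each = nrow(pairs)),
    seq = seqs, qual = quals,
    score = aln$score, ref_start = aln$ref_start, cigar = aln$cigar,
    aligned = aln$aligned, stringsAsFactors = FALSE)
  list(alignments = alignments, n_unalignable = sum(!aln$aligned))
}

#' Build a pileup from alignments
#'
#' Accumulates, per reference position, the spanning-read depth, the
#' quality-filtered substitution-allele counts, deletion spans, and keyed
#' insertion/deletion events anchored at the base immediately 5' of the
#' event. Bases below `min_base_qual` count toward depth but never toward
#' allele counts.
#'
#' @param alignments Alignment data.frame from [align_sample()].
#' @param ref An [amplicon_reference()].
#' @param min_base_qual Phred cutoff (default 20).
#' @return A `pileup` list: `depth`, `base_counts` (4 x L, rows ACGT),
#'   `qual_sums`, `del_span`, `ins_events`, `del_events`, `n_reads`.
#' @export
build_pileup <- function(alignments, ref, min_base_qual = 20L) {
  ok <- alignments$aligned
  a <- alignments[ok, , drop = FALSE]
  res <- pileup_cpp(a$seq, a$qual, a$ref_start, a$cigar, ref$seq,
                    as.integer(min_base_qual))
  bc <- res$base_counts
  rownames(bc) <- c("A", "C", "G", "T")
  qs <- res$qual_sums
  rownames(qs) <- c("A", "C", "G", "T")
  structure(list(
    ref_name = ref$name,
    depth = res$depth,
    base_counts = bc,
    qual_sums = qs,
    del_span = res$del_span,
    ins_events = data.frame(anchor0 = res$ins_anchor0, seq = res$ins_seq,
                            count = res$ins_count, qual = res$ins_qual,
                            stringsAsFactors = FALSE),
    del_events = data.frame(start0 = res$del_start0, len = res$del_len,
                            count = res$del_count, qual = res$del_qual,
                            stringsAsFactors = FALSE),
    n_reads = nrow(a)), class = "pileup")
}

#' Left-align an indel against the reference
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement
#' (VCF normalization). Idempotent: normalizing a normalized indel is the
#' identity.
#'
#' @param ref_seq Reference string.
#' @param type `"INS"` or `"DEL"`.
#' @param pos0 0-based event position: anchor base before the inserted
#'   sequence (INS) or first deleted base (DEL).
#' @param allele Inserted sequence (INS) or deletion length (DEL).
#' @return List: `pos0`, `allele` after normalization.
#' @export
normalize_indel <- function(ref_seq, type, pos0, allele) {
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  if (type == "DEL") {
    len <- as.integer(allele)
    s <- pos0
    while (s > 0L && rc[s] == rc[s + len]) s <- s - 1L
    list(pos0 = s, allele = len)
  } else if (type == "INS") {
    seq <- allele
    L <- nchar(seq)
    a <- pos0
    while (a >= 1L && substr(seq, L, L) == rc[a + 1L]) {
      seq <- paste0(rc[a + 1L], substr(seq, 1L, L - 1L))
      a <- a - 1L
    }
    list(pos0 = a, allele = seq)
  } else stop2("normalize_indel handles INS and DEL only")
}

#' Call variants from a pileup
#'
#' Frequency-threshold caller: emits every allele reaching `min_af`
#' frequency with at least `min_alt_count` supporting reads at a site with
#' depth at least `min_depth`. Indels are left-aligned, equivalent events
#' merged, and anchored with one reference base per VCF convention.
#' Multi-allelic sites yield one record per alternate allele.
#'
#' @param pileup A `pileup`.
#' @param ref An [amplicon_reference()].
#' @param params [genotype_params()].
#' @return data.frame of calls: `pos` (1-based), `ref`, `alt`, `type`,
#'   `DP`, `AD_ref`, `AD_alt`, `AF`, `qual`.
#' @export
call_variants <- function(pileup, ref, params = genotype_params()) {
  rc <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  L <- length(rc)
  depth <- pileup$depth
  rows <- list()

  # SNVs
  bc <- pileup$base_counts
  for (b in c("A", "C", "G", "T")) {
    cand <- which(rc != b & bc[b, ] >= params$min_alt_count &
                    depth >= params$min_depth)
    cand <- cand[bc[b, cand] / depth[cand] >= params$min_af]
    for (p in cand) {
      cnt <- bc[b, p]
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, ref = rc[p], alt = b, type = "SNV", DP = depth[p],
        AD_ref = bc[rc[p], p], AD_alt = cnt, AF = cnt / depth[p],
        qual = pileup$qual_sums[b, p] / cnt, stringsAsFactors = FALSE)
    }
  }

  # deletions: normalize, merge, anchor
  de <- pileup$del_events
  if (nrow(de) > 0L) {
    norm <- lapply(seq_len(nrow(de)), function(i)
      normalize_indel(ref$seq, "DEL", de$start0[i], de$len[i]))
    de$start0 <- vapply(norm, `[[`, 0L, "pos0")
    agg <- aggregate(cbind(count, qw = qual * count) ~ start0 + len, de, sum)
    for (i in seq_len(nrow(agg))) {
      s <- agg$start0[i]; len <- agg$len[i]; cnt <- agg$count[i]
      if (s >= 1L) {
        pos <- s                                    # 1-based anchor base
        refa <- paste(rc[s:(s + len)], collapse = "")
        alta <- rc[s]
      } else {                                      # deletion at amplicon start
        pos <- 1L
        refa <- paste(rc[1:(len + 1L)], collapse = "")
        alta <- rc[len + 1L]
      }
      dp <- depth[pos]
      if (dp >= params$min_depth && cnt >= params$min_alt_count &&
          cnt / dp >= params$min_af) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, ref = refa, alt = alta, type = "DEL", DP = dp,
          AD_ref = max(dp - cnt, 0L), AD_alt = cnt, AF = min(cnt / dp, 1),
          qual = agg$qw[i] / cnt, stringsAsFactors = FALSE)
      }
    }
  }

  # insertions: normalize, merge, anchor
  ie <- pileup$ins_events
  if (nrow(ie) > 0L) {
    norm <- lapply(seq_len(nrow(ie)), function(i)
      normalize_indel(ref$seq, "INS", ie$anchor0[i], ie$seq[i]))
    ie$anchor0 <- vapply(norm, `[[`, 0L, "pos0")
    ie$seq <- vapply(norm, `[[`, "", "allele")
    agg <- aggregate(cbind(count, qw = qual * count) ~ anchor0 + seq, ie, sum)
    for (i in seq_len(nrow(agg))) {
      a0 <- agg$anchor0[i]; cnt <- agg$count[i]
      pos <- a0 + 1L
      dp <- depth[pos]
      if (dp >= params$min_depth && cnt >= params$min_alt_count &&
          cnt / dp >= params$min_af) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, ref = rc[pos], alt = paste0(rc[pos], agg$seq[i]),
          type = "INS", DP = dp, AD_ref = max(dp - cnt, 0L), AD_alt = cnt,
          AF = min(cnt / dp, 1), qual = agg$qw[i] / cnt,
          stringsAsFactors = FALSE)
      }
    }
  }

  if (length(rows) == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      DP = integer(0), AD_ref = integer(0),
                      AD_alt = integer(0), AF = numeric(0),
                      qual = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$type, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 0-based half-open reference span affected by a call
#' @noRd
call_span <- function(calls) {
  if (nrow(calls) == 0L)
    return(matrix(integer(0), ncol = 2))
  start <- calls$pos - 1L
  end <- ifelse(calls$type == "DEL", calls$pos - 1L + nchar(calls$ref),
                calls$pos)
  cbind(start, end)
}

#' Restrict calls to the reference's target windows
#'
#' @param calls Call data.frame from [call_variants()].
#' @param ref An [amplicon_reference()].
#' @return The subset of calls whose affected span overlaps a window.
#' @export
calls_in_windows <- function(calls, ref) {
  if (nrow(calls) == 0L) return(calls)
  sp <- call_span(calls)
  keep <- vapply(seq_len(nrow(calls)), function(i)
    any(sp[i, 1] < ref$target_windows[, 2] &
          sp[i, 2] > ref$target_windows[, 1]), NA)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a sample's genotype from its target-window calls
#'
#' Rules, applied to calls restricted to the target windows:
#' `low_coverage` when mean window depth is below the floor (overrides
#' everything); `wild_type` with no surviving call; `homozygous` with one
#' alternate allele at AF >= `hom_af`; `heterozygous` with one alternate
#' inside the `het_band`; otherwise `mixed` (chimeric/somatic editing).
#'
#' @param calls Call data.frame.
#' @param ref An [amplicon_reference()].
#' @param pileup The sample's `pileup` (for mean window depth).
#' @param sample_id Sample label.
#' @param params [genotype_params()].
#' @return A `sample_genotype` list: `sample_id`, `class`, `calls`,
#'   `mean_target_depth`.
#' @export
classify_genotype <- function(calls, ref, pileup, sample_id = NA_character_,
                              params = genotype_params()) {
  win_pos <- unique(unlist(apply(ref$target_windows, 1, function(w)
    seq.int(w[1] + 1L, w[2]), simplify = FALSE)))
  mtd <- mean(pileup$depth[win_pos])
  calls <- calls_in_windows(calls, ref)
  cls <- if (mtd < params$depth_floor) {
    "low_coverage"
  } else if (nrow(calls) == 0L) {
    "wild_type"
  } else if (nrow(calls) == 1L) {
    af <- calls$AF[1]
    if (af >= params$hom_af) "homozygous"
    else if (af >= params$het_band[1] && af <= params$het_band[2])
      "heterozygous"
    else "mixed"
  } else {
    "mixed"
  }
  structure(list(sample_id = sample_id, class = cls, calls = calls,
                 mean_target_depth = mtd), class = "sample_genotype")
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat(sprintf("<sample_genotype> %s: %s (mean target depth %.1f, %d call(s))\n",
              x$sample_id, x$class, x$mean_target_depth, nrow(x$calls)))
  invisible(x)
}

#' Genotype one demultiplexed sample end to end
#'
#' Trims frameshift bases, aligns both mates, builds the pileup, calls
#' variants and classifies zygosity.
#'
#' @param pairs The sample's read pairs (untrimmed, as demultiplexed).
#' @param sample_id Sample label.
#' @param fwd_fs_len,rev_fs_len Frameshift lengths for this sample.
#' @param ref An [amplicon_reference()].
#' @param aln_params [align_params()].
#' @param gt_params [genotype_params()].
#' @return A `sample_genotype` with extra fields `counts` (named integer:
#'   `n_pairs`, `n_discarded`, `n_unalignable`, `n_aligned_reads`) and
#'   `pileup`.
#' @export
genotype_sample <- function(pairs, sample_id, fwd_fs_len, rev_fs_len, ref,
                            aln_params = align_params(),
                            gt_params = genotype_params()) {
  tr <- trim_prefix(pairs, fwd_fs_len, rev_fs_len)
  al <- align_sample(tr$pairs, ref, aln_params)
  pu <- build_pileup(al$alignments, ref, gt_params$min_base_qual)
  calls <- call_variants(pu, ref, gt_params)
  g <- classify_genotype(calls, ref, pu, sample_id, gt_params)
  g$counts <- c(n_pairs = nrow(pairs), n_discarded = tr$n_discarded,
                n_unalignable = al$n_unalignable,
                n_aligned_reads = pu$n_reads)
  g$pileup <- pu
  g$alignments <- al$alignments
  g
}
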