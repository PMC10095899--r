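# Two-stage demultiplexing: plate index first, then exact-match 9-base
# frameshift prefixes. Read pairs travel as data.frames with columns
# read_id, seq1, qual1, seq2, qual2, index_seq.

#' Primary demultiplexing by plate index
#'
#' Assigns each read pair to the unique plate index within `max_mismatch`
#' Hamming distance of its observed index sequence. If no index, or more
#' than one, lies within range the pair is undetermined. The index is
#' carried in the header annotation and never written into the mate
#' sequences (the primary demultiplexer is assumed to have trimmed it).
#'
#' @param pairs data.frame of read pairs (see [read_fastq_pairs()]).
#' @param indices data.frame of plate indices (`id`, `seq`), equal widths.
#' @param max_mismatch 0 or 1 allowed index mismatches (default 1).
#' @return List: `plates` (named list of pair data.frames, one per index
#'   with >= 1 read), `undetermined` (data.frame), `per_plate_counts`
#'   (named integer over all indices), `n_undetermined`, `n_missing_index`.
#' @export
primary_demux <- function(pairs, indices, max_mismatch = 1L) {
  max_mismatch <- as.integer(max_mismatch)
  if (!max_mismatch %in% c(0L, 1L)) stop2("max_mismatch must be 0 or 1")
  if (length(unique(nchar(indices$seq))) != 1L)
    stop2("index sequences must share one length")
  w <- nchar(indices$seq[1])
  obs <- pairs$index_seq
  missing <- is.na(obs) | !nzchar(obs) | nchar(obs) != w
  if (any(missing))
    warning(sprintf("%d read pair(s) without a valid index annotation -> undetermined",
                    sum(missing)), call. = FALSE)
  assign_idx <- rep(NA_integer_, nrow(pairs))

  idx_dist <- hamming_matrix(indices$seq, indices$seq)
  diag(idx_dist) <- NA_integer_
  safe_exact <- all(idx_dist > max_mismatch, na.rm = TRUE)

  exact <- match(obs, indices$seq)
  need_full <- !missing & (is.na(exact) | !safe_exact)
  if (safe_exact) assign_idx[!missing & !is.na(exact)] <- exact[!missing & !is.na(exact)]
  if (any(need_full)) {
    d <- hamming_matrix(obs[need_full], indices$seq)
    within <- d <= max_mismatch
    nw <- rowSums(within)
    best <- max.col(-d, ties.method = "first")
    assign_idx[need_full] <- ifelse(nw == 1L, best, NA_integer_)
  }

  per_plate <- setNames(tabulate(assign_idx, nbins = nrow(indices)),
                        indices$id)
  ok <- !is.na(assign_idx)
  plates <- split(pairs[ok, , drop = FALSE],
                  factor(indices$id[assign_idx[ok]], levels = indices$id),
                  drop = TRUE)
  list(plates = plates,
       undetermined = pairs[!ok, , drop = FALSE],
       per_plate_counts = per_plate,
       n_undetermined = sum(!ok),
       n_missing_index = sum(missing))
}

#' Secondary demultiplexing by exact-match frameshift prefixes
#'
#' A pair is assigned iff the first k bases of mate 1 equal a known forward
#' prefix, the first k bases of mate 2 equal a known reverse prefix, and
#' that (forward, reverse) combination is registered to a sample on this
#' plate. No mismatches are tolerated. Assigned reads are not trimmed: the
#' prefixes are part of the amplicon and are needed downstream.
#'
#' @param pairs data.frame of read pairs for one plate.
#' @param table A `barcode_table`.
#' @param sheet Sample sheet (all plates; filtered by `plate_index_id`).
#' @param plate_index_id Which plate these pairs belong to.
#' @param mode `"both"` (default: both mates' prefixes must match) or
#'   `"either"`: a pair with exactly one recognizable prefix is assigned
#'   when that prefix identifies a unique sample on the plate.
#' @return List: `samples` (named list of pair data.frames), `unassigned`
#'   (data.frame with a `reason` column: `prefix` or `chimeric`), `report`.
#' @export
secondary_demux <- function(pairs, table, sheet, plate_index_id,
                            mode = c("both", "either")) {
  mode <- match.arg(mode)
  k <- attr(table, "k")
  sh <- sheet[sheet$plate_index_id == plate_index_id, , drop = FALSE]
  reg_key <- paste(sh$fwd_primer_id, sh$rev_primer_id)
  tab_key <- paste(table$fwd_primer_id, table$rev_primer_id)
  if (!all(reg_key %in% tab_key))
    stop2("sample sheet references primer combinations absent from the barcode table")

  fwd_map <- unique(data.frame(id = table$fwd_primer_id,
                               prefix = table$fwd_prefix9))
  rev_map <- unique(data.frame(id = table$rev_primer_id,
                               prefix = table$rev_prefix9))
  p1 <- substr(pairs$seq1, 1L, k)
  p2 <- substr(pairs$seq2, 1L, k)
  f_id <- fwd_map$id[match(p1, fwd_map$prefix)]
  r_id <- rev_map$id[match(p2, rev_map$prefix)]
  sample <- sh$sample_id[match(paste(f_id, r_id), reg_key)]

  if (mode == "either") {
    one_sided <- is.na(sample) & (is.na(f_id) != is.na(r_id))
    if (any(one_sided)) {
      cand_f <- sh$sample_id[match(f_id[one_sided], sh$fwd_primer_id)]
      uniq_f <- vapply(f_id[one_sided], function(x)
        if (is.na(x)) NA_integer_ else sum(sh$fwd_primer_id == x), 0L)
      cand_r <- sh$sample_id[match(r_id[one_sided], sh$rev_primer_id)]
      uniq_r <- vapply(r_id[one_sided], function(x)
        if (is.na(x)) NA_integer_ else sum(sh$rev_primer_id == x), 0L)
      pick <- ifelse(!is.na(uniq_f) & uniq_f == 1L, cand_f,
                     ifelse(!is.na(uniq_r) & uniq_r == 1L, cand_r,
                            NA_character_))
      sample[one_sided] <- pick
    }
  }

  assigned <- !is.na(sample)
  chimeric <- !assigned & !is.na(f_id) & !is.na(r_id)
  samples <- split(pairs[assigned, , drop = FALSE],
                   factor(sample[assigned], levels = sh$sample_id),
                   drop = FALSE)
  un <- pairs[!assigned, , drop = FALSE]
  if (nrow(un) > 0L)
    un$reason <- ifelse(chimeric[!assigned], "chimeric", "prefix")
  else un$reason <- character(0)

  per_sample <- setNames(tabulate(factor(sample[assigned],
                                         levels = sh$sample_id),
                                  nbins = nrow(sh)), sh$sample_id)
  report <- list(plate_index_id = plate_index_id,
                 n_samples = nrow(sh),
                 total_pairs = nrow(pairs),
                 per_sample_counts = per_sample,
                 n_assigned = sum(assigned),
                 n_unassigned = sum(!assigned),
                 n_chimeric = sum(chimeric),
                 assigned_fraction = if (nrow(pairs) > 0L)
                   sum(assigned) / nrow(pairs) else NA_real_)
  list(samples = samples, unassigned = un, report = report)
}

#' Summarize a demultiplexing run
#'
#' Combines the primary result and the per-plate secondary reports into a
#' run-level summary: per-plate totals and mean reads per sample, and the
#' grand assigned fraction recomputed from raw counts (never averaged over
#' plates).
#'
#' @param primary Result of [primary_demux()].
#' @param secondary_reports List of `report` entries from
#'   [secondary_demux()].
#' @param path Optional TSV output path for the per-plate table; a JSON
#'   sidecar with the run totals is written next to it.
#' @return List: `per_plate` data.frame (`plate_index_id`, `n_samples`,
#'   `n_pairs`, `n_assigned`, `mean_reads_per_sample`, `empty`),
#'   `total_pairs`, `undetermined_primary`, `unassigned_secondary`,
#'   `assigned`, `assigned_fraction`.
#' @export
demux_report <- function(primary, secondary_reports, path = NULL) {
  stopifnot(length(secondary_reports) >= 1L)
  pp <- do.call(rbind, lapply(secondary_reports, function(r) {
    data.frame(plate_index_id = r$plate_index_id,
               n_samples = r$n_samples,
               n_pairs = r$total_pairs,
               n_assigned = r$n_assigned,
               mean_reads_per_sample = if (r$n_samples > 0L)
                 r$n_assigned / r$n_samples else 0,
               empty = r$total_pairs == 0L,
               stringsAsFactors = FALSE)
  }))
  total <- primary$n_undetermined + sum(pp$n_pairs)
  assigned <- sum(pp$n_assigned)
  unassigned <- sum(pp$n_pairs) - assigned
  out <- list(per_plate = pp,
              total_pairs = total,
              undetermined_primary = primary$n_undetermined,
              unassigned_secondary = unassigned,
              assigned = assigned,
              assigned_fraction = if (total > 0L) assigned / total else NA_real_)
  if (!is.null(path)) {
    write.table(pp, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out[-1], paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
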