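# Synthetic sequencing-run generator: edited templates, frameshift
# prefixes, plate indices, paired reads with substitution errors and
# coverage skew, plus a per-read truth table.

#' Coverage model with skewed per-sample representation
#'
#' Defaults encode the pooling-skew scenario used for capacity planning:
#' 10% of samples yield 10x the targeted read count, 10% yield one tenth,
#' and 80% yield the target itself, around a 1,000-pair-per-sample aim
#' (one read pair spans the whole amplicon, so pairs stand in for fold
#' coverage).
#'
#' @param target_pairs_per_sample Aimed-for pairs per sample (default 1000).
#' @param skew data.frame with `fraction` (sums to 1) and `multiplier`
#'   (> 0) columns.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(target_pairs_per_sample = 1000,
                           skew = data.frame(
                             fraction = c(0.1, 0.1, 0.8),
                             multiplier = c(10, 0.1, 1))) {
  if (abs(sum(skew$fraction) - 1) > 1e-9)
    stop2("skew fractions must sum to 1")
  if (any(skew$multiplier <= 0)) stop2("skew multipliers must be positive")
  if (target_pairs_per_sample <= 0) stop2("target pairs must be positive")
  structure(list(target_pairs_per_sample = target_pairs_per_sample,
                 skew = skew), class = "coverage_model")
}

#' Describe a planted edit
#'
#' @param sample_id Sample carrying the edit.
#' @param type `"NONE"`, `"INS"`, `"DEL"` or `"SUB"`.
#' @param position 0-based amplicon position: base before the insertion
#'   point for INS, first deleted base for DEL, substituted base for SUB.
#' @param payload Inserted sequence (INS), deleted length (DEL), or
#'   replacement base (SUB).
#' @param dosage `"0/2"`, `"1/2"`, `"2/2"`, or a numeric somatic fraction
#'   in (0, 1).
#' @return An `edit_spec` list.
#' @export
edit_spec <- function(sample_id, type = c("NONE", "INS", "DEL", "SUB"),
                      position = NA_integer_, payload = NULL,
                      dosage = "0/2") {
  type <- match.arg(type)
  if (is.character(dosage)) {
    if (!dosage %in% c("0/2", "1/2", "2/2"))
      stop2("dosage must be 0/2, 1/2, 2/2 or a fraction in (0,1)")
  } else if (!is.numeric(dosage) || dosage <= 0 || dosage >= 1) {
    stop2("numeric dosage must lie strictly between 0 and 1")
  }
  structure(list(sample_id = sample_id, type = type,
                 position = as.integer(position), payload = payload,
                 dosage = dosage), class = "edit_spec")
}

#' @noRd
edited_fraction <- function(dosage) {
  if (is.numeric(dosage)) return(dosage)
  c("0/2" = 0, "1/2" = 0.5, "2/2" = 1)[[dosage]]
}

#' Apply a planted edit to the reference amplicon
#'
#' Validates the edit against the reference (it must start inside a target
#' window; a deletion must not run off the amplicon end) and returns the
#' edited template string. `NONE` returns the reference unchanged.
#'
#' @param ref An [amplicon_reference()].
#' @param spec An [edit_spec()].
#' @return Edited template string.
#' @export
apply_edit <- function(ref, spec) {
  s <- ref$seq
  if (spec$type == "NONE") return(s)
  p <- spec$position
  L <- nchar(s)
  in_window <- any(p >= ref$target_windows[, 1] & p < ref$target_windows[, 2])
  if (is.na(p) || !in_window)
    stop2(sprintf("edit position %d lies outside every target window", p))
  switch(spec$type,
    INS = {
      check_alphabet(spec$payload, c("A", "C", "G", "T"), "inserted sequence")
      paste0(substr(s, 1L, p + 1L), spec$payload, substr(s, p + 2L, L))
    },
    DEL = {
      len <- as.integer(spec$payload)
      if (len < 1L || p + len > L)
        stop2("deletion runs off the amplicon end")
      paste0(substr(s, 1L, p), substr(s, p + len + 1L, L))
    },
    SUB = {
      check_alphabet(spec$payload, c("A", "C", "G", "T"), "substituted base")
      if (nchar(spec$payload) != 1L) stop2("SUB payload must be one base")
      paste0(substr(s, 1L, p), spec$payload, substr(s, p + 2L, L))
    })
}

# Apply substitution errors at iid per-base rate. Returns the mutated
# sequences, Phred+33 qualities (Q37 clean / Q20 errored), and a per-read
# list of 1-based error positions. Drawing K ~ Binomial(total bases, rate)
# positions uniformly without replacement is exactly the iid Bernoulli
# model.
#' @noRd
inject_errors <- function(seqs, error_rate) {
  lens <- nchar(seqs)
  quals <- strrep("F", lens)                      # Q37
  n_total <- sum(lens)
  err_pos <- vector("list", length(seqs))
  if (error_rate > 0 && n_total > 0L) {
    k <- rbinom(1L, n_total, error_rate)
    if (k > 0L) {
      gpos <- sort(sample.int(n_total, k))
      offs <- cumsum(c(0L, lens[-length(lens)]))
      ridx <- findInterval(gpos - 1L, cumsum(lens), left.open = FALSE) + 1L
      within <- gpos - offs[ridx]
      shift <- sample.int(3L, k, replace = TRUE)
      bases <- c("A", "C", "G", "T")
      # rounds: several errors in one read need sequential writes
      ord <- order(ridx, within)
      ridx <- ridx[ord]; within <- within[ord]; shift <- shift[ord]
      rank_in_read <- sequence(rle(ridx)$lengths)
      for (r in seq_len(max(rank_in_read))) {
        sel <- rank_in_read == r
        ri <- ridx[sel]; po <- within[sel]
        orig <- substring(seqs[ri], po, po)
        newb <- bases[(match(orig, bases) - 1L + shift[sel]) %% 4L + 1L]
        x <- seqs[ri]; substring(x, po, po) <- newb; seqs[ri] <- x
        q <- quals[ri]; substring(q, po, po) <- "5"; quals[ri] <- q  # Q20
      }
      err_pos[unique(ridx)] <- split(within, ridx)
    }
  }
  list(seqs = seqs, quals = quals, err_pos = err_pos)
}

#' Simulate a full sequencing run
#'
#' For every sample on the sheet, draws an allele (reference or edited,
#' by dosage) per fragment, constructs mate 1 as forward frameshift bases
#' followed by the template and mate 2 as the reverse analogue on the
#' reverse complement, truncates reads at the template end when it is
#' reached, injects iid substitution errors, and annotates each pair with
#' the sample's plate index. Qualities are two-level and truth-aware: Q37
#' everywhere except Q20 at errored bases. A truth table records, per
#' pair, the source sample, drawn allele, error positions, and whether an
#' error fell inside either k-base secondary-barcode prefix.
#'
#' @param sheet Sample sheet from [make_sample_sheet()].
#' @param table The `barcode_table` used for the sheet.
#' @param ref An [amplicon_reference()].
#' @param edits List of [edit_spec()] (at most one per sample; samples
#'   without one are wild type), or NULL for an all-wild-type run.
#' @param coverage A [coverage_model()]. Skew multipliers are assigned to
#'   samples at exact fractional counts, in randomized order.
#' @param read_len 150 or 250.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed; fixed seed gives byte-identical runs.
#' @param out_dir Optional directory: writes `R1.fastq.gz`, `R2.fastq.gz`,
#'   `truth.tsv`, `sample_sheet.tsv`, `barcode_table.tsv`.
#' @return List: `pairs` (read-pair data.frame), `truth` (data.frame:
#'   `read_id`, `sample_id`, `allele`, `n_errors`, `err1`, `err2`,
#'   `prefix_error`), `sheet`, `table`, `ref`.
#' @export
simulate_run <- function(sheet, table, ref, edits = NULL,
                         coverage = coverage_model(), read_len = 150L,
                         error_rate = 0, seed = NULL, out_dir = NULL) {
  if (!read_len %in% c(150L, 250L))
    stop2("read_len must be 150 or 250")
  if (!is.null(seed)) set.seed(seed)
  k <- attr(table, "k")
  n <- nrow(sheet)
  edits <- edits %||% list()
  if (inherits(edits, "edit_spec")) edits <- list(edits)
  emap <- setNames(edits, vapply(edits, `[[`, "", "sample_id"))
  if (!all(names(emap) %in% sheet$sample_id))
    stop2("edit specs reference samples absent from the sheet")

  # exact skew-group sizes, randomized assignment to samples
  sk <- coverage$skew
  counts <- floor(sk$fraction * n)
  rem <- n - sum(counts)
  if (rem > 0L) counts[order(sk$fraction * n - counts,
                             decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(sk$fraction * n - counts,
                   decreasing = TRUE)[seq_len(rem)]] + 1L
  mult <- rep(sk$multiplier, counts)[sample.int(n)]
  n_pairs <- pmax(1L, as.integer(round(coverage$target_pairs_per_sample * mult)))

  tab_key <- paste(table$fwd_primer_id, table$rev_primer_id)
  truncated <- FALSE
  all_s1 <- all_s2 <- all_id <- all_idx <- all_sample <- all_allele <-
    vector("list", n)
  for (i in seq_len(n)) {
    sid <- sheet$sample_id[i]
    te <- table[match(paste(sheet$fwd_primer_id[i], sheet$rev_primer_id[i]),
                      tab_key), ]
    fs_f <- substr(te$fwd_prefix9, 1L, te$fwd_fs_len)
    fs_r <- substr(te$rev_prefix9, 1L, te$rev_fs_len)
    spec <- emap[[sid]]
    p_edit <- if (is.null(spec)) 0 else
      if (spec$type == "NONE") 0 else edited_fraction(spec$dosage)
    tpl_edit <- if (is.null(spec)) ref$seq else apply_edit(ref, spec)
    m <- n_pairs[i]
    is_edit <- if (p_edit == 0) rep(FALSE, m) else
      if (p_edit == 1) rep(TRUE, m) else as.logical(rbinom(m, 1L, p_edit))
    build <- function(tpl, fs, rc) {
      body <- if (rc) revcomp(tpl) else tpl
      full <- paste0(fs, body)
      if (nchar(full) < read_len) truncated <<- TRUE
      substr(full, 1L, read_len)
    }
    r1 <- ifelse(is_edit, build(tpl_edit, fs_f, FALSE),
                 build(ref$seq, fs_f, FALSE))
    r2 <- ifelse(is_edit, build(tpl_edit, fs_r, TRUE),
                 build(ref$seq, fs_r, TRUE))
    all_s1[[i]] <- r1
    all_s2[[i]] <- r2
    all_id[[i]] <- sprintf("%s_%06d", sid, seq_len(m))
    all_idx[[i]] <- rep(sheet$index_seq[i], m)
    all_sample[[i]] <- rep(sid, m)
    all_allele[[i]] <- ifelse(is_edit, "edited", "ref")
  }
  if (truncated)
    warning("read_len exceeds frameshift + template for some alleles; reads truncated at template end",
            call. = FALSE)

  s1 <- unlist(all_s1); s2 <- unlist(all_s2)
  e1 <- inject_errors(s1, error_rate)
  e2 <- inject_errors(s2, error_rate)
  join <- function(x) vapply(x, function(p)
    if (is.null(p)) "" else paste(p, collapse = ","), "")
  prefix_err <- vapply(seq_along(s1), function(j) {
    any(e1$err_pos[[j]] <= k) || any(e2$err_pos[[j]] <= k)
  }, NA)
  pairs <- data.frame(read_id = unlist(all_id),
                      seq1 = e1$seqs, qual1 = e1$quals,
                      seq2 = e2$seqs, qual2 = e2$quals,
                      index_seq = unlist(all_idx),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = pairs$read_id,
                      sample_id = unlist(all_sample),
                      allele = unlist(all_allele),
                      n_errors = lengths(e1$err_pos) + lengths(e2$err_pos),
                      err1 = join(e1$err_pos), err2 = join(e2$err_pos),
                      prefix_error = prefix_err,
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs, truth = truth, sheet = sheet, table = table,
              ref = ref)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq_pairs(pairs, file.path(out_dir, "R1.fastq.gz"),
                      file.path(out_dir, "R2.fastq.gz"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_barcode_table(table, file.path(out_dir, "barcode_table.tsv"))
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
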