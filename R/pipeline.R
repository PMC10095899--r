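# Single entry point chaining design -> simulate -> demux -> genotype ->
# report, with a manifest of parameters, counts and output checksums.

#' Build a pipeline configuration
#'
#' All knobs of the simulated screen in one validated list. File-based
#' inputs (an existing reference FASTA and target BED) may replace the
#' built-in synthetic design.
#'
#' @param out_dir Output directory.
#' @param n_samples Number of samples.
#' @param read_len 150 or 250.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed for the simulation.
#' @param target_pairs Aimed-for pairs per sample.
#' @param skew Skew data.frame for [coverage_model()], or NULL for uniform
#'   coverage.
#' @param edits `"auto"` (cycle wild type / heterozygous insertion /
#'   homozygous deletion across samples), NULL (all wild type), or a list
#'   of [edit_spec()].
#' @param reference_fasta,target_bed Optional file inputs overriding the
#'   default synthetic reference.
#' @param max_mismatch Primary demultiplexing mismatch allowance.
#' @param aln_params [align_params()].
#' @param gt_params [genotype_params()].
#' @param write_per_sample_fastq Write one FASTQ pair per sample?
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, n_samples = 96L, read_len = 150L,
                       error_rate = 0, seed = 1L, target_pairs = 200,
                       skew = NULL, edits = "auto",
                       reference_fasta = NULL, target_bed = NULL,
                       max_mismatch = 1L, aln_params = align_params(),
                       gt_params = genotype_params(),
                       write_per_sample_fastq = FALSE) {
  if (!is.null(reference_fasta) && !file.exists(reference_fasta))
    stop2(sprintf("reference FASTA not found: %s", reference_fasta))
  if (!is.null(target_bed) && !file.exists(target_bed))
    stop2(sprintf("target BED not found: %s", target_bed))
  if (!read_len %in% c(150L, 250L)) stop2("read_len must be 150 or 250")
  if (error_rate < 0 || error_rate > 0.5) stop2("error_rate out of range")
  structure(list(out_dir = out_dir, n_samples = as.integer(n_samples),
                 read_len = as.integer(read_len), error_rate = error_rate,
                 seed = as.integer(seed), target_pairs = target_pairs,
                 skew = skew, edits = edits,
                 reference_fasta = reference_fasta, target_bed = target_bed,
                 max_mismatch = as.integer(max_mismatch),
                 aln_params = aln_params, gt_params = gt_params,
                 write_per_sample_fastq = isTRUE(write_per_sample_fastq)),
            class = "run_config")
}

#' Read a key = value run configuration file
#'
#' Simple text dialect: one `key = value` per line, `#` comments. Keys
#' match the arguments of [run_config()] (scalar ones only).
#'
#' @param path Config file.
#' @param out_dir Output directory (overrides any `out_dir` in the file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  args <- as.list(vals)
  names(args) <- keys
  num_keys <- c("n_samples", "read_len", "error_rate", "seed",
                "target_pairs", "max_mismatch")
  for (k in intersect(names(args), num_keys)) args[[k]] <- as.numeric(args[[k]])
  if (!is.null(out_dir)) args$out_dir <- out_dir
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0L)
    stop2(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, args)
}

#' Example planted-edit panel
#'
#' Cycles samples through wild type, heterozygous 1-bp insertion at the
#' first cut site, and homozygous 4-bp deletion at the second cut site --
#' the canonical NHEJ outcomes a screen must separate.
#'
#' @param sheet Sample sheet.
#' @param ref An [amplicon_reference()].
#' @return List of [edit_spec()] with attribute `truth_class` (named
#'   character: expected zygosity class per sample).
#' @export
example_edits <- function(sheet, ref = default_reference()) {
  cut1 <- ref$target_windows[1, 1] + 10L   # cut site at window center
  cut2 <- ref$target_windows[2, 1] + 10L
  n <- nrow(sheet)
  kind <- rep_len(c("wt", "het_ins", "hom_del"), n)
  edits <- list()
  truth <- character(n)
  names(truth) <- sheet$sample_id
  for (i in seq_len(n)) {
    sid <- sheet$sample_id[i]
    e <- switch(kind[i],
      wt = edit_spec(sid, "NONE"),
      het_ins = edit_spec(sid, "INS", position = cut1 - 1L, payload = "T",
                          dosage = "1/2"),
      hom_del = edit_spec(sid, "DEL", position = cut2 - 2L, payload = 4L,
                          dosage = "2/2"))
    edits[[i]] <- e
    truth[i] <- switch(kind[i], wt = "wild_type", het_ins = "heterozygous",
                       hom_del = "homozygous")
  }
  attr(edits, "truth_class") <- truth
  edits
}

#' Run the full simulated screen
#'
#' Stages in order: design (or file-based reference), read simulation,
#' primary and secondary demultiplexing, per-sample genotyping, VCF and
#' report emission, and a JSON manifest with parameters, per-stage counts
#' and MD5 checksums of every output file. Counts must reconcile exactly
#' across stages or the run aborts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `genotypes`, `truth`, `truth_class`,
#'   `counts`, `report`, `files`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- design
  ref <- if (is.null(config$reference_fasta)) default_reference() else {
    fa <- read_fasta(config$reference_fasta)
    tw <- if (is.null(config$target_bed)) stop2("target_bed required with reference_fasta")
          else read_target_bed(config$target_bed)
    amplicon_reference(names(fa)[1], fa[[1]], tw)
  }
  table <- default_barcode_table(ref)
  n_plates <- ceiling(config$n_samples / nrow(table))
  indices <- default_plate_indices(max(n_plates, 1L))
  sheet <- make_sample_sheet(config$n_samples, table, indices)

  # --- simulate
  cov <- if (is.null(config$skew))
    coverage_model(config$target_pairs,
                   data.frame(fraction = 1, multiplier = 1))
  else coverage_model(config$target_pairs, config$skew)
  edits <- config$edits
  truth_class <- NULL
  if (identical(edits, "auto")) {
    edits <- example_edits(sheet, ref)
    truth_class <- attr(edits, "truth_class")
  }
  sim <- simulate_run(sheet, table, ref, edits = edits, coverage = cov,
                      read_len = config$read_len,
                      error_rate = config$error_rate, seed = config$seed)

  # --- demultiplex
  pd <- primary_demux(sim$pairs, indices, config$max_mismatch)
  sec <- lapply(names(pd$plates), function(pid)
    secondary_demux(pd$plates[[pid]], table, sheet, pid))
  names(sec) <- names(pd$plates)
  report <- demux_report(pd, lapply(sec, `[[`, "report"),
                         path = file.path(config$out_dir, "demux_report.tsv"))

  # --- genotype
  tab_key <- paste(table$fwd_primer_id, table$rev_primer_id)
  genotypes <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    te <- table[match(paste(sheet$fwd_primer_id[i], sheet$rev_primer_id[i]),
                      tab_key), ]
    sp <- sec[[sheet$plate_index_id[i]]]$samples[[sid]]
    if (is.null(sp)) sp <- sim$pairs[0, ]
    genotypes[[i]] <- genotype_sample(sp, sid, te$fwd_fs_len, te$rev_fs_len,
                                      ref, config$aln_params,
                                      config$gt_params)
  }
  names(genotypes) <- sheet$sample_id

  # --- outputs
  files <- c(demux_report = file.path(config$out_dir, "demux_report.tsv"),
             demux_report_json = file.path(config$out_dir,
                                           "demux_report.tsv.json"))
  vcf <- file.path(config$out_dir, "genotypes.vcf")
  tsv <- file.path(config$out_dir, "genotypes.tsv")
  filter_and_write_vcf(genotypes, ref, vcf, tsv)
  truth_path <- file.path(config$out_dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, vcf = vcf, genotype_tsv = tsv, truth = truth_path)
  if (config$write_per_sample_fastq) {
    fq_dir <- file.path(config$out_dir, "per_sample_fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (s in sec) for (sid in names(s$samples)) {
      if (nrow(s$samples[[sid]]) == 0L) next
      write_fastq_pairs(s$samples[[sid]],
                        file.path(fq_dir, sprintf("%s_R1.fastq.gz", sid)),
                        file.path(fq_dir, sprintf("%s_R2.fastq.gz", sid)))
    }
  }

  # --- count reconciliation
  n_sim <- nrow(sim$pairs)
  n_primary <- pd$n_undetermined + sum(vapply(pd$plates, nrow, 0L))
  n_secondary <- sum(vapply(sec, function(s) s$report$total_pairs, 0L))
  n_assigned <- sum(vapply(sec, function(s) s$report$n_assigned, 0L))
  n_unassigned <- sum(vapply(sec, function(s) s$report$n_unassigned, 0L))
  gt_pairs <- sum(vapply(genotypes, function(g) g$counts[["n_pairs"]], 0))
  counts <- c(simulated_pairs = n_sim,
              primary_total = n_primary,
              undetermined_primary = pd$n_undetermined,
              secondary_total = n_secondary,
              assigned = n_assigned,
              unassigned_secondary = n_unassigned,
              genotyped_pairs = gt_pairs,
              discarded_short = sum(vapply(genotypes, function(g)
                g$counts[["n_discarded"]], 0)),
              unalignable_reads = sum(vapply(genotypes, function(g)
                g$counts[["n_unalignable"]], 0)),
              aligned_reads = sum(vapply(genotypes, function(g)
                g$counts[["n_aligned_reads"]], 0)))
  if (n_sim != n_primary || n_secondary + pd$n_undetermined != n_sim ||
      n_assigned + n_unassigned != n_secondary || gt_pairs != n_assigned)
    stop2("pipeline stage counts do not reconcile")

  manifest <- list(
    package_version = as.character(utils::packageVersion("crispgeno")),
    seed = config$seed,
    parameters = config[c("n_samples", "read_len", "error_rate",
                          "target_pairs", "max_mismatch")],
    counts = as.list(counts),
    assigned_fraction = report$assigned_fraction,
    files = lapply(as.list(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(genotypes = genotypes, truth = sim$truth,
                 truth_class = truth_class, counts = counts,
                 report = report, files = files,
                 manifest = manifest_path, ref = ref, sheet = sheet))
}
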