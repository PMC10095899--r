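# VCF 4.2 and SAM emission.

#' Write genotypes to a multi-sample VCF and a per-sample TSV
#'
#' Emits one VCF 4.2 sample column per plant with FORMAT `GT:DP:AD`:
#' `1/1` for homozygous, `0/1` for heterozygous, `./.` for mixed or
#' low-coverage samples, `0/0` elsewhere. Only calls inside the target
#' windows are written. The TSV lists each sample's class, mean target
#' depth and a variant summary.
#'
#' @param genotypes List of `sample_genotype` objects.
#' @param ref An [amplicon_reference()].
#' @param vcf_path Output VCF path.
#' @param tsv_path Optional per-sample TSV path.
#' @return Invisibly, the data.frame of unique variant rows.
#' @export
filter_and_write_vcf <- function(genotypes, ref, vcf_path, tsv_path = NULL) {
  for (g in genotypes) {
    if (!inherits(g, "sample_genotype")) stop2("expected sample_genotype objects")
  }
  sample_ids <- vapply(genotypes, `[[`, "", "sample_id")
  wcalls <- lapply(genotypes, function(g) calls_in_windows(g$calls, ref))

  allc <- do.call(rbind, wcalls)
  variants <- if (!is.null(allc) && nrow(allc) > 0L)
    unique(allc[, c("pos", "ref", "alt", "type")]) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               type = character(0))
  variants <- variants[order(variants$pos, variants$alt), , drop = FALSE]
  rownames(variants) <- NULL

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=crispgeno",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, nchar(ref$seq)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))

  body <- character(0)
  if (nrow(variants) > 0L) {
    body <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      quals <- numeric(0)
      cols <- vapply(seq_along(genotypes), function(s) {
        g <- genotypes[[s]]
        cs <- wcalls[[s]]
        hit <- which(cs$pos == v$pos & cs$ref == v$ref & cs$alt == v$alt)
        if (length(hit) == 1L) {
          quals <<- c(quals, cs$qual[hit])
          gt <- switch(g$class, homozygous = "1/1", heterozygous = "0/1",
                       "./.")
          sprintf("%s:%d:%d,%d", gt, cs$DP[hit], cs$AD_ref[hit],
                  cs$AD_alt[hit])
        } else if (g$class == "low_coverage") {
          sprintf("./.:%d:.", as.integer(round(g$mean_target_depth)))
        } else {
          dp <- as.integer(round(g$mean_target_depth))
          sprintf("0/0:%d:%d,0", dp, dp)
        }
      }, "")
      paste(c(ref$name, v$pos, ".", v$ref, v$alt,
              sprintf("%.1f", mean(quals)), "PASS",
              paste0("TYPE=", v$type), "GT:DP:AD", cols), collapse = "\t")
    }, "")
  }
  writeLines(c(hdr, body), vcf_path)

  if (!is.null(tsv_path)) {
    tsv <- data.frame(
      sample_id = sample_ids,
      class = vapply(genotypes, `[[`, "", "class"),
      mean_target_depth = round(vapply(genotypes, `[[`, 0,
                                       "mean_target_depth"), 2),
      n_variants = vapply(wcalls, nrow, 0L),
      variants = vapply(wcalls, function(cs) {
        if (nrow(cs) == 0L) return("")
        paste(sprintf("%d:%s>%s@%.2f", cs$pos, cs$ref, cs$alt, cs$AF),
              collapse = ";")
      }, ""), stringsAsFactors = FALSE)
    write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(variants)
}

#' Export alignments as SAM text
#'
#' Minimal SAM 1.6 single-end records (mate 2 flagged as reverse strand)
#' for inspection in genome viewers or conversion with samtools; provided
#' for parity checks against external aligner/caller chains.
#'
#' @param alignments Alignment data.frame from [align_sample()].
#' @param ref An [amplicon_reference()].
#' @param path Output SAM path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(alignments, ref, path) {
  a <- alignments[alignments$aligned, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, nchar(ref$seq)),
           "@PG\tID:crispgeno\tPN:crispgeno")
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 a$read_id, ifelse(a$mate == 2L, 16L, 0L), ref$name,
                 a$ref_start + 1L, a$cigar, a$seq, a$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read target windows from a BED file
#'
#' @param path BED path (0-based half-open, first three columns used).
#' @return Two-column integer matrix of windows.
#' @export
read_target_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  matrix(c(as.integer(bed[[2]]), as.integer(bed[[3]])), ncol = 2)
}
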