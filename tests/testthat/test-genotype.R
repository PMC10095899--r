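perfect_pairs <- function(seqs1, seqs2, ids = sprintf("r%03d", seq_along(seqs1))) {
  data.frame(read_id = ids, seq1 = seqs1, qual1 = strrep("F", nchar(seqs1)),
             seq2 = seqs2, qual2 = strrep("F", nchar(seqs2)),
             index_seq = "AAAAAAAA", stringsAsFactors = FALSE)
}

test_that("trim_prefix removes exactly the frameshift bases, in register", {
  p <- perfect_pairs("ACGTACGTAC", "TTGCAACGTT")
  t0 <- trim_prefix(p, 0L, 0L)
  expect_identical(t0$pairs, p)
  t3 <- trim_prefix(p, 3L, 2L)
  expect_equal(t3$pairs$seq1, "TACGTAC")
  expect_equal(nchar(t3$pairs$qual1), 7L)
  expect_equal(t3$pairs$seq2, "GCAACGTT")
  expect_equal(t3$n_discarded, 0L)

  long <- perfect_pairs(strrep("A", 150), strrep("A", 150))
  expect_equal(nchar(trim_prefix(long, 2L, 0L)$pairs$seq1), 148L)

  short <- perfect_pairs("AC", "ACGT")
  tr <- trim_prefix(short, 3L, 0L)
  expect_equal(tr$n_discarded, 1L)
  expect_equal(nrow(tr$pairs), 0L)
})

test_that("aligner recovers exact substrings and simple indels", {
  ref <- amplicon_reference("r", "ACGTACGTACGT", rbind(c(0, 12)))
  a <- align_reads("GTACGTAC", ref)
  expect_true(a$aligned)
  expect_equal(a$cigar, "8M")
  expect_equal(a$ref_start, 2L)
  expect_equal(a$score, 16L)

  d <- align_reads("ACGTCGTACGT", ref, align_params(band = 300))
  expect_equal(d$cigar, "4M1D7M")
  expect_equal(d$ref_start, 0L)
  expect_equal(d$score, 11L * 2L - 7L)

  # garbage read is marked unalignable and excluded
  g <- align_reads(strrep("T", 40), ref)
  expect_false(g$aligned)
})

test_that("banded alignment equals the full dynamic program within band validity", {
  set.seed(501)
  refseq <- random_seq(211)
  ref <- amplicon_reference("r", refseq, rbind(c(0, 211)))
  for (i in 1:50) {
    # read from the amplicon start or end with a small planted indel:
    # band 32 covers 2x the length difference plus the edit distance
    from_start <- i %% 2 == 0
    rd <- if (from_start) substr(refseq, 1, 60) else substr(refseq, 152, 211)
    p <- sample(10:50, 1); L <- sample(1:5, 1)
    rd <- if (i %% 3 == 0)
      paste0(substr(rd, 1, p), substr(rd, p + L + 1, nchar(rd)))
    else
      paste0(substr(rd, 1, p), random_seq(L), substr(rd, p + 1, nchar(rd)))
    banded <- align_reads(rd, ref, align_params(band = 32))$score
    full <- align_reads(rd, ref, align_params(band = 1000))$score
    expect_equal(banded, full, info = rd)
  }
})

test_that("scores match an independent affine-gap implementation", {
  skip_if_not_installed("Biostrings")
  set.seed(502)
  refseq <- random_seq(150)
  ref <- amplicon_reference("r", refseq, rbind(c(0, 150)))
  for (i in 1:40) {
    rd <- substr(refseq, sample(1:40, 1), sample(90, 1) + 50)
    ch <- strsplit(rd, "")[[1]]
    for (j in sample(length(ch), sample(0:3, 1)))
      ch[j] <- sample(BASES, 1)
    rd <- paste(ch, collapse = "")
    expect_equal(align_reads(rd, ref)$score,
                 biostrings_glocal_score(rd, refseq), info = rd)
  }
})

test_that("pileup counts depth, alleles and events with quality filtering", {
  refseq <- substr(default_reference()$seq, 1, 40)   # repeat-free fixture
  ref <- amplicon_reference("r", refseq, rbind(c(0, 40)))
  p <- perfect_pairs(rep(substr(refseq, 1, 20), 10),
                     rep(revcomp(substr(refseq, 21, 40)), 10))
  al <- align_sample(p, ref)
  pu <- build_pileup(al$alignments, ref)
  expect_equal(pu$depth, rep(10L, 40))
  alt_total <- sum(pu$base_counts) - sum(vapply(1:40, function(i)
    pu$base_counts[substr(refseq, i, i), i], 0L))
  expect_equal(alt_total, 0L)
  expect_equal(nrow(pu$ins_events), 0L)

  # 6 reads with a 1-base insertion, 4 without: anchor count 6, depth 10
  ins_read <- paste0(substr(refseq, 1, 10), "T", substr(refseq, 11, 20))
  p2 <- perfect_pairs(c(rep(ins_read, 6), rep(substr(refseq, 1, 20), 4)),
                      rep(revcomp(substr(refseq, 21, 40)), 10))
  pu2 <- build_pileup(align_sample(p2, ref)$alignments, ref)
  expect_equal(sum(pu2$ins_events$count), 6L)
  expect_equal(pu2$depth[10], 10L)

  # a low-quality mismatch contributes depth but no allele count
  mm <- substr(refseq, 1, 20)
  substring(mm, 5, 5) <- "T"
  q <- strrep("F", 20); substring(q, 5, 5) <- "#"   # Q2
  p3 <- data.frame(read_id = "x", seq1 = mm, qual1 = q,
                   seq2 = revcomp(substr(refseq, 21, 40)),
                   qual2 = strrep("F", 20), index_seq = "A")
  pu3 <- build_pileup(align_sample(p3, ref)$alignments, ref)
  expect_equal(pu3$depth[5], 1L)
  expect_equal(unname(pu3$base_counts["T", 5]), 0L)
})

test_that("variant caller applies frequency and count thresholds", {
  refseq <- default_reference()$seq
  ref <- default_reference()
  ins_tpl <- apply_edit(ref, edit_spec("s", "INS", position = 56L,
                                       payload = "T", dosage = "2/2"))
  n_alt <- 520; n_ref <- 480
  p <- perfect_pairs(c(rep(substr(ins_tpl, 1, 150), n_alt),
                       rep(substr(refseq, 1, 150), n_ref)),
                     rep(revcomp(substr(refseq, 62, 211)), 1000))
  pu <- build_pileup(align_sample(p, ref)$alignments, ref)
  calls <- call_variants(pu, ref)
  ins <- calls[calls$type == "INS", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$AD_alt, 520L)
  expect_equal(ins$AD_ref, 480L)
  expect_equal(ins$AF, 0.52)

  # 5% allele: below the default min_af, no call
  p5 <- perfect_pairs(c(rep(substr(ins_tpl, 1, 150), 50),
                        rep(substr(refseq, 1, 150), 950)),
                      rep(revcomp(substr(refseq, 62, 211)), 1000))
  pu5 <- build_pileup(align_sample(p5, ref)$alignments, ref)
  expect_equal(nrow(call_variants(pu5, ref)), 0L)
})

test_that("indel normalization is leftmost and idempotent", {
  set.seed(503)
  for (i in 1:40) {
    refseq <- random_seq(60)
    if (i %% 2 == 0) {
      len <- sample(1:4, 1)
      pos <- sample(5:(60 - len - 1), 1)
      got <- normalize_indel(refseq, "DEL", pos, len)
      expect_equal(got$pos0, exhaustive_leftmost(refseq, "DEL", pos, len))
      expect_identical(normalize_indel(refseq, "DEL", got$pos0, got$allele),
                       got)                               # idempotent
    } else {
      seq <- random_seq(sample(1:3, 1))
      pos <- sample(2:58, 1)
      got <- normalize_indel(refseq, "INS", pos, seq)
      expect_equal(got$pos0, exhaustive_leftmost(refseq, "INS", pos, seq))
      expect_identical(normalize_indel(refseq, "INS", got$pos0, got$allele),
                       got)
    }
  }
  # homopolymer deletion placed rightmost by a read left-aligns fully
  expect_equal(normalize_indel("GGAAAATT", "DEL", 5, 1)$pos0, 2L)
})

test_that("allele depths never exceed site depth", {
  set.seed(504)
  d <- small_design(3, 1)
  edits <- list(edit_spec("S0001", "INS", 56L, "T", "1/2"),
                edit_spec("S0002", "DEL", 127L, 4L, 0.3))
  sim <- simulate_run(d$sheet, d$tab, d$ref, edits,
                      coverage = coverage_model(60, data.frame(fraction = 1,
                                                               multiplier = 1)),
                      error_rate = 0.02, seed = 31)
  sec <- secondary_demux(sim$pairs, d$tab, d$sheet, "IDX01")
  for (sid in names(sec$samples)) {
    pu <- build_pileup(align_sample(sec$samples[[sid]], d$ref)$alignments,
                       d$ref)
    for (pos in seq_along(pu$depth)) {
      allele_sum <- sum(pu$base_counts[, pos]) + pu$del_span[pos]
      expect_lte(allele_sum, pu$depth[pos])
    }
  }
})

test_that("zygosity classification follows the threshold table", {
  ref <- default_reference()
  mk_pu <- function(depth) {
    structure(list(depth = rep(depth, nchar(ref$seq)),
                   base_counts = matrix(0L, 4, nchar(ref$seq),
                                        dimnames = list(c("A","C","G","T"),
                                                        NULL)),
                   qual_sums = matrix(0, 4, nchar(ref$seq)),
                   del_span = rep(0L, nchar(ref$seq)),
                   ins_events = data.frame(), del_events = data.frame(),
                   n_reads = depth), class = "pileup")
  }
  call_row <- function(af, pos = 58L, alt = "AT") {
    data.frame(pos = pos, ref = "A", alt = alt, type = "INS", DP = 200L,
               AD_ref = as.integer(200 * (1 - af)),
               AD_alt = as.integer(200 * af), AF = af, qual = 37)
  }
  cls <- function(calls, depth = 200) {
    classify_genotype(calls, ref, mk_pu(depth), "s")$class
  }
  expect_equal(cls(call_row(1.00)), "homozygous")
  expect_equal(cls(call_row(0.90)), "homozygous")
  expect_equal(cls(call_row(0.50)), "heterozygous")
  expect_equal(cls(call_row(0.35)), "heterozygous")
  expect_equal(cls(call_row(0.70)), "mixed")            # between bands
  expect_equal(cls(call_row(0.20)), "mixed")
  expect_equal(cls(rbind(call_row(0.45), call_row(0.40, alt = "ATT"))),
               "mixed")                                  # two alts, chimeric
  expect_equal(cls(call_row(0.50)[0, ]), "wild_type")
  expect_equal(cls(call_row(0.50), depth = 10), "low_coverage")
  # calls outside the target windows never drive the class
  expect_equal(cls(call_row(0.50, pos = 5L)), "wild_type")
})

test_that("VCF output round-trips through an independent parser", {
  skip_if_not_installed("vcfR")
  d <- small_design(3, 1)
  edits <- example_edits(d$sheet, d$ref)
  sim <- simulate_run(d$sheet, d$tab, d$ref, edits,
                      coverage = coverage_model(100, data.frame(fraction = 1,
                                                                multiplier = 1)),
                      error_rate = 0, seed = 32)
  sec <- secondary_demux(sim$pairs, d$tab, d$sheet, "IDX01")
  tab_key <- paste(d$tab$fwd_primer_id, d$tab$rev_primer_id)
  gts <- lapply(seq_len(3), function(i) {
    te <- d$tab[match(paste(d$sheet$fwd_primer_id[i], d$sheet$rev_primer_id[i]),
                      tab_key), ]
    genotype_sample(sec$samples[[d$sheet$sample_id[i]]], d$sheet$sample_id[i],
                    te$fwd_fs_len, te$rev_fs_len, d$ref)
  })
  vcf_path <- tempfile(fileext = ".vcf")
  vars <- filter_and_write_vcf(gts, d$ref, vcf_path,
                               tsv_path = tempfile(fileext = ".tsv"))
  expect_equal(nrow(vars), 2L)   # het insertion + hom deletion

  v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  expect_equal(as.integer(vcfR::getPOS(v)), vars$pos)
  expect_equal(vcfR::getREF(v), vars$ref)
  expect_equal(vcfR::getALT(v), vars$alt)
  gt <- vcfR::extract.gt(v)
  classes <- vapply(gts, `[[`, "", "class")
  expect_equal(unname(gt[, classes == "heterozygous"]) %in%
                 c("0/1", "0/0") , c(TRUE, TRUE))
  hom_col <- gt[, classes == "homozygous"]
  expect_true("1/1" %in% hom_col)
  wt_col <- gt[, classes == "wild_type"]
  expect_true(all(wt_col == "0/0"))
})

test_that("SAM export is accepted by an external toolkit", {
  d <- small_design(2, 1)
  sim <- simulate_run(d$sheet, d$tab, d$ref,
                      coverage = coverage_model(10, data.frame(fraction = 1,
                                                               multiplier = 1)),
                      error_rate = 0, seed = 33)
  al <- align_sample(trim_prefix(sim$pairs, 0L, 0L)$pairs, d$ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(al$alignments, d$ref, sam)
  if (nzchar(Sys.which("samtools"))) {
    out <- system2("samtools", c("view", "-c", sam), stdout = TRUE,
                   stderr = TRUE)
    expect_equal(as.integer(out[length(out)]), sum(al$alignments$aligned))
  } else {
    first <- readLines(sam, n = 1)
    expect_match(first, "^@HD")
  }
})
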