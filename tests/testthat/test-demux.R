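make_pairs <- function(seq1, seq2, index, ids = NULL) {
  n <- length(seq1)
  data.frame(read_id = ids %||% sprintf("r%03d", seq_len(n)),
             seq1 = seq1, qual1 = strrep("F", nchar(seq1)),
             seq2 = seq2, qual2 = strrep("F", nchar(seq2)),
             index_seq = index, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("primary demux applies the unique-within-distance rule", {
  idx <- data.frame(id = c("P1", "P2"), seq = c("AAAAAAAA", "CCCCAAAA"))
  p <- make_pairs(rep("ACGT", 4), rep("ACGT", 4),
                  c("AAAAAAAA",      # exact
                    "AAAAAAAT",      # one mismatch, unique neighbour
                    "CCAAAAAA",      # distance 2 from P1, 2 from P2
                    "CCCAAAAA"))     # distance 3/1: unique neighbour P2
  res <- primary_demux(p, idx, max_mismatch = 1)
  expect_equal(res$per_plate_counts, c(P1 = 2L, P2 = 1L))
  expect_equal(res$n_undetermined, 1L)
  expect_equal(res$plates$P2$read_id, "r004")

  # equidistant between two indices at distance 1 each -> undetermined
  idx2 <- data.frame(id = c("A", "B"), seq = c("AAAAAAAA", "AAAAAATT"))
  amb <- make_pairs("ACGT", "ACGT", "AAAAAAAT")
  res2 <- primary_demux(amb, idx2, max_mismatch = 1)
  expect_equal(res2$n_undetermined, 1L)

  # zero-mismatch mode only takes exact hits
  res3 <- primary_demux(p, idx, max_mismatch = 0)
  expect_equal(sum(res3$per_plate_counts), 1L)
})

test_that("pairs without an index annotation are undetermined with a warning", {
  idx <- data.frame(id = "P1", seq = "AAAAAAAA")
  p <- make_pairs(c("ACGT", "ACGT"), c("ACGT", "ACGT"),
                  c(NA, "AAAAAAAA"))
  expect_warning(res <- primary_demux(p, idx), "without a valid index")
  expect_equal(res$n_undetermined, 1L)
  expect_equal(res$n_missing_index, 1L)
})

test_that("secondary demux is exact-match and never trims", {
  d <- small_design(6, 1)
  sim <- simulate_run(d$sheet, d$tab, d$ref,
                      coverage = coverage_model(20, data.frame(fraction = 1,
                                                               multiplier = 1)),
                      error_rate = 0, seed = 21)
  sec <- secondary_demux(sim$pairs, d$tab, d$sheet, "IDX01")
  expect_equal(sec$report$n_assigned, nrow(sim$pairs))
  expect_equal(sec$report$assigned_fraction, 1.0)
  # full round trip: every read back in its source sample, unmodified
  for (sid in names(sec$samples)) {
    got <- sec$samples[[sid]]
    truth_ids <- sim$truth$read_id[sim$truth$sample_id == sid]
    expect_setequal(got$read_id, truth_ids)
    src <- sim$pairs[match(got$read_id, sim$pairs$read_id), ]
    rownames(src) <- rownames(got) <- NULL
    expect_identical(got, src)                     # no trimming, byte-equal
  }

  # one substitution inside a prefix makes the pair unassigned, never moved
  poked <- poke_base(sim$pairs, 1, "seq1", 5)
  sec2 <- secondary_demux(poked, d$tab, d$sheet, "IDX01")
  expect_equal(sec2$report$n_unassigned, 1L)
  expect_equal(sec2$unassigned$read_id, sim$pairs$read_id[1])
  expect_equal(sec2$unassigned$reason, "prefix")
})

test_that("valid-but-unregistered prefix combinations count as chimeric", {
  d <- small_design(2, 1)   # only combos (FSF-0,FSR-0) and (FSF-0,FSR-1)
  tab <- d$tab
  fs1_prefix <- tab$fwd_prefix9[tab$fwd_primer_id == "FSF-1"][1]
  rev0_prefix <- tab$rev_prefix9[tab$rev_primer_id == "FSR-0"][1]
  chim <- make_pairs(paste0(fs1_prefix, strrep("A", 50)),
                     paste0(rev0_prefix, strrep("A", 50)), "X")
  sec <- secondary_demux(chim, tab, d$sheet, "IDX01")
  expect_equal(sec$report$n_chimeric, 1L)
  expect_equal(sec$unassigned$reason, "chimeric")
})

test_that("demux partitions every pair exactly once", {
  set.seed(22)
  d <- small_design(8, 2)
  sim <- simulate_run(d$sheet, d$tab, d$ref,
                      coverage = coverage_model(30, data.frame(fraction = 1,
                                                               multiplier = 1)),
                      error_rate = 0.02, seed = 22)
  pd <- primary_demux(sim$pairs, d$indices)
  total_secondary <- 0L
  for (pid in names(pd$plates)) {
    sec <- secondary_demux(pd$plates[[pid]], d$tab, d$sheet, pid)
    n_in_bins <- sum(vapply(sec$samples, nrow, 0L)) + nrow(sec$unassigned)
    expect_equal(n_in_bins, nrow(pd$plates[[pid]]))
    expect_equal(sec$report$n_assigned + sec$report$n_unassigned,
                 sec$report$total_pairs)
    total_secondary <- total_secondary + sec$report$total_pairs
  }
  expect_equal(total_secondary + pd$n_undetermined, nrow(sim$pairs))
})

test_that("demux is deterministic across repeated runs", {
  d <- small_design(4, 1)
  sim <- simulate_run(d$sheet, d$tab, d$ref,
                      coverage = coverage_model(15, data.frame(fraction = 1,
                                                               multiplier = 1)),
                      error_rate = 0.05, seed = 23)
  run <- function() {
    pd <- primary_demux(sim$pairs, d$indices)
    secondary_demux(pd$plates[[1]], d$tab, d$sheet, names(pd$plates)[1])
  }
  expect_identical(run(), run())
})

test_that("demux_report computes per-plate means and raw-count fractions", {
  rep1 <- list(plate_index_id = "IDX01", n_samples = 96L,
               total_pairs = 98000L, per_sample_counts = integer(0),
               n_assigned = 96000L, n_unassigned = 2000L, n_chimeric = 0L,
               assigned_fraction = 96000 / 98000)
  rep2 <- list(plate_index_id = "IDX02", n_samples = 48L,
               total_pairs = 24000L, per_sample_counts = integer(0),
               n_assigned = 24000L, n_unassigned = 0L, n_chimeric = 0L,
               assigned_fraction = 1)
  rep3 <- list(plate_index_id = "IDX03", n_samples = 10L, total_pairs = 0L,
               per_sample_counts = integer(0), n_assigned = 0L,
               n_unassigned = 0L, n_chimeric = 0L,
               assigned_fraction = NA_real_)
  primary <- list(n_undetermined = 1000L)
  out <- demux_report(primary, list(rep1, rep2, rep3))
  expect_equal(out$per_plate$mean_reads_per_sample, c(1000, 500, 0))
  expect_true(out$per_plate$empty[3])
  expect_equal(out$total_pairs, 123000L)
  # grand fraction from raw counts, not averaged over plates
  expect_equal(out$assigned_fraction, 120000 / 123000)
  expect_equal(out$undetermined_primary + out$unassigned_secondary +
                 out$assigned, out$total_pairs)
})

test_that("FASTQ pair round trip preserves records and index annotation", {
  d <- small_design(2, 1)
  sim <- simulate_run(d$sheet, d$tab, d$ref,
                      coverage = coverage_model(5, data.frame(fraction = 1,
                                                              multiplier = 1)),
                      error_rate = 0, seed = 24)
  r1 <- tempfile(fileext = ".fastq.gz"); r2 <- tempfile(fileext = ".fastq.gz")
  write_fastq_pairs(sim$pairs, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  rownames(back) <- rownames(sim$pairs) <- NULL
  expect_identical(back, sim$pairs)
})
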