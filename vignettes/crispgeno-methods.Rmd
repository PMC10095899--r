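---
title: "crispgeno: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crispgeno: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

CRISPR/Cas9 mutagenesis is easy to perform and hard to read out: editing
efficiency varies between individuals, and error-prone repair (NHEJ)
produces a spectrum of small insertions and deletions at the cut site. A
screen therefore has to sequence the targeted locus in hundreds to
thousands of individuals and decide, per plant, whether it is wild type,
heterozygous, homozygous, or a somatic mosaic. crispgeno implements the
desk side of such a screen built on two-step barcoded amplicon
sequencing, plus a read simulator that provides ground truth for every
downstream claim.

The barcode architecture is two-level. A first PCR adds, on each side of
the locus-specific primer, 0--8 "frameshifting" nucleotides and half of a
TruSeq adapter; a second PCR adds the remaining adapter and one of 96
plate indices. The frameshifting bases stagger the locus primer across
sequencing cycles (helping flowcell base diversity) and double as a
per-sample secondary barcode: with four forward and four reverse
frameshift variants, one plate index distinguishes 16 samples, and 96
indices give 1,536 identities in one run. Demultiplexing is two-stage:
reads are first binned by plate index (one mismatch allowed, ambiguous
pairs discarded), then assigned to samples by *exact* match of the first
nine bases of each mate against the expected frameshift-plus-primer
prefixes. The exact-match regime trades a small, quantifiable loss
(pairs with an error inside a prefix become unassignable) for a strong
guarantee: with a substitution-robust barcode table, a single sequencing
error can never move a read to the wrong sample.

# Guide selection

`scan_pam_sites()` enumerates every 20-mer protospacer 5' of an NGG PAM
on both strands, reporting reverse-strand sites in plus-strand
coordinates. `find_conserved_targets()` intersects these sites with a
haplotype alignment and keeps only windows that are identical and
gap-free across all haplotypes, so that guides work across genetic
backgrounds. The blunt cut is modeled 3 bp 5' of the PAM (between
protospacer positions 17 and 18). That cut offset is standard SpCas9
biology and is stated here as a package assumption, not a measured
quantity.

# The synthetic reference and barcode defaults

The packaged reference (`default_reference()`) is a synthetic 211-bp
amplicon: a fixed random backbone into which the two published guide
protospacers (`example_guides()`) were embedded next to NGG PAMs so that
the two cut sites fall 72 bp apart -- the geometry of a two-site,
single-amplicon screen. The original oligonucleotide table of the
wet-lab protocol is not public, so the default frameshift sequences
(lengths 0--3 per side, one full codon-register cycle, 16 combinations)
and the 96 plate indices are likewise synthetic stand-ins, clearly
flagged as such. They are not arbitrary: the frameshifts were chosen so
the nine-base prefixes on each side are pairwise Hamming distance >= 2
(validated by `validate_barcode_table(robust = TRUE)`), and the indices
form a deterministic lexicographic-greedy code of length 8 with pairwise
distance >= 3, so one-mismatch primary demultiplexing is never
ambiguous. User-supplied designs pass through exactly the same
validation.

# Demultiplexing contract

Each read pair lands in exactly one of three bins -- a sample, the
plate's unassigned bin, or the run's undetermined bin -- and the counts
reconcile exactly; this partition is asserted in the test suite on every
simulated run. Assigned reads are never trimmed at the secondary stage:
the prefixes are part of the amplicon and are removed only later, by
`trim_prefix()`, which cuts exactly the frameshift bases (never the
locus primer) before alignment. Both mates' prefixes must match by
default. Whether the original secondary demultiplexer required one or
both mates is not documented; we read "each read" as both mates and
expose a `mode = "either"` flag for robustness experiments rather than
silently changing the default.

# Alignment

Reads are aligned with a banded glocal dynamic program: global in the
read, local in the reference, affine gaps (match +2, mismatch -4, gap
open 6, gap extend 1; a gap of length L costs open + L x extend). These
defaults favor indel sensitivity on short amplicons. The band
(half-width 32) is placed around candidate diagonals found by exact
12-mer seeds at stride 4, with the amplicon ends as fallback anchors --
in amplicon data mate 1 starts at the reference start and mate 2 ends at
its end, so the fallbacks alone already cover the common case. If no
seeded band reaches the acceptance floor (0.4 x the perfect score), a
full-matrix pass is run before declaring a read unalignable. Traceback
ties prefer match over deletion over insertion, which yields leftmost
indel placement; boundary insertions are reported as soft clips. Mate 2
is reverse-complemented before alignment (standard FR orientation).

The aligner is verified two ways: banded scores equal full-matrix scores
whenever the band covers the edit (property test), and scores equal an
independent affine-gap implementation (`Biostrings::pairwiseAlignment`,
`type = "global-local"`) on 1,000 randomized read/reference instances.
That library is used only as a cross-check oracle, never as the
implementation.

# Pileup, calling, classification

The pileup counts, per reference position, the spanning-read depth and
quality-filtered allele support; bases below Q20 count toward depth but
never toward an allele. Insertions are keyed to the anchor base
immediately 5' of the inserted sequence; deletions to their start and
length. The caller is a deliberate frequency-threshold design with
explicit knobs rather than a diploid likelihood model: an allele is
reported when site depth >= 20, supporting reads >= 5, and allele
frequency >= 0.10. Indels are left-aligned (`normalize_indel()`, checked
against an exhaustive-shift oracle and for idempotence) and anchored
with one reference base per VCF convention.

Zygosity classes are assigned from calls restricted to the target
windows: homozygous at AF >= 0.85; heterozygous at AF in [0.35, 0.65];
anything else supported above 0.10, or any multi-allele site, is
mixed/chimeric; no surviving call is wild type; and a mean window depth
below 20 overrides everything as low coverage. These bands are package
choices -- the upstream toolchain this replaces ran "standard
parameters" whose thresholds are nowhere stated -- and they are surfaced
in `genotype_params()`, not buried. The depth floor of 20 is 2% of the
1,000x coverage aim. At 200x coverage the binomial sampling noise of a
heterozygote's AF has standard deviation ~0.035, so the [0.35, 0.65]
band sits more than 4 sigma from 0.5; at depths of a few dozen reads the
band will occasionally misclassify a true heterozygote as mixed, which
is why the low end of usable coverage matters more than the thresholds
themselves.

# The simulator: what it does and does not emulate

`simulate_run()` fabricates a complete run: per-sample allele draws by
dosage (0/2, 1/2, 2/2 or a somatic fraction), mate construction with the
sample's frameshift prefixes, iid substitution errors at a configurable
rate, plate-index annotation, and a per-read truth table (source sample,
drawn allele, error positions, and whether an error fell in a prefix).
Drawing K ~ Binomial(total bases, rate) error positions uniformly
without replacement is exactly the iid per-base Bernoulli model. The
coverage model reproduces the pooling-skew scenario used for capacity
planning -- 10% of samples at 10x the target, 10% at 0.1x, 80% at 1x,
around a 1,000-pair aim -- with exact group sizes and randomized
assignment; one read pair spans the whole amplicon, so pairs stand in
for fold coverage.

Deliberate simplifications: substitution-only errors (the dominant
Illumina mode; no indel errors, no quality-by-cycle decay -- qualities
are two-level, Q37 clean and Q20 at errored bases, which makes the
caller's quality filter testable against truth), no PCR chimeras, no
duplicate reads, no fragmentation (the fragment is the full amplicon).
Passing tests on this simulator therefore demonstrate the pipeline's
bookkeeping, alignment and thresholds under a clean error model; they do
not demonstrate robustness to chimeric amplicons, index hopping, or
context-dependent error hotspots in real data.

# Pooling arithmetic

`normalization_volumes()` implements the 6/3/1.5 microlitre rule against
the plate mean: 6 ul below half the mean, 1.5 ul above twice the mean, 3
ul otherwise. The inequalities are read strictly, so wells exactly at
half or twice the mean take 3 ul. The rule is scale-invariant.
`equimolar_subpool_volumes()` delivers equal mass per subpool, which is
equal molarity for same-length amplicons. `run_capacity()` divides total
read pairs by the skew-weighted expected pairs per sample (1,810 under
the defaults): 20 million pairs support 11,049 samples. Note that 15
million pairs support only ~8,287 under the same skew; the model is
implemented faithfully rather than tuned so that the lower end of a
15--20 M read run also clears 10,000.

# Numerical and interface choices

Internally all coordinates are 0-based half-open; VCF output is 1-based
with anchored indels. DP tie-breaks are deterministic, so every stage is
reproducible: a fixed seed yields byte-identical FASTQ and identical
output checksums, which the manifest (MD5 per output file) makes
checkable. Degenerate inputs are defined rather than accidental:
sequences shorter than a protospacer-plus-PAM window yield an empty site
list, an all-zero concentration plate is an error (the volume rule is
undefined), an empty plate reports a mean of zero and is flagged, and a
read shorter than its frameshift is discarded and counted.

Problem sizes in the test suite are chosen to keep the full suite under
a minute on one core while preserving the operating points that matter:
the demultiplexing fidelity check runs on ~100,000 pairs across 96
samples, and planted-edit recovery runs 96 samples at 200x with 0.5%
error -- large enough that the thresholds, not luck, determine the
outcome.

# Known limitations

Large deletions that remove a primer binding site produce no amplicon
and therefore escape detection entirely; this is a limitation of the
assay design itself, not of the caller. The genotype model is
frequency-based: it does not compute genotype likelihoods, and it will
report complex events (two distinct indels in trans) as mixed rather
than phasing them. The simulator's clean error model means published
error-rate figures should be re-derived on real data before being relied
on. The secondary demultiplexer is exact-match by design; lowering k or
allowing mismatches would trade its zero-misassignment guarantee for
yield.
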