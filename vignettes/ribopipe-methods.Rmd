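---
title: "ribopipe: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribopipe: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the data model, the
rules each stage applies, the statistics and their decision rules, what the
synthetic-data generator does and does not emulate, and the design choices
made where several defensible options existed.

## The data model

Ribosome profiling reads are ~28–32 nt fragments protected by translating
ribosomes. `ribopipe` maps them against an *ORF-centric* reference: one
transcript per gene, laid out as

```
[ 5' UTR buffer | ORF: ATG ... stop (length % 3 == 0) | 3' UTR buffer ]
```

The fixed-width buffers exist so that reads overhanging the start or stop
codon still map. All internal coordinates are **0-based, half-open, on the
transcript**; GFF3 input/output (1-based inclusive) is converted at the
parse boundary. This single convention eliminates the ±1 ambiguities that
otherwise leak into every positional statistic. Genes whose CDS length is
not divisible by 3 are *excluded*, not truncated: reading-frame statistics
are meaningless on a broken frame, and silently truncating would bias them.

The atomic observation is an alignment `(gene, pos_5p, read_length)` where
`pos_5p` is the 0-based transcript coordinate of the read's sequenced 5′
terminus. The central container is a per-gene integer matrix of counts
indexed by `(read length, 5′-end position)`. Counts are **keyed by the 5′
end, not the ribosomal A-site**: offset rules that convert read positions
to A/P/E-site codons vary between studies, so the store stays rule-agnostic
and A-site shifting is a cheap downstream view (`assign_asites()`), meaning
one store serves any offset table. The packaged default offset table (15 nt
for 28–30-mers, the common yeast convention) is a starting point, not a
claim; users supply their own TSV for anything serious.

## Read preparation rules

**Adapter trimming.** The scan is leftmost-first over read positions. At
position $i$, the overlap is $o = \min(|A|,\, L - i + 1)$ for adapter $A$
and read length $L$; the position qualifies when $o \ge$ `min_overlap`
(default 5) and the mismatch fraction over the overlap is at most
`max_mismatch_rate` (default 0, i.e. exact). A full internal adapter
occurrence therefore removes the occurrence and everything 3′ of it, and a
terminal partial occurrence removes the matching suffix. The default of
exact matching was chosen because the trimming guarantee the generator
makes (below) is easiest to reason about there; mismatch-tolerant trimming
is available through the parameter.

**Length window.** Default `[15, 50]` nt for general use; the pipeline
configuration defaults to the footprint preset `[25, 35]`. The window
discard counter covers both too-short and too-long reads.

**rRNA filtering** is exact k-mer membership (default k = 15) against a
contaminant FASTA, sense strand only — riboseq libraries are
strand-specific against a transcriptome reference. This is deliberately not
an alignment: membership is fast, order-independent, and exactly
reproducible; mismatch-tolerant contaminant removal is out of scope.

**Alignment.** The built-in aligner searches each read as an exact
substring of every transcript (sense strand). Exactly one occurrence
transcriptome-wide yields an alignment; two or more make the read
*multimapped*, which is discarded and counted — unique mapping is the
least-assumption default and what the periodicity statistics need. Real
datasets aligned with bowtie/hisat2 enter through SAM/BAM ingestion, which
keeps primary, mapped, forward-strand records with a pure-match CIGAR. Any
soft/hard clip (or indel) disqualifies a record rather than being
"un-clipped": `pos_5p` must always mean the sequenced 5′ terminus, because
every downstream statistic assumes it.

Every run produces a `prep_stats` partition —
`n_input = n_too_short + n_rrna_removed + n_unaligned + n_multimapped +
n_accepted` — validated at construction, so a read can never silently
vanish.

## The count store

The HDF5 layout is this package's own versioned contract (the format, not
the layout, is the established choice):

```
/<dataset_id>/<gene_id>/reads/data   integer matrix, gzip-chunked per gene
  gene attrs: lengths, buffer_left, buffer_right,
              start_codon_pos, stop_codon_pos, reads_total
root attrs:   schema_version, dataset_id, provenance (JSON)
```

One group per gene with whole-gene chunks matches the gene-at-a-time access
pattern of every consumer and makes partial loading trivial. Readers refuse
unknown schema majors. Flat per-gene TSVs (position × read-length columns)
round-trip to identical matrices for spreadsheet-level use.

## QC statistics and their decision rules

**Reading frame** is `(pos_5p − start_codon_pos) mod 3` over reads whose 5′
end lies inside the ORF (stop codon included). Frame is defined on 5′ ends,
not A-sites, so the diagnostic cannot depend on the offset table it helps
calibrate.

**Three-nucleotide periodicity.** The input is the pooled per-position 5′
count profile along ORFs. The statistic is discrete Fourier power of the
mean-subtracted profile at candidate periods (default 2–10 nt), with one
refinement: the profile is cut into half-overlapping segments (default
length `3 × max(candidate period)` = 30 nt), each segment is linearly
detrended, and both the candidate-period power and the mean spectral power
(the segment variance, by Parseval) are averaged across segments. The
reported *peak-to-mean ratio* is candidate power over mean spectral power;
the dominant period is the argmax if its ratio reaches the threshold
(default 2.0), ties broken toward the smaller period. The segment averaging
is the reason the threshold works: a single-bin periodogram value under
white noise is approximately exponential, so the maximum over ~9 candidates
exceeds twice the mean most of the time even for structureless data, and no
fixed threshold separates the cases; averaging over many segments
concentrates the noise power near its mean, making false calls on
RNA-seq-like data rare while leaving the (much larger) genuine period-3
signal untouched. Two honest caveats are documented with the tie rule: an
impulse comb spreads equal power over its harmonics, so a pure period-4
comb legitimately ties periods 2 and 4 and resolves to 2; and a constant
or low-count (< `min_total`) profile yields "none" rather than NaN.

**Metagene profiles** around the start or stop codon: each eligible gene's
per-position count vector in the window is divided by that gene's mean over
the window, then averaged across genes with equal weight. Equal weighting
prevents a handful of high-coverage genes from dominating the shape —
uniform-coverage data produce an identically-1.0 profile regardless of
coverage imbalance. Genes are eligible when the window fits inside their
transcript, they carry at least `min_reads` (default 64) reads, and the
window is not all-zero; exclusions are counted, and zero eligible genes is
an error naming the threshold, never a silent empty profile. With counts
keyed by 5′ ends, the initiation peak appears at position −offset
(−15 by default), not at 0.

**Positional distribution** bins each read's relative position
`(pos_5p − start) / orf_length`, clipped to `[0, 1)`, into `n_bins`
(default 50) equal bins; per-gene vectors are normalised to unit mass and
averaged with equal weight. The clipping convention means 5′ ends in the
buffers contribute to the terminal bins rather than being dropped.

**Nucleotide frequencies** per read position diagnose ligation and
amplification biases; positions beyond a read's length simply do not
contribute to that position's denominator.

## Quantification

ORF membership of a read uses its **5′-end position** (consistent with the
store's keying), so RPKM does not depend on the offset table:
`rpkm = 1e9 × orf_count / (total_orf_count × orf_length_nt)`.
Expression–feature association uses **Spearman** rank correlation with
average ranks for ties, pairwise-complete over missing features and no
imputation: the features span orders of magnitude and rank correlation is
invariant to monotone transforms, so no log-transform choice has to be
defended. Relative abundance of a gene against a panel of reference
datasets is `log2(rpkm / median(panel rpkm))` — the median, not the mean,
so one outlier reference cannot move every comparison — with a pseudo-RPKM
floor (default 0.01) applied only to a zero numerator, and flagged.

## The synthetic-data generator

The generator emulates exactly the structures the QC suite is built to
detect, with a per-read truth table:

* read lengths from a distribution with mode 30 nt over 28–32 nt (a
  ribosome protects ~30 nt);
* an A-site codon drawn per read from a within-gene density with a 5-fold
  initiation peak and 3-fold termination peak (defaults);
* the 5′ end placed at `A-site codon start − 15 nt`, jittered ±1 nt with
  probability `1 − frame_fidelity` (default fidelity 0.9) — so the frame-0
  fraction of 5′ ends *is* the fidelity parameter;
* optional per-position nucleotide bias, an appended 3′ adapter, and a
  configurable fraction of reads replaced by rRNA contaminant substrings;
* RNA-seq-like controls: uniform positions, no frame structure, a flat
  28–40 nt length profile.

Gene sampling weights default to log-normal(0, 1) draws, giving the
order-of-magnitude expression spread real libraries show. All generators
are pure functions of (annotation, config, seed); per-stage streams are
derived from the single seed by fixed offsets (transcriptome +0, weights
+7, footprints +1, RNA-seq +2, contamination +3), so stages are
independently reproducible and byte-identical under reruns.

Two generator guarantees keep truth tables *exact* under the pipeline's own
rules, rather than approximately right:

1. **Contaminants are k-mer-disjoint from the transcriptome.** Random
   "rRNA" sequences are mutated until they share no 15-mer with any
   transcript. Without this, chance 15-mer collisions (expected about 0.8
   per 200-gene transcriptome against 3 kb of contaminant) would remove
   genuine footprints, and planted contaminants could align. These
   sequences are synthetic stand-ins built for clean truth tables, not
   biologically realistic rRNA.
2. **Reads are trimming-unambiguous.** A read whose insert happens to
   contain a full adapter occurrence, or whose 3′ insert end coincides with
   an adapter prefix, would trim early (about one read per 10^5 at an 11 nt
   adapter); such reads are resampled at generation time, under the same
   trimming parameters the pipeline will use.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: sequencing errors and quality variation
(qualities are constant Q40 and never consulted), codon-specific dwell
times and pause sites, UMI structure, spliced or genome-coordinate
alignment, mismatch-tolerant mapping, and biological covariation between
expression and sequence features. Multimapping arises only when explicitly
planted (`shared_block_codons`), so the multimap-discard path is tested
deterministically rather than by chance.

## Numerical and degenerate-input conventions

* Frame fractions with zero eligible reads are `NA`, never NaN propagation.
* A constant profile has zero spectral baseline and yields "none".
* An empty FASTQ flows through with all-zero stats rather than erroring.
* Empty 5′ buffers give `NA` GC content and zero upstream ATGs.
* A gene with no reads exports an all-zero TSV with correct dimensions.
* Periodicity ties are broken toward the smaller period and reported.
* Statistical tests in the suite use a 4-standard-error tolerance under the
  generator's sampling model, with seeds fixed in the tests.

## Problem sizes

The test suite exercises the pipeline end-to-end at 200 genes × 100,000
reads with 20% rRNA contamination (truth recovery, conservation), 100 genes
× 50,000 reads (periodicity contrast, parameter recovery), and smaller
fixtures for unit-level checks; the acceptance script uses the same sizes.
These sizes were chosen to make sampling-based checks sharp (4 SE bounds in
the sub-percent range) while keeping a full run on one CPU in minutes.

## Known limitations

* The exact aligner is a documented stand-in for a real aligner, suitable
  for error-free synthetic reads and for small exact analyses; real
  datasets should be aligned externally and ingested as SAM/BAM.
* P- and E-site views are derivable (A-site − 3/− 6 nt) but not separately
  stored.
* No translation-efficiency (RPF/mRNA), differential-expression, TPM or
  effective-length modelling; folding energies and poly(A) lengths are
  consumed from an external table, never computed.
* The HDF5 schema is this package's own; it does not reproduce any other
  tool's internal layout.
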