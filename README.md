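# ribopipe

Processing core for ribosome profiling (riboseq) experiments in R: from raw
footprint FASTQ reads to per-gene count matrices, translation QC, and gene
expression estimates.

Ribosome profiling sequences the ~28–32 nt mRNA fragments a translating
ribosome protects from nuclease digestion. Because ribosomes step one codon
(3 nt) at a time, genuine footprint data carry signatures that RNA-seq data
do not: a three-nucleotide periodicity of 5′-end positions along ORFs,
accumulation of footprints at start and stop codons, and a tight read-length
distribution. `ribopipe` implements the processing and QC pipeline that
exposes these signatures, for systems biologists analysing whole datasets
and for groups focused on individual genes.

## What it does

* **Read preparation** — 3′ adapter trimming (leftmost suffix/prefix rule),
  read-length windowing, rRNA contaminant removal by exact k-mer membership
  (default k = 15), and transcriptome alignment: either the built-in exact
  substring aligner (unique hits kept, multimappers discarded and counted)
  or ingestion of SAM/BAM from an external aligner such as bowtie or hisat2.
  The reference is ORF-centric: one sequence per gene, a CDS flanked by
  fixed-width UTR buffers, described by FASTA + GFF3.
* **Count store** — per-gene integer matrices indexed by (read length,
  5′-end position), persisted in HDF5 (one gzip-chunked dataset per gene,
  coordinate frame stored as group attributes, versioned schema) and
  exportable as flat TSVs. Counts are keyed by the 5′ end, not the A-site,
  so one store serves any offset table.
* **QC / metagene suite** — A-site assignment from a read-length → offset
  table (packaged default: 15 nt for 28–30-mers); reading-frame
  distribution; three-nucleotide periodicity diagnosis by segment-averaged
  Fourier power with an explicit decision rule; start/stop metagene
  profiles (per-gene mean-normalised, equal-weight averaged); read-length
  histograms; positional distributions along ORFs; position-specific
  nucleotide frequencies.
* **Quantification** — RPKM per gene
  (`1e9 × count / (total × ORF length in nt)`), Spearman correlation of
  RPKM against sequence features (ORF length, 5′ UTR length, UTR GC,
  upstream ATG count, and externally supplied folding energies and poly(A)
  lengths), and per-gene log2 relative abundance against a reference panel
  of wild-type datasets.
* **Synthetic data generator** — transcriptomes (ATG start, no internal
  in-frame stops, fixed buffers) and reads with controlled length
  distribution, frame fidelity, initiation/termination peaks, nucleotide
  bias, adapter and rRNA contamination — each read recorded in a truth
  table, so every pipeline stage is verifiable end-to-end without any
  download.

## Worked example

Everything runs from one configuration, via R or the `exec/ribopipe` CLI
(`ribopipe <simulate|prepare|count|qc|quantify|all> [--config FILE] ...`):

```r
library(ribopipe)
cfg <- load_run_config(overrides = list(
  outdir = "demo_out", seed = 42L,
  sim = list(n_genes = 50, n_reads = 20000, rrna_fraction = 0.1)))
res <- run_all(cfg)   # simulate -> prepare -> count -> qc -> quantify
print(res$prepare$stats)
print(res$qc$periodicity)
print(res$qc$frame)
```

which prints

```
prep_stats:
  n_input            20000
  n_adapter_trimmed  20000
  n_too_short        0
  n_rrna_removed     2062
  n_unaligned        0
  n_multimapped      0
  n_accepted         17938
spectrum_result: dominant period 3 nt (peak-to-mean 14.4, 17108 counts)
frame_distribution over 17108 reads
  frame 0: 0.9017 (15427)
  frame 1: 0.0506 (865)
  frame 2: 0.0477 (816)
```

Reading the numbers: of 20,000 input reads, all had their adapter trimmed,
2,062 were removed as rRNA (exactly the planted contaminant fraction), and
17,938 aligned uniquely — the counts always partition the input. The QC
detects the codon-step signature: dominant spectral period 3 nt with
peak-to-mean power ratio 14.4 (the detector calls "none" below 2.0, which
is what it returns on RNA-seq-like reads), and 90% of in-ORF 5′ ends sit in
frame 0, matching the simulation's frame fidelity of 0.9. `demo_out/`
contains the HDF5 count store, one TSV per statistic with a JSON parameter
sidecar, per-gene count TSVs, the RPKM table, feature correlations, a run
log and a provenance snapshot.

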