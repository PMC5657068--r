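# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small simulated dataset pushed through the full read-prep path.
small_pipeline <- function() {
  cached("small_pipeline", {
    cfg <- sim_config(n_genes = 20, orf_length_range = c(100, 250),
                      n_reads = 4000, rrna_fraction = 0.15, seed = 101)
    tx <- generate_transcriptome(cfg)
    cfg$rrna_seqs <- generate_contaminants(tx, seed = 102)
    fp <- contaminate(simulate_footprints(tx, cfg), cfg)
    trimmed <- trim_adapter(fp$reads, cfg$adapter)
    fl <- filter_length(trimmed, 25, 35)
    rr <- filter_rrna(fl$kept, cfg$rrna_seqs, k = cfg$rrna_k)
    al <- align_exact(rr$kept, tx)
    stats <- prep_stats(
      n_input = nrow(fp$reads),
      n_adapter_trimmed = sum(trimmed$adapter_trimmed),
      n_too_short = fl$discarded_count,
      n_rrna_removed = rr$removed_count,
      n_unaligned = al$stats$n_unaligned,
      n_multimapped = al$stats$n_multimapped,
      n_accepted = al$stats$n_accepted)
    store <- build_count_matrices(al$alignments, tx, 25, 35, "small")
    list(cfg = cfg, tx = tx, sim = fp, trimmed = trimmed,
         alignments = al$alignments, stats = stats, store = store)
  })
}

# Annotation with uniform 5'-end coverage at every position of each
# transcript (one read per placeable position), for self-normalization
# checks.
uniform_store <- function(n_genes = 2, read_length = 28, boost_gene = NULL,
                          boost = 10L) {
  cfg <- sim_config(n_genes = n_genes, orf_length_range = c(100, 100),
                    seed = 77)
  tx <- generate_transcriptome(cfg)
  al <- data.table::rbindlist(lapply(seq_len(n_genes), function(i) {
    rec <- tx$records[i, ]
    pos <- 0:(rec$tx_length - read_length)
    reps <- if (!is.null(boost_gene) && i == boost_gene) boost else 1L
    data.table::data.table(
      read_id = sprintf("u%d_%d_%d", i, rep(pos, each = reps),
                        sequence(rep(reps, length(pos)))),
      gene_id = rec$gene_id,
      pos_5p = rep(pos, each = reps),
      read_length = read_length)
  }))
  list(tx = tx, alignments = al,
       store = build_count_matrices(al, tx, 25, 35, "uniform"))
}

# Hand-construct a minimal dataset_store (the documented list contract)
# so closed-form expectations can be pinned to round numbers.
make_store <- function(orf_counts, orf_lengths, buffer = 25L) {
  n <- length(orf_counts)
  gene_id <- sprintf("g%02d", seq_len(n))
  tx_len <- buffer + orf_lengths + buffer
  matrices <- lapply(seq_len(n), function(i) {
    m <- matrix(0L, nrow = 1, ncol = tx_len[i],
                dimnames = list("28", NULL))
    m[1, buffer + 1L] <- as.integer(orf_counts[i])  # all reads at the start
    m
  })
  names(matrices) <- gene_id
  structure(
    list(dataset_id = "crafted", lmin = 28L, lmax = 28L, matrices = matrices,
         fingerprint = data.frame(
           gene_id = gene_id, tx_length = tx_len, buffer_left = buffer,
           buffer_right = buffer, start_codon_pos = buffer,
           stop_codon_pos = buffer + orf_lengths - 3L,
           orf_length = orf_lengths, stringsAsFactors = FALSE),
         provenance = list()),
    class = "dataset_store")
}

# Write a tiny hand-made transcriptome to files; returns the paths.
write_tiny_transcriptome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # gene A: 25 nt buffer + 999 nt ORF (ATG..TAA) + 25 nt buffer = 1049 nt
  # gene B: CDS length 1000 -- not divisible by 3, must be rejected
  orf_a <- paste0("ATG", strrep("GCT", 331), "TAA")
  seq_a <- paste0(strrep("A", 25), orf_a, strrep("T", 25))
  seq_b <- paste0(strrep("A", 25), "ATG", strrep("C", 994), "TAA",
                  strrep("T", 25))
  fa <- file.path(dir, "tiny.fa")
  writeLines(c(">geneA", seq_a, ">geneB", seq_b), fa)
  gff <- file.path(dir, "tiny.gff3")
  writeLines(c(
    "##gff-version 3",
    "geneA\ttest\tCDS\t26\t1024\t.\t+\t0\tID=cds_geneA",
    "geneB\ttest\tCDS\t26\t1025\t.\t+\t0\tID=cds_geneB"), gff)
  list(fasta = fa, gff = gff, seq_a = seq_a, seq_b = seq_b)
}
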