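test_that("generators are pure functions of (annotation, config, seed)", {
  cfg <- sim_config(n_genes = 8, n_reads = 500, seed = 71)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(as.character(tx1$sequences), as.character(tx2$sequences))
  expect_identical(tx1$records, tx2$records)

  # byte-identical files under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_transcriptome(tx1, file.path(d1, "t.fa"), file.path(d1, "t.gff3"))
  write_transcriptome(tx2, file.path(d2, "t.fa"), file.path(d2, "t.gff3"))
  expect_identical(readLines(file.path(d1, "t.fa")),
                   readLines(file.path(d2, "t.fa")))
  expect_identical(readLines(file.path(d1, "t.gff3")),
                   readLines(file.path(d2, "t.gff3")))

  fp1 <- simulate_footprints(tx1, cfg)
  fp2 <- simulate_footprints(tx1, cfg)
  expect_identical(fp1$reads, fp2$reads)
  expect_identical(fp1$truth, fp2$truth)

  rs1 <- simulate_rnaseq(tx1, cfg)
  rs2 <- simulate_rnaseq(tx1, cfg)
  expect_identical(rs1$reads, rs2$reads)
})

test_that("generated ORFs have no internal in-frame stop codon", {
  tx <- generate_transcriptome(sim_config(n_genes = 30, seed = 19))
  seqs <- unname(as.character(tx$sequences))
  rec <- tx$records
  for (i in seq_len(nrow(rec))) {
    orf <- substr(seqs[i], rec$start_codon_pos[i] + 1,
                  rec$start_codon_pos[i] + rec$orf_length[i])
    codons <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_equal(substr(orf, 1, 3), "ATG")
    expect_true(utils::tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
    expect_false(any(utils::head(codons, -1)[-1] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("footprints respect frame fidelity and copy transcript bases", {
  cfg <- sim_config(n_genes = 10, n_reads = 2000, frame_fidelity = 1,
                    seed = 23)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg)
  expect_true(all(fp$truth$frame == 0L))

  # emitted bases (insert part) equal the transcript substring at the truth
  # position when no nucleotide bias is configured
  seqs <- as.character(tx$sequences)
  ins <- substr(fp$reads$bases, 1, fp$truth$true_length)
  expected <- unname(substr(seqs[fp$truth$gene_id], fp$truth$true_pos_5p + 1,
                            fp$truth$true_pos_5p + fp$truth$true_length))
  expect_identical(ins, expected)
  # and the adapter really is appended after the insert
  expect_true(all(substr(fp$reads$bases, fp$truth$true_length + 1,
                         nchar(fp$reads$bases)) == cfg$adapter))
})

test_that("the simulated length distribution is recovered within 4 SE", {
  cfg <- sim_config(n_genes = 20, n_reads = 8000, seed = 27)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg)
  tab <- table(factor(fp$truth$true_length, levels = 28:32))
  n <- nrow(fp$truth)
  for (L in names(cfg$length_distribution)) {
    p <- cfg$length_distribution[[L]]
    se <- sqrt(n * p * (1 - p))
    expect_lt(abs(tab[[L]] - n * p), 4 * se)
  }
})

test_that("RNA-seq-like truth frames are uniform within 4 SE", {
  cfg <- sim_config(n_genes = 20, n_reads = 9000, seed = 31)
  tx <- generate_transcriptome(cfg)
  rs <- simulate_rnaseq(tx, cfg)
  tab <- table(factor(rs$truth$frame, levels = 0:2))
  se <- sqrt(9000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(tab - 3000) < 4 * se))
})

test_that("contamination plants the advertised fraction and updates truth", {
  cfg <- sim_config(n_genes = 15, n_reads = 5000, rrna_fraction = 0.2,
                    seed = 37)
  tx <- generate_transcriptome(cfg)
  cfg$rrna_seqs <- generate_contaminants(tx, seed = 38)
  fp0 <- simulate_footprints(tx, cfg)
  fp <- contaminate(fp0, cfg)

  n_planted <- sum(fp$truth$origin == "rrna")
  se <- sqrt(5000 * 0.2 * 0.8)
  expect_lt(abs(n_planted - 1000), 4 * se)
  expect_true(all(fp$truth$gene_id[fp$truth$origin == "rrna"] %in%
                    names(cfg$rrna_seqs)))

  # rrna_fraction = 0 leaves reads untouched
  cfg0 <- sim_config(n_genes = 15, n_reads = 500, rrna_fraction = 0, seed = 37)
  expect_identical(contaminate(fp0, cfg0), fp0)

  # planted contaminants are exactly the reads the k-mer filter removes
  trimmed <- trim_adapter(fp$reads, cfg$adapter)
  rr <- filter_rrna(trimmed, cfg$rrna_seqs, k = cfg$rrna_k)
  expect_setequal(rr$removed$read_id,
                  fp$truth$read_id[fp$truth$origin == "rrna"])
})

test_that("contaminants shorter than a read are fatal; missing seqs fatal", {
  cfg <- sim_config(n_genes = 5, n_reads = 100, rrna_fraction = 0.5, seed = 41)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg)
  expect_error(contaminate(fp, cfg), "rrna_seqs")
  cfg$rrna_seqs <- Biostrings::DNAStringSet(c(rrna_1 = "ACGTACGTAA"))
  expect_error(contaminate(fp, cfg), "shorter")
})

test_that("synthetic contaminants share no k-mer with the transcriptome", {
  cfg <- sim_config(n_genes = 25, seed = 43)
  tx <- generate_transcriptome(cfg)
  rr <- generate_contaminants(tx, n = 2, length = 800, k = 15, seed = 44)
  tx_kmers <- unique(unlist(lapply(as.character(tx$sequences), function(s) {
    nk <- nchar(s) - 15 + 1
    substring(s, seq_len(nk), seq_len(nk) + 14)
  })))
  for (s in as.character(rr)) {
    nk <- nchar(s) - 15 + 1
    expect_false(any(substring(s, seq_len(nk), seq_len(nk) + 14) %in% tx_kmers))
  }
})

test_that("every emitted read survives its own adapter trimming unambiguously", {
  sp <- small_pipeline()
  # after trimming, each gene-origin read must be restored to its insert
  trimmed <- sp$trimmed
  truth <- sp$sim$truth
  idx <- match(truth$read_id, trimmed$read_id)
  expect_identical(nchar(trimmed$bases[idx]), truth$true_length)
})
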