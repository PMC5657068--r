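adapter <- "CTGTAGGCACC"

make_reads <- function(bases) {
  data.table::data.table(read_id = sprintf("r%03d", seq_along(bases)),
                         bases = bases, quals = strrep("I", nchar(bases)))
}

test_that("adapter trimming removes full and partial terminal occurrences", {
  set.seed(1)
  insert <- random_read(28)
  reads <- make_reads(c(
    paste0(insert, adapter),          # full adapter appended
    insert,                           # no adapter at all
    paste0(insert, "CTGTAG")          # 6 nt adapter prefix at the 3' end
  ))
  out <- trim_adapter(reads, adapter, min_overlap = 5, max_mismatch_rate = 0)
  expect_equal(out$bases[1], insert)
  expect_true(out$adapter_trimmed[1])
  expect_equal(out$bases[2], insert)
  expect_false(out$adapter_trimmed[2])
  expect_equal(out$bases[3], insert)
  expect_true(out$adapter_trimmed[3])
  # quals stay in register with bases
  expect_equal(nchar(out$quals), nchar(out$bases))
})

test_that("a full internal adapter occurrence removes everything 3' of it", {
  set.seed(2)
  left <- random_read(12)
  right <- random_read(20)
  reads <- make_reads(paste0(left, adapter, right, adapter))
  out <- trim_adapter(reads, adapter, min_overlap = 5)
  expect_equal(out$bases, left)
})

test_that("trimming equals the exhaustive suffix-prefix scan on random reads", {
  set.seed(33)
  n <- 400
  bases <- vapply(sample(12:45, n, replace = TRUE), random_read, character(1))
  # make some reads adapter-bearing so both branches are exercised
  with_ad <- seq_len(n) %% 3 == 0
  bases[with_ad] <- paste0(substr(bases[with_ad], 1, 20), adapter)
  for (rate in c(0, 0.15)) {
    out <- trim_adapter(make_reads(bases), adapter, min_overlap = 5,
                        max_mismatch_rate = rate)
    oracle <- vapply(bases, oracle_trim_one, character(1),
                     adapter = adapter, min_overlap = 5,
                     max_mismatch_rate = rate, USE.NAMES = FALSE)
    expect_identical(out$bases, oracle)
  }
})

test_that("length filter keeps the window and conserves counts", {
  reads <- make_reads(c(strrep("A", 10), strrep("C", 28), strrep("G", 51)))
  fl <- filter_length(reads, 15, 50)
  expect_equal(nchar(fl$kept$bases), 28)
  expect_equal(fl$discarded_count, 2L)
  expect_equal(nrow(fl$kept) + fl$discarded_count, nrow(reads))

  fl28 <- filter_length(reads, 28, 28)
  expect_equal(nchar(fl28$kept$bases), 28)
})

test_that("rRNA filter removes exactly the reads sharing a contaminant k-mer", {
  set.seed(7)
  rrna <- random_read(300)
  clean <- vapply(rep(30, 20), random_read, character(1))
  planted <- substring(rrna, c(1, 50, 200), c(30, 79, 229))
  reads <- make_reads(c(clean, planted))
  res <- filter_rrna(reads, rrna, k = 15)
  expect_equal(sort(res$removed$bases), sort(planted))
  expect_equal(res$removed_count, 3L)
  expect_equal(nrow(res$kept) + res$removed_count, nrow(reads))

  expect_warning(res0 <- filter_rrna(reads, character(0), k = 15), "empty")
  expect_equal(res0$removed_count, 0L)
})

test_that("exact aligner reports unique hits and discards multimappers", {
  tx <- generate_transcriptome(sim_config(n_genes = 5, seed = 21))
  seqs <- as.character(tx$sequences)
  unique_read <- substr(seqs[1], 101, 128)
  reads <- make_reads(c(unique_read, random_read(28)))
  res <- align_exact(reads, tx)
  expect_equal(res$alignments$gene_id, tx$records$gene_id[1])
  expect_equal(res$alignments$pos_5p, 100L)
  expect_equal(res$alignments$read_length, 28L)
  expect_equal(res$stats$n_unaligned, 1L)

  # a deliberately duplicated block across two genes -> multimapped
  tx2 <- generate_transcriptome(sim_config(n_genes = 5, seed = 21,
                                           shared_block_codons = 12))
  shared <- substr(as.character(tx2$sequences)[1],
                   tx2$records$buffer_left[1] + 31,
                   tx2$records$buffer_left[1] + 58)
  res2 <- align_exact(make_reads(shared), tx2)
  expect_equal(nrow(res2$alignments), 0L)
  expect_equal(res2$stats$n_multimapped, 1L)
})

test_that("exact aligner equals a naive per-read scan over all transcripts", {
  set.seed(55)
  tx <- generate_transcriptome(sim_config(n_genes = 40, seed = 31))
  seq_strings <- as.list(as.character(tx$sequences))
  rec <- tx$records

  # mixture: planted unique reads, random junk, a read planted twice
  planted <- vapply(1:60, function(i) {
    g <- sample(nrow(rec), 1)
    L <- sample(25:35, 1)
    p <- sample(rec$tx_length[g] - L, 1)
    substr(seq_strings[[g]], p + 1, p + L)
  }, character(1))
  junk <- vapply(rep(30, 20), random_read, character(1))
  reads <- make_reads(c(planted, junk))
  res <- align_exact(reads, tx)

  for (i in seq_len(nrow(reads))) {
    hits <- oracle_align_one(reads$bases[i], setNames(seq_strings, rec$gene_id))
    got <- res$alignments[res$alignments$read_id == reads$read_id[i], ]
    if (length(hits) == 1L) {
      expect_equal(got$gene_id, hits[[1]]$gene)
      expect_equal(got$pos_5p, hits[[1]]$pos0)
    } else {
      expect_equal(nrow(got), 0L)
    }
  }
  n_multi_oracle <- sum(vapply(reads$bases, function(b)
    length(oracle_align_one(b, setNames(seq_strings, rec$gene_id))) >= 2,
    logical(1)))
  expect_equal(res$stats$n_multimapped, n_multi_oracle)
})

test_that("SAM ingestion keeps primary forward unclipped records only", {
  tx <- generate_transcriptome(sim_config(n_genes = 3,
                                          orf_length_range = c(50, 60),
                                          seed = 2))
  g <- tx$records$gene_id
  seqs <- as.character(tx$sequences)
  ins <- substr(seqs[1], 101, 128)
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", g, "\tLN:", tx$records$tx_length),
    paste0("r1\t0\t", g[1], "\t101\t42\t28M\t*\t0\t0\t", ins, "\t", strrep("I", 28)),
    paste0("r2\t16\t", g[1], "\t10\t42\t28M\t*\t0\t0\t", ins, "\t", strrep("I", 28)),
    paste0("r3\t4\t*\t0\t0\t*\t*\t0\t0\t", ins, "\t", strrep("I", 28)),
    paste0("r4\t0\t", g[2], "\t5\t42\t2S26M\t*\t0\t0\t", ins, "\t", strrep("I", 28)),
    paste0("r5\t256\t", g[1], "\t50\t42\t28M\t*\t0\t0\t*\t*"),
    paste0("r6\t0\t", g[3], "\t20\t42\t60M\t*\t0\t0\t",
           substr(seqs[3], 20, 79), "\t", strrep("I", 60))
  )
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  res <- read_alignments_sam(f, tx, lmin = 15, lmax = 50)

  # 1-based POS 101 -> 0-based pos_5p 100
  expect_equal(res$alignments$read_id, "r1")
  expect_equal(res$alignments$pos_5p, 100L)
  # secondary r5 is not part of n_input; reverse/unmapped/clipped -> unaligned;
  # the 60M record is outside the window
  expect_equal(res$stats$n_input, 5L)
  expect_equal(res$stats$n_unaligned, 3L)
  expect_equal(res$stats$n_too_short, 1L)
  expect_equal(res$stats$n_accepted, 1L)
})

test_that("SAM reference names missing from the annotation are fatal", {
  tx <- generate_transcriptome(sim_config(n_genes = 2,
                                          orf_length_range = c(50, 60),
                                          seed = 2))
  sam <- c(
    paste0("@SQ\tSN:", tx$records$gene_id[1], "\tLN:", tx$records$tx_length[1]),
    "@SQ\tSN:ghost\tLN:500",
    paste0("r1\t0\tghost\t10\t42\t28M\t*\t0\t0\t", strrep("A", 28),
           "\t", strrep("I", 28))
  )
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  expect_error(read_alignments_sam(f, tx), "ghost")
})

test_that("prep_stats enforces the input partition", {
  expect_error(prep_stats(n_input = 10, n_accepted = 5), "partition")
  s <- prep_stats(n_input = 10, n_too_short = 2, n_rrna_removed = 1,
                  n_unaligned = 1, n_multimapped = 1, n_accepted = 5)
  expect_s3_class(s, "prep_stats")
})
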