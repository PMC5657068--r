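test_that("A-site assignment applies offsets and flags outside-ORF reads", {
  tx <- generate_transcriptome(sim_config(n_genes = 1, buffer_left = 25,
                                          seed = 3))
  g <- tx$records$gene_id[1]
  offsets <- data.frame(read_length = 28L, asite_offset = 15L)
  al <- data.table::data.table(
    read_id = c("a", "b", "c"),
    gene_id = g,
    pos_5p = c(100L, 0L, 50L),
    read_length = c(28L, 28L, 33L))
  res <- assign_asites(al, offsets, tx)

  # pos 100 + offset 15 = 115; start codon at 25 -> codon (115-25)/3 = 30
  expect_equal(res[res$read_id == "a", ]$asite_pos, 115L)
  expect_equal(res[res$read_id == "a", ]$codon_index, 30L)
  # pos 0 + 15 = 15 < start 25 -> outside-ORF marker
  expect_true(is.na(res[res$read_id == "b", ]$codon_index))
  # length 33 has no offset -> skipped and counted
  expect_false("c" %in% res$read_id)
  expect_equal(attr(res, "n_skipped"), 1L)
})

test_that("the packaged offset table is valid and loadable", {
  ot <- default_offset_table()
  expect_equal(ot$read_length, 28:30)
  expect_true(all(ot$asite_offset == 15L))
  expect_true(all(ot$asite_offset >= 0 & ot$asite_offset < ot$read_length))
})

test_that("frame distribution is exact on phased reads and NA when empty", {
  tx <- generate_transcriptome(sim_config(n_genes = 2, seed = 8))
  rec <- tx$records[1, ]
  al <- data.table::data.table(
    read_id = sprintf("r%d", 1:30),
    gene_id = rec$gene_id,
    pos_5p = rec$start_codon_pos + 3L * (0:29),
    read_length = 28L)
  store <- build_count_matrices(al, tx, 25, 35)
  fr <- frame_distribution(store)
  expect_equal(unname(fr$fractions), c(1, 0, 0))
  expect_equal(fr$n_reads, 30)

  empty <- build_count_matrices(al[0], tx, 25, 35)
  fr0 <- frame_distribution(empty)
  expect_true(all(is.na(fr0$fractions)))
  expect_equal(fr0$n_reads, 0)
})

test_that("uniform 5' ends give frame fractions within 4 SE of 1/3", {
  tx <- generate_transcriptome(sim_config(n_genes = 5,
                                          orf_length_range = c(300, 300),
                                          seed = 14))
  n <- 30000
  set.seed(15)
  gi <- sample(5, n, replace = TRUE)
  rec <- tx$records
  pos <- rec$start_codon_pos[gi] +
    floor(runif(n) * rec$orf_length[gi])  # uniform within ORF
  al <- data.table::data.table(read_id = sprintf("r%d", 1:n),
                               gene_id = rec$gene_id[gi],
                               pos_5p = as.integer(pos), read_length = 30L)
  store <- build_count_matrices(al, tx, 25, 35)
  fr <- frame_distribution(store)
  se <- sqrt((1 / 3) * (2 / 3) / fr$n_reads)
  expect_true(all(abs(fr$fractions - 1 / 3) < 4 * se))
})

test_that("periodicity detector identifies pure combs and rejects constants", {
  # period-3 comb: c[p] = 1 + (p mod 3 == 0)
  comb3 <- 1 + (seq_len(300) %% 3 == 0)
  sp3 <- periodicity_spectrum(comb3)
  expect_equal(sp3$dominant_period, 3L)
  expect_gt(sp3$peak_to_mean, 2)

  expect_true(is.na(periodicity_spectrum(rep(5, 300))$dominant_period))

  comb2 <- 1 + (seq_len(300) %% 2 == 0)
  sp2 <- periodicity_spectrum(comb2)
  expect_equal(sp2$dominant_period, 2L)
  expect_true(all(sp2$power[sp2$periods == 2] > sp2$power[sp2$periods != 2]))
})

test_that("spectral power agrees with the autocorrelation oracle on combs", {
  # periods whose harmonics do not collide with other integer candidates;
  # an impulse comb spreads equal power across its harmonics, so e.g. a
  # period-4 comb legitimately ties periods 2 and 4 (resolved to 2 by the
  # smaller-period rule)
  for (p_true in c(2L, 3L, 5L)) {
    comb <- 1 + 2 * (seq_len(420) %% p_true == 0)
    sp <- periodicity_spectrum(comb, candidate_periods = 2:10)
    expect_equal(sp$dominant_period, p_true)
    # the true period must sit in the autocorrelation oracle's top tie
    # group (lag multiples of the period tie up to boundary effects)
    ac <- oracle_autocorr(comb, 2:10)
    expect_gte(ac[p_true - 1L], max(ac) * (1 - 1e-6))
    # and carry strictly more power than every non-multiple candidate
    non_harmonic <- sp$periods %% p_true != 0
    expect_true(all(sp$power[sp$periods == p_true] > sp$power[non_harmonic]))
  }

  # harmonic ambiguity is resolved toward the smaller period
  comb4 <- 1 + 2 * (seq_len(420) %% 4 == 0)
  expect_equal(periodicity_spectrum(comb4)$dominant_period, 2L)
})

test_that("detector calls 'none' on noise and '3' on footprint-like profiles", {
  # false-positive rate under Poisson noise; decision threshold 2.0
  set.seed(41)
  calls <- vapply(1:100, function(i) {
    prof <- rpois(900, lambda = 50)
    is.na(periodicity_spectrum(prof)$dominant_period)
  }, logical(1))
  expect_gte(mean(calls), 0.95)

  # frame-biased profiles (80% of mass in frame 0) must be detected
  set.seed(42)
  hits <- vapply(1:100, function(i) {
    lam <- ifelse(seq_len(900) %% 3 == 1, 0.8 * 3 * 50, 0.1 * 3 * 50)
    prof <- rpois(900, lambda = lam)
    identical(periodicity_spectrum(prof)$dominant_period, 3L)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("periodicity preconditions are enforced", {
  expect_error(periodicity_spectrum(rep(1, 20)), "3 x max")
  low <- periodicity_spectrum(c(rep(0, 299), 1), min_total = 100)
  expect_true(is.na(low$dominant_period))
})

test_that("metagene self-normalization yields a flat profile of 1", {
  u1 <- uniform_store(n_genes = 1)
  mg <- metagene_profile(u1$store, "start", window_up = 20, window_down = 20,
                         min_reads = 10)
  expect_equal(unname(mg$density), rep(1, 41), tolerance = 1e-12)
  expect_equal(mg$positions, -20:20)

  # equal-weight contract: a 10x-coverage gene does not dominate
  u2 <- uniform_store(n_genes = 2, boost_gene = 1, boost = 10L)
  mg2 <- metagene_profile(u2$store, "start", window_up = 20, window_down = 20,
                          min_reads = 10)
  expect_equal(unname(mg2$density), rep(1, 41), tolerance = 1e-12)
  expect_equal(mg2$n_genes, 2L)

  # stop anchor works symmetrically on uniform coverage away from the edge
  mg3 <- metagene_profile(u1$store, "stop", window_up = 20, window_down = 10,
                          min_reads = 10)
  expect_equal(unname(mg3$density), rep(1, 31), tolerance = 1e-12)
})

test_that("metagene excludes short-buffer/low-coverage genes and can fail", {
  u1 <- uniform_store(n_genes = 2)
  expect_error(metagene_profile(u1$store, "start", min_reads = 1e7),
               "min_reads")
  # a window wider than the buffers excludes every gene
  expect_error(metagene_profile(u1$store, "start", window_up = 500,
                                window_down = 10, min_reads = 10))
})

test_that("read-length histogram conserves totals per gene and dataset", {
  sp <- small_pipeline()
  h <- read_length_hist(sp$store)
  expect_equal(sum(h), sp$stats$n_accepted)
  expect_equal(as.integer(names(h)), 25:35)

  g1 <- names(sp$store$matrices)[1]
  hg <- read_length_hist(sp$store, gene = g1)
  expect_equal(sum(hg), unname(reads_per_gene(sp$store)[g1]))
  expect_error(read_length_hist(sp$store, gene = "nope"), "nope")

  # a gene with no reads has an all-zero histogram
  tx <- generate_transcriptome(sim_config(n_genes = 2, seed = 3))
  empty <- build_count_matrices(
    data.table::data.table(read_id = character(), gene_id = character(),
                           pos_5p = integer(), read_length = integer()),
    tx, 25, 35)
  expect_equal(sum(read_length_hist(empty, tx$records$gene_id[1])), 0)
})

test_that("positional distribution sums to 1 and localizes start-codon reads", {
  tx <- generate_transcriptome(sim_config(n_genes = 2, seed = 30))
  rec <- tx$records
  al <- data.table::data.table(
    read_id = sprintf("r%d", 1:200),
    gene_id = rep(rec$gene_id, each = 100),
    pos_5p = rep(rec$start_codon_pos, each = 100),
    read_length = 28L)
  store <- build_count_matrices(al, tx, 25, 35)
  pd <- positional_distribution(store, n_bins = 50, min_reads = 50)
  expect_equal(sum(pd$density), 1, tolerance = 1e-12)
  expect_equal(pd$density[1], 1)

  sp <- small_pipeline()
  pd2 <- positional_distribution(sp$store, n_bins = 20, min_reads = 20)
  expect_equal(sum(pd2$density), 1, tolerance = 1e-9)
})

test_that("nucleotide frequencies are per-position and properly normalized", {
  reads <- data.table::data.table(
    read_id = c("a", "b", "c"),
    bases = c(strrep("A", 30), strrep("A", 28), strrep("A", 25)),
    quals = c(strrep("I", 30), strrep("I", 28), strrep("I", 25)))
  al <- data.table::data.table(read_id = c("a", "b", "c"), gene_id = "g",
                               pos_5p = 0L, read_length = c(30L, 28L, 25L))
  nf <- nucleotide_freqs(al, reads)
  expect_equal(nrow(nf$freq), 30)
  expect_true(all(nf$freq[, "A"] == 1))
  expect_equal(nf$coverage, c(rep(3L, 25), rep(2L, 3), rep(1L, 2)))
  covered <- nf$coverage > 0
  expect_true(all(abs(rowSums(nf$freq[covered, , drop = FALSE]) - 1) < 1e-9))
})

test_that("gene profiles slice the matrix by read length", {
  sp <- small_pipeline()
  g <- names(which.max(reads_per_gene(sp$store)))
  m <- sp$store$matrices[[g]]
  start <- sp$store$fingerprint$start_codon_pos[
    sp$store$fingerprint$gene_id == g]

  full <- gene_profile(sp$store, g)
  expect_equal(full$count, unname(colSums(m)))
  expect_equal(full$position[start + 1], 0)

  only28 <- gene_profile(sp$store, g, lengths = 28)
  expect_equal(only28$count, unname(m["28", ]))

  # slice totals equal a brute-force filter of the alignment table
  al <- sp$alignments
  expect_equal(sum(only28$count),
               nrow(al[al$gene_id == g & al$read_length == 28, ]))
  expect_error(gene_profile(sp$store, "nope"), "nope")
  expect_error(gene_profile(sp$store, g, lengths = 99), "window")
})

test_that("statistics from the HDF5 store equal the in-memory ones", {
  sp <- small_pipeline()
  h5 <- tempfile(fileext = ".h5")
  write_counts_h5(sp$store, h5)
  back <- read_counts_h5(h5)

  expect_equal(frame_distribution(back)$fractions,
               frame_distribution(sp$store)$fractions)
  expect_equal(read_length_hist(back), read_length_hist(sp$store))
  expect_equal(orf_profile(back), orf_profile(sp$store))
  expect_equal(compute_rpkm(back)$rpkm, compute_rpkm(sp$store)$rpkm)
  file.remove(h5)
})
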