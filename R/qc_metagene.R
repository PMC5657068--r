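# Metagene / QC statistics: A-site assignment, reading-frame and
# three-nucleotide periodicity diagnostics, start/stop metagene profiles,
# read-length and positional distributions, nucleotide-frequency bias.
#
# Frame is defined on 5'-end positions, (pos_5p - start_codon_pos) mod 3,
# not on A-sites, so the frame diagnostic cannot depend on the offset table
# it helps calibrate.

#' Read an A-site offset table
#'
#' Tab-delimited, columns `read_length` and `asite_offset` (nt from the
#' read's 5' end to the first base of the A-site codon).
#'
#' @param path TSV path.
#' @return data.frame with `read_length`, `asite_offset`.
#' @export
read_offset_table <- function(path) {
  ot <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("read_length", "asite_offset") %in% names(ot)))
    stop("offset table must have columns read_length, asite_offset")
  if (anyDuplicated(ot$read_length)) stop("duplicate read_length in offset table")
  if (any(ot$asite_offset < 0L) || any(ot$asite_offset >= ot$read_length))
    stop("offsets must satisfy 0 <= offset < read_length")
  ot[, c("read_length", "asite_offset")]
}

#' The packaged default A-site offset table
#'
#' 15 nt for read lengths 28-30, the standard yeast convention; fully
#' user-overridable via [read_offset_table()].
#'
#' @return data.frame with `read_length`, `asite_offset`.
#' @export
default_offset_table <- function() {
  read_offset_table(system.file("extdata", "asite_offsets.tsv",
                                package = "ribopipe", mustWork = TRUE))
}

#' Assign A-site positions and codon indices to alignments
#'
#' The A-site position is `pos_5p + offset(read_length)`; the codon index
#' is `floor((asite_pos - start_codon_pos) / 3)` when the A-site lies
#' within the ORF (stop codon included), `NA` otherwise (outside-ORF
#' marker). Reads whose length has no offset are skipped and counted.
#'
#' @param alignments alignment data.table.
#' @param offsets offset table (see [read_offset_table()]); defaults to the
#'   packaged table.
#' @param annotation an `annotation_set`.
#' @return data.table of the assignable alignments with extra columns
#'   `asite_pos` and `codon_index` (`NA` = outside ORF); attribute
#'   `n_skipped` counts reads with no offset for their length.
#' @export
assign_asites <- function(alignments, offsets = default_offset_table(),
                          annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  al <- data.table::as.data.table(alignments)
  off <- offsets$asite_offset[match(al$read_length, offsets$read_length)]
  n_skipped <- sum(is.na(off))
  keep <- !is.na(off)
  al <- al[keep]
  off <- off[keep]

  rec <- annotation$records
  ri <- match(al$gene_id, rec$gene_id)
  if (anyNA(ri)) stop("alignment to gene absent from annotation")
  asite_pos <- al$pos_5p + off
  start <- rec$start_codon_pos[ri]
  stop_ <- rec$stop_codon_pos[ri]
  inside <- asite_pos >= start & asite_pos < stop_ + 3L
  codon_index <- ifelse(inside, (asite_pos - start) %/% 3L, NA_integer_)
  al[, `:=`(asite_pos = as.integer(asite_pos),
            codon_index = as.integer(codon_index))]
  data.table::setattr(al, "n_skipped", n_skipped)
  al[]
}

#' Reading-frame distribution of 5' ends within ORFs
#'
#' Counts reads whose 5' end lies inside the ORF (stop codon included) by
#' frame `(pos_5p - start_codon_pos) mod 3`. Translating footprints pile up
#' in frame 0; RNA-seq-like data spread uniformly.
#'
#' @param store a `dataset_store`.
#' @param lengths optional subset of read lengths to include.
#' @return object of class `frame_distribution`: list with `counts`
#'   (length-3 integer), `fractions` (`NA` when no eligible reads), and
#'   `n_reads`.
#' @export
frame_distribution <- function(store, lengths = NULL) {
  stopifnot(inherits(store, "dataset_store"))
  rows <- .length_rows(store, lengths)
  counts <- c(`0` = 0, `1` = 0, `2` = 0)
  fp <- store$fingerprint
  for (i in seq_len(nrow(fp))) {
    m <- store$matrices[[fp$gene_id[i]]]
    cols <- (fp$start_codon_pos[i] + 1L):(fp$stop_codon_pos[i] + 3L)
    v <- colSums(m[rows, cols, drop = FALSE])
    f <- (seq_along(v) - 1L) %% 3L
    counts <- counts + vapply(0:2, function(k) sum(v[f == k]), numeric(1))
  }
  n <- sum(counts)
  structure(
    list(counts = counts,
         fractions = if (n > 0) counts / n else rep(NA_real_, 3),
         n_reads = n),
    class = "frame_distribution"
  )
}

#' @export
print.frame_distribution <- function(x, ...) {
  cat("frame_distribution over", x$n_reads, "reads\n")
  if (x$n_reads > 0)
    cat(sprintf("  frame %d: %.4f (%d)\n", 0:2, x$fractions,
                as.integer(x$counts)), sep = "")
  invisible(x)
}

.length_rows <- function(store, lengths) {
  all_lens <- store$lmin:store$lmax
  if (is.null(lengths)) return(as.character(all_lens))
  lengths <- intersect(lengths, all_lens)
  if (length(lengths) == 0L) stop("no requested read length inside the store window")
  as.character(lengths)
}

#' Pooled 5'-end count profile along ORFs
#'
#' Sums, across genes, the 5'-end counts at each ORF-relative position
#' (position 0 = first base of the start codon), giving the positional
#' profile that the periodicity diagnostic operates on.
#'
#' @param store a `dataset_store`.
#' @param lengths optional read-length subset.
#' @return numeric vector; element `i` is the pooled count at ORF position
#'   `i - 1`.
#' @export
orf_profile <- function(store, lengths = NULL) {
  stopifnot(inherits(store, "dataset_store"))
  rows <- .length_rows(store, lengths)
  fp <- store$fingerprint
  prof <- numeric(max(fp$orf_length))
  for (i in seq_len(nrow(fp))) {
    m <- store$matrices[[fp$gene_id[i]]]
    cols <- (fp$start_codon_pos[i] + 1L):(fp$stop_codon_pos[i] + 3L)
    v <- colSums(m[rows, cols, drop = FALSE])
    prof[seq_along(v)] <- prof[seq_along(v)] + v
  }
  prof
}

#' Periodicity diagnosis of a positional count profile
#'
#' Computes discrete Fourier power of the mean-subtracted profile at each
#' candidate period and decides whether one period dominates. To give the
#' decision a stable noise floor, the profile is cut into overlapping
#' segments (Welch-style averaging): each segment is linearly detrended,
#' its Fourier power at every candidate period and its mean spectral power
#' (= its variance, by Parseval) are computed, and both are averaged across
#' segments. The reported ratio is candidate power over mean spectral
#' power; the dominant period is the argmax if its ratio reaches
#' `peak_ratio_threshold`, with ties broken toward the smaller period.
#'
#' A constant profile, or one with fewer than `min_total` counts, yields no
#' dominant period.
#'
#' @param profile numeric vector of per-position counts (e.g.
#'   [orf_profile()]); length must be at least `3 * max(candidate_periods)`.
#' @param candidate_periods integer periods to test, in nt.
#' @param min_total minimum total counts for a call.
#' @param peak_ratio_threshold minimum peak-to-mean power ratio.
#' @param segment_length segment size in nt; default
#'   `max(30, 3 * max(candidate_periods))`.
#' @return object of class `spectrum_result`: list with `periods`, `power`,
#'   `ratio`, `dominant_period` (integer or `NA`), `peak_to_mean`,
#'   `n_segments`, `total_counts`, `ties` (periods tied at the peak, if any).
#' @export
periodicity_spectrum <- function(profile, candidate_periods = 2:10,
                                 min_total = 100, peak_ratio_threshold = 2,
                                 segment_length = NULL) {
  candidate_periods <- sort(unique(as.integer(candidate_periods)))
  stopifnot(all(candidate_periods >= 2L))
  N <- length(profile)
  maxp <- max(candidate_periods)
  if (N < 3L * maxp)
    stop("profile length ", N, " < 3 x max candidate period (", 3L * maxp, ")")
  if (is.null(segment_length)) segment_length <- max(30L, 3L * maxp)
  segment_length <- min(as.integer(segment_length), N)

  total <- sum(profile)
  none <- function(reason) structure(
    list(periods = candidate_periods,
         power = rep(NA_real_, length(candidate_periods)),
         ratio = rep(NA_real_, length(candidate_periods)),
         dominant_period = NA_integer_, peak_to_mean = NA_real_,
         n_segments = 0L, total_counts = total, ties = integer(0),
         reason = reason),
    class = "spectrum_result")
  if (total < min_total) return(none("insufficient counts"))

  starts <- seq(1L, N - segment_length + 1L, by = max(1L, segment_length %/% 2L))
  tt <- seq_len(segment_length)
  tc <- tt - mean(tt)
  basis <- lapply(candidate_periods, function(p)
    exp(-2i * pi * (tt - 1L) / p))

  pw <- matrix(0, nrow = length(starts), ncol = length(candidate_periods))
  vr <- numeric(length(starts))
  for (s in seq_along(starts)) {
    y <- profile[starts[s]:(starts[s] + segment_length - 1L)]
    y <- y - mean(y)
    slope <- sum(y * tc) / sum(tc^2)
    y <- y - slope * tc
    vr[s] <- sum(y^2) / segment_length
    pw[s, ] <- vapply(basis, function(b)
      Mod(sum(y * b))^2 / segment_length, numeric(1))
  }
  power <- colMeans(pw)
  baseline <- mean(vr)
  if (baseline <= 0) return(none("constant profile"))

  ratio <- power / baseline
  peak <- max(ratio)
  tied <- candidate_periods[ratio >= peak * (1 - 1e-9)]
  dominant <- if (peak >= peak_ratio_threshold) tied[1] else NA_integer_
  if (length(tied) > 1L && !is.na(dominant))
    message("periodicity tie between periods ",
            paste(tied, collapse = ", "), "; choosing ", dominant)

  structure(
    list(periods = candidate_periods, power = power, ratio = ratio,
         dominant_period = dominant, peak_to_mean = peak,
         n_segments = length(starts), total_counts = total,
         ties = if (length(tied) > 1L) tied else integer(0)),
    class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result: dominant period ",
      if (is.na(x$dominant_period)) "none" else paste0(x$dominant_period, " nt"),
      " (peak-to-mean ", formatC(x$peak_to_mean, digits = 3, format = "fg"),
      ", ", x$total_counts, " counts)\n", sep = "")
  invisible(x)
}

#' Metagene profile around the start or stop codon
#'
#' For every eligible gene the per-position 5'-end count vector inside the
#' window is divided by that gene's mean count over the window, and the
#' normalized vectors are averaged across genes with equal weight, so
#' high-coverage genes do not dominate. Position 0 is the first base of the
#' start codon (`anchor = "start"`) or of the stop codon
#' (`anchor = "stop"`). Genes whose buffers cannot accommodate the window,
#' or with fewer than `min_reads` total reads, or with an all-zero window,
#' are excluded and counted.
#'
#' @param store a `dataset_store`.
#' @param anchor `"start"` or `"stop"`.
#' @param window_up,window_down window half-widths in nt (positions
#'   `-window_up .. +window_down` relative to the anchor).
#' @param min_reads minimum total reads for a gene to contribute.
#' @return object of class `metagene_profile`: list with `anchor`,
#'   `positions`, `density` (mean normalized density), `n_genes`,
#'   `n_excluded_window`, `n_excluded_low`.
#' @export
metagene_profile <- function(store, anchor = c("start", "stop"),
                             window_up = 25L, window_down = 25L,
                             min_reads = 64L) {
  stopifnot(inherits(store, "dataset_store"))
  anchor <- match.arg(anchor)
  fp <- store$fingerprint
  totals <- reads_per_gene(store)

  rows_norm <- NULL
  n_excluded_window <- 0L
  n_excluded_low <- 0L
  for (i in seq_len(nrow(fp))) {
    a <- if (anchor == "start") fp$start_codon_pos[i] else fp$stop_codon_pos[i]
    lo <- a - window_up
    hi <- a + window_down
    if (lo < 0L || hi >= fp$tx_length[i]) {
      n_excluded_window <- n_excluded_window + 1L
      next
    }
    if (totals[fp$gene_id[i]] < min_reads) {
      n_excluded_low <- n_excluded_low + 1L
      next
    }
    v <- colSums(store$matrices[[fp$gene_id[i]]][, (lo + 1L):(hi + 1L),
                                                 drop = FALSE])
    if (mean(v) <= 0) {
      n_excluded_low <- n_excluded_low + 1L
      next
    }
    rows_norm <- rbind(rows_norm, v / mean(v))
  }
  if (is.null(rows_norm))
    stop("no gene eligible for the metagene profile ",
         "(min_reads = ", min_reads, ", window ", window_up, "/", window_down, ")")

  structure(
    list(anchor = anchor, positions = seq(-window_up, window_down),
         density = colMeans(rows_norm), n_genes = nrow(rows_norm),
         n_excluded_window = n_excluded_window,
         n_excluded_low = n_excluded_low),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile (", x$anchor, "): ", length(x$positions),
      " positions, ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Read-length histogram
#'
#' Dataset-wide by default, or for a single gene.
#'
#' @param store a `dataset_store`.
#' @param gene optional gene id.
#' @return named numeric vector of counts, one entry per read length
#'   `lmin..lmax`; sums to the (gene's) total counted reads.
#' @export
read_length_hist <- function(store, gene = NULL) {
  stopifnot(inherits(store, "dataset_store"))
  if (is.null(gene)) {
    Reduce(`+`, lapply(store$matrices, rowSums))
  } else {
    if (!gene %in% names(store$matrices)) stop("unknown gene: ", gene)
    rowSums(store$matrices[[gene]])
  }
}

#' Positional distribution of reads along ORFs
#'
#' Each read's relative position `(pos_5p - start_codon_pos) / orf_length`
#' (clipped to `[0, 1)`, so 5' ends in the buffers land in the terminal
#' bins) is binned into `n_bins` equal bins; per-gene bin vectors are
#' normalized to unit mass and averaged with equal weight over genes with
#' at least `min_reads` reads. The result sums to 1.
#'
#' @param store a `dataset_store`.
#' @param n_bins number of bins (>= 2).
#' @param min_reads per-gene eligibility threshold.
#' @return list with `breaks` (relative positions, length `n_bins + 1`),
#'   `density` (per-bin mean normalized mass, sums to 1) and `n_genes`.
#' @export
positional_distribution <- function(store, n_bins = 50L, min_reads = 64L) {
  stopifnot(inherits(store, "dataset_store"), n_bins >= 2L)
  fp <- store$fingerprint
  acc <- NULL
  for (i in seq_len(nrow(fp))) {
    v <- colSums(store$matrices[[fp$gene_id[i]]])
    if (sum(v) < min_reads) next
    rel <- ((seq_along(v) - 1L) - fp$start_codon_pos[i]) / fp$orf_length[i]
    rel <- pmin(pmax(rel, 0), 1 - 1e-12)
    bin <- floor(rel * n_bins) + 1L
    bv <- vapply(seq_len(n_bins), function(b) sum(v[bin == b]), numeric(1))
    acc <- rbind(acc, bv / sum(bv))
  }
  if (is.null(acc))
    stop("no gene with at least min_reads = ", min_reads, " reads")
  list(breaks = seq(0, 1, length.out = n_bins + 1L),
       density = colMeans(acc), n_genes = nrow(acc))
}

#' Position-specific nucleotide frequencies of mapped reads
#'
#' Frequency of A/C/G/T/N at each read position among accepted alignments;
#' positions beyond a read's length do not contribute. Used to spot
#' ligation / amplification biases introduced during library preparation.
#'
#' @param alignments alignment data.table of the accepted reads.
#' @param reads read table supplying the sequences (matched by `read_id`).
#' @param lmax number of read positions to report; default: longest
#'   aligned read.
#' @return object of class `nuc_freq_matrix`: list with `freq`
#'   (`lmax` x 5 matrix, rows sum to 1 where covered) and `coverage`
#'   (reads covering each position).
#' @export
nucleotide_freqs <- function(alignments, reads, lmax = NULL) {
  al <- data.table::as.data.table(alignments)
  idx <- match(al$read_id, reads$read_id)
  if (anyNA(idx)) stop(sum(is.na(idx)), " aligned read id(s) missing from reads")
  seqs <- reads$bases[idx]
  len <- nchar(seqs)
  if (is.null(lmax)) lmax <- max(len)
  lmax <- as.integer(lmax)

  bases <- c("A", "C", "G", "T", "N")
  freq <- matrix(NA_real_, nrow = lmax, ncol = 5L,
                 dimnames = list(NULL, bases))
  coverage <- integer(lmax)
  for (j in seq_len(lmax)) {
    cj <- substring(seqs, j, j)
    cj <- cj[cj != ""]
    coverage[j] <- length(cj)
    if (length(cj) > 0L) {
      tab <- table(factor(cj, levels = bases))
      freq[j, ] <- as.numeric(tab) / length(cj)
    }
  }
  structure(list(freq = freq, coverage = coverage), class = "nuc_freq_matrix")
}

#' Per-gene positional read profile for selected lengths
#'
#' The gene's matrix summed over the selected read lengths, with positions
#' annotated relative to the start codon -- the per-gene view of where
#' reads of specific lengths fall along an ORF.
#'
#' @param store a `dataset_store`.
#' @param gene gene id.
#' @param lengths read-length subset (default: all lengths in the store).
#' @return data.frame with `position` (nt relative to the first base of
#'   the start codon) and `count`.
#' @export
gene_profile <- function(store, gene, lengths = NULL) {
  stopifnot(inherits(store, "dataset_store"))
  if (!gene %in% names(store$matrices)) stop("unknown gene: ", gene)
  rows <- .length_rows(store, lengths)
  fp <- store$fingerprint
  i <- match(gene, fp$gene_id)
  v <- colSums(store$matrices[[gene]][rows, , drop = FALSE])
  data.frame(position = seq_along(v) - 1L - fp$start_codon_pos[i],
             count = as.numeric(v))
}
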