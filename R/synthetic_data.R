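# Synthetic transcriptomes and reads with the statistical structure the QC
# suite assumes, plus a per-read truth table, so every pipeline stage is
# verifiable without external downloads.
#
# All generators are pure functions of (annotation, config, seed): a single
# integer seed drives one R RNG stream per operation, with fixed offsets
# per stage (transcriptome +0, gene weights +7, footprints +1, RNA-seq +2,
# contamination +3) so the stages are independently reproducible. Quality
# strings are constant high quality ("I", Q40): the pipeline never reads
# qualities, and nothing should silently start to.
#
# Two generator guarantees keep the truth table exact under the pipeline's
# own rules:
#   * reads whose insert would confuse the adapter trimmer (an internal
#     full-adapter occurrence or a terminal adapter-prefix coincidence)
#     are resampled at generation time;
#   * synthetic rRNA contaminants share no k-mer with the transcriptome
#     (see generate_contaminants()), so the k-mer filter removes exactly
#     the planted reads and no genuine footprint.

STOP_CODONS <- c("TAA", "TAG", "TGA")

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe a footprint library: read-length mode at 30 nt over
#' 28-32 nt (a translating ribosome protects ~30 nt), 90% of 5' ends in
#' frame 0, a 5-fold initiation peak and 3-fold termination peak in A-site
#' occupancy, a fixed 15 nt 5'-end-to-A-site offset, and a 3' adapter.
#'
#' @param n_genes number of genes.
#' @param orf_length_range ORF length range in codons (stop included).
#' @param buffer_left,buffer_right fixed UTR buffer widths in nt.
#' @param n_reads reads to simulate.
#' @param length_distribution named probability vector over read lengths.
#' @param frame_fidelity probability a footprint 5' end lands in frame 0;
#'   otherwise it is jittered +/-1 nt.
#' @param start_peak_factor,stop_peak_factor A-site density multipliers at
#'   the initiation and termination codons (>= 1).
#' @param asite_offset nt from a footprint's 5' end to the first base of
#'   its A-site codon.
#' @param nuc_bias optional per-read-position base bias: a named list
#'   mapping read position (1-based) to a named probability vector over
#'   A/C/G/T with which the base at that position is redrawn.
#' @param adapter 3' adapter sequence appended to every read (`""` for
#'   none).
#' @param adapter_min_overlap,adapter_max_mismatch_rate trimming parameters
#'   the generator's unambiguity guarantee is evaluated against.
#' @param rrna_fraction fraction of reads replaced by rRNA contaminants.
#' @param rrna_seqs contaminant sequences (see [generate_contaminants()]).
#' @param rrna_k k-mer size the contaminant guarantee is built for.
#' @param rnaseq_length_distribution length distribution for RNA-seq-like
#'   reads (default: uniform over 28-40 nt).
#' @param gene_weights optional per-gene sampling weights; default:
#'   log-normal(0, 1) draws derived from `seed`.
#' @param shared_block_codons if > 0, an identical in-frame codon block of
#'   this length is planted in genes 1 and 2 so the multimap-discard path
#'   can be exercised deterministically.
#' @param seed single integer seed driving every stage.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 50L,
                       orf_length_range = c(100L, 350L),
                       buffer_left = 50L, buffer_right = 50L,
                       n_reads = 10000L,
                       length_distribution = c(`28` = 0.1, `29` = 0.2,
                                               `30` = 0.4, `31` = 0.2,
                                               `32` = 0.1),
                       frame_fidelity = 0.9,
                       start_peak_factor = 5, stop_peak_factor = 3,
                       asite_offset = 15L,
                       nuc_bias = NULL,
                       adapter = "CTGTAGGCACC",
                       adapter_min_overlap = 5L,
                       adapter_max_mismatch_rate = 0,
                       rrna_fraction = 0,
                       rrna_seqs = NULL,
                       rrna_k = 15L,
                       rnaseq_length_distribution = NULL,
                       gene_weights = NULL,
                       shared_block_codons = 0L,
                       seed = 42L) {
  if (is.null(rnaseq_length_distribution))
    rnaseq_length_distribution <- setNames(rep(1 / 13, 13), 28:40)
  cfg <- list(n_genes = as.integer(n_genes),
              orf_length_range = as.integer(orf_length_range),
              buffer_left = as.integer(buffer_left),
              buffer_right = as.integer(buffer_right),
              n_reads = as.integer(n_reads),
              length_distribution = length_distribution,
              frame_fidelity = frame_fidelity,
              start_peak_factor = start_peak_factor,
              stop_peak_factor = stop_peak_factor,
              asite_offset = as.integer(asite_offset),
              nuc_bias = nuc_bias,
              adapter = adapter,
              adapter_min_overlap = as.integer(adapter_min_overlap),
              adapter_max_mismatch_rate = adapter_max_mismatch_rate,
              rrna_fraction = rrna_fraction,
              rrna_seqs = rrna_seqs,
              rrna_k = as.integer(rrna_k),
              rnaseq_length_distribution = rnaseq_length_distribution,
              gene_weights = gene_weights,
              shared_block_codons = as.integer(shared_block_codons),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L,
            length(cfg$orf_length_range) == 2L,
            cfg$orf_length_range[1] >= 10L,
            cfg$orf_length_range[1] <= cfg$orf_length_range[2],
            cfg$buffer_left >= 0L, cfg$buffer_right >= 0L,
            abs(sum(cfg$length_distribution) - 1) < 1e-8,
            abs(sum(cfg$rnaseq_length_distribution) - 1) < 1e-8,
            cfg$frame_fidelity >= 0, cfg$frame_fidelity <= 1,
            cfg$start_peak_factor >= 1, cfg$stop_peak_factor >= 1,
            cfg$asite_offset >= 0L,
            cfg$rrna_fraction >= 0, cfg$rrna_fraction <= 1)
  structure(cfg, class = "sim_config")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_codons <- function(n) {
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic ORF-centric transcriptome
#'
#' Random transcript sequences with an ATG start, no internal in-frame stop
#' codon, a terminal stop, and fixed-width UTR buffers. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an `annotation_set` (directly usable by every downstream stage,
#'   and writable with [write_transcriptome()]).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_codons <- sample(seq(cfg$orf_length_range[1], cfg$orf_length_range[2]),
                       cfg$n_genes, replace = TRUE)
    seqs <- vapply(n_codons, function(k) {
      paste0(.random_bases(cfg$buffer_left),
             "ATG", .random_codons(k - 2L), sample(STOP_CODONS, 1L),
             .random_bases(cfg$buffer_right))
    }, character(1))

    if (cfg$shared_block_codons > 0L) {
      stopifnot(cfg$n_genes >= 2L,
                cfg$orf_length_range[1] >= cfg$shared_block_codons + 12L)
      from <- cfg$buffer_left + 30L  # codon 11 onwards, in frame
      w <- 3L * cfg$shared_block_codons
      block <- substr(seqs[1], from + 1L, from + w)
      substr(seqs[2], from + 1L, from + w) <- block
    }

    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- gene_ids
    records <- data.frame(
      gene_id = gene_ids,
      tx_length = nchar(seqs),
      buffer_left = cfg$buffer_left,
      buffer_right = cfg$buffer_right,
      start_codon_pos = cfg$buffer_left,
      stop_codon_pos = cfg$buffer_left + 3L * n_codons - 3L,
      orf_length = 3L * n_codons,
      stringsAsFactors = FALSE
    )
    structure(
      list(records = records, sequences = dna,
           excluded = data.frame(gene_id = character(), reason = character()),
           warnings = character(),
           source = list(fasta = NA_character_, gff = NA_character_,
                         generator_seed = cfg$seed)),
      class = "annotation_set")
  })
}

.gene_weights <- function(cfg, n_genes) {
  if (!is.null(cfg$gene_weights)) {
    stopifnot(length(cfg$gene_weights) == n_genes, all(cfg$gene_weights > 0))
    return(cfg$gene_weights / sum(cfg$gene_weights))
  }
  with_seed(cfg$seed + 7L, {
    w <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    w / sum(w)
  })
}

# TRUE for reads whose full sequence (insert + adapter) does not trim back
# to exactly the insert under the configured trimming rule.
.trim_ambiguous <- function(inserts, cfg) {
  if (!nzchar(cfg$adapter)) return(rep(FALSE, length(inserts)))
  full <- paste0(inserts, cfg$adapter)
  tr <- trim_adapter(
    data.table::data.table(read_id = as.character(seq_along(full)),
                           bases = full, quals = strrep("I", nchar(full))),
    adapter = cfg$adapter, min_overlap = cfg$adapter_min_overlap,
    max_mismatch_rate = cfg$adapter_max_mismatch_rate)
  tr$bases != inserts
}

#' Simulate ribosome footprint reads
#'
#' For each read a gene is drawn proportional to the gene weights; an
#' A-site codon is drawn from a within-gene density with `start_peak_factor`
#' at the initiation codon and `stop_peak_factor` at the termination codon;
#' the 5' end is placed at `A-site codon start - asite_offset`, jittered
#' +/-1 nt with probability `1 - frame_fidelity`; the length is drawn from
#' `length_distribution`; bases are copied from the transcript (sense
#' strand), the optional position-specific base bias is applied, and the
#' adapter appended. Reads that would overrun the transcript are resampled
#' (bounded retries, then skipped and counted).
#'
#' @param annotation an `annotation_set` (typically from
#'   [generate_transcriptome()]).
#' @param cfg a [sim_config()]; the RNG stream is seeded with
#'   `cfg$seed + 1`.
#' @return list with `reads` (read table, adapter included in `bases`),
#'   `truth` (data.table: read_id, origin, gene_id, true_pos_5p,
#'   true_length, frame, asite_codon, was_adapter_appended) and
#'   `n_skipped` (reads dropped after bounded resampling).
#' @export
simulate_footprints <- function(annotation, cfg) {
  stopifnot(inherits(annotation, "annotation_set"), inherits(cfg, "sim_config"))
  rec <- annotation$records
  seq_str <- as.character(annotation$sequences)
  w <- .gene_weights(cfg, nrow(rec))
  lens <- as.integer(names(cfg$length_distribution))

  codon_weights <- lapply(seq_len(nrow(rec)), function(i) {
    k <- rec$orf_length[i] %/% 3L
    cw <- rep(1, k)
    cw[1] <- cfg$start_peak_factor
    cw[k] <- cfg$stop_peak_factor
    cw
  })

  with_seed(cfg$seed + 1L, {
    draw <- function(gi) {
      # draw codon, jitter, and length for reads assigned to genes gi
      n <- length(gi)
      k0 <- integer(n)
      for (g in unique(gi)) {
        sel <- gi == g
        k0[sel] <- sample.int(length(codon_weights[[g]]), sum(sel),
                              replace = TRUE, prob = codon_weights[[g]]) - 1L
      }
      jit <- integer(n)
      off_frame <- runif(n) >= cfg$frame_fidelity
      jit[off_frame] <- sample(c(-1L, 1L), sum(off_frame), replace = TRUE)
      L <- lens[sample.int(length(lens), n, replace = TRUE,
                           prob = cfg$length_distribution)]
      pos <- rec$start_codon_pos[gi] + 3L * k0 - cfg$asite_offset + jit
      list(k0 = k0, pos = pos, L = L)
    }

    gi <- sample.int(nrow(rec), cfg$n_reads, replace = TRUE, prob = w)
    d <- draw(gi)
    n_skipped <- 0L
    for (round in seq_len(10L)) {
      bad <- d$pos < 0L | d$pos + d$L > rec$tx_length[gi]
      if (!any(bad)) break
      if (round == 10L) {
        n_skipped <- sum(bad)
        keep <- !bad
        gi <- gi[keep]
        d <- lapply(d, `[`, keep)
        break
      }
      nd <- draw(gi[bad])
      d$k0[bad] <- nd$k0; d$pos[bad] <- nd$pos; d$L[bad] <- nd$L
    }

    make_inserts <- function(idx) {
      ins <- substring(seq_str[gi[idx]], d$pos[idx] + 1L,
                       d$pos[idx] + d$L[idx])
      if (!is.null(cfg$nuc_bias)) {
        for (p_chr in names(cfg$nuc_bias)) {
          p <- as.integer(p_chr)
          pv <- cfg$nuc_bias[[p_chr]]
          hit <- d$L[idx] >= p
          if (any(hit)) {
            nb <- sample(names(pv), sum(hit), replace = TRUE, prob = pv)
            s <- ins[hit]
            substr(s, p, p) <- nb
            ins[hit] <- s
          }
        }
      }
      ins
    }

    inserts <- make_inserts(seq_along(gi))
    for (round in seq_len(20L)) {
      amb <- .trim_ambiguous(inserts, cfg)
      if (!any(amb)) break
      if (round == 20L) stop("could not resolve adapter-ambiguous reads")
      nd <- draw(gi[amb])
      ok <- nd$pos >= 0L & nd$pos + nd$L <= rec$tx_length[gi[amb]]
      rd <- which(amb)[ok]
      d$k0[rd] <- nd$k0[ok]; d$pos[rd] <- nd$pos[ok]; d$L[rd] <- nd$L[ok]
      inserts[rd] <- make_inserts(rd)
    }

    has_adapter <- nzchar(cfg$adapter)
    bases <- if (has_adapter) paste0(inserts, cfg$adapter) else inserts
    truth <- data.table::data.table(
      read_id = sprintf("fp%07d", seq_along(gi)),
      origin = "gene",
      gene_id = rec$gene_id[gi],
      true_pos_5p = d$pos,
      true_length = d$L,
      frame = (d$pos - rec$start_codon_pos[gi]) %% 3L,
      asite_codon = d$k0,
      was_adapter_appended = has_adapter
    )
    reads <- data.table::data.table(
      read_id = truth$read_id, bases = bases, quals = strrep("I", nchar(bases)))
    list(reads = reads, truth = truth, n_skipped = n_skipped)
  })
}

#' Simulate RNA-seq-like reads
#'
#' Uniform 5'-end positions over each transcript and lengths from
#' `rnaseq_length_distribution`: no frame structure, no start/stop peaks --
#' the no-periodicity control. Seeded with `cfg$seed + 2`.
#'
#' @inheritParams simulate_footprints
#' @return as [simulate_footprints()]; `asite_codon` is `NA`.
#' @export
simulate_rnaseq <- function(annotation, cfg) {
  stopifnot(inherits(annotation, "annotation_set"), inherits(cfg, "sim_config"))
  rec <- annotation$records
  seq_str <- as.character(annotation$sequences)
  w <- .gene_weights(cfg, nrow(rec))
  lens <- as.integer(names(cfg$rnaseq_length_distribution))

  with_seed(cfg$seed + 2L, {
    gi <- sample.int(nrow(rec), cfg$n_reads, replace = TRUE, prob = w)
    L <- lens[sample.int(length(lens), cfg$n_reads, replace = TRUE,
                         prob = cfg$rnaseq_length_distribution)]
    pos <- as.integer(floor(runif(cfg$n_reads) * (rec$tx_length[gi] - L + 1L)))
    inserts <- substring(seq_str[gi], pos + 1L, pos + L)

    for (round in seq_len(20L)) {
      amb <- .trim_ambiguous(inserts, cfg)
      if (!any(amb)) break
      if (round == 20L) stop("could not resolve adapter-ambiguous reads")
      n <- sum(amb)
      L[amb] <- lens[sample.int(length(lens), n, replace = TRUE,
                                prob = cfg$rnaseq_length_distribution)]
      pos[amb] <- as.integer(floor(runif(n) * (rec$tx_length[gi[amb]] - L[amb] + 1L)))
      inserts[amb] <- substring(seq_str[gi[amb]], pos[amb] + 1L, pos[amb] + L[amb])
    }

    has_adapter <- nzchar(cfg$adapter)
    bases <- if (has_adapter) paste0(inserts, cfg$adapter) else inserts
    truth <- data.table::data.table(
      read_id = sprintf("rs%07d", seq_along(gi)),
      origin = "gene",
      gene_id = rec$gene_id[gi],
      true_pos_5p = pos,
      true_length = L,
      frame = (pos - rec$start_codon_pos[gi]) %% 3L,
      asite_codon = NA_integer_,
      was_adapter_appended = has_adapter
    )
    reads <- data.table::data.table(
      read_id = truth$read_id, bases = bases, quals = strrep("I", nchar(bases)))
    list(reads = reads, truth = truth, n_skipped = 0L)
  })
}

#' Generate rRNA-like contaminant sequences
#'
#' Random sequences guaranteed to share no `k`-mer with the transcriptome,
#' so the exact k-mer filter removes exactly the planted contaminant reads
#' and never a genuine footprint. These are synthetic stand-ins for real
#' rRNA references, built for clean truth tables rather than biological
#' realism.
#'
#' @param annotation the `annotation_set` the contaminants must avoid.
#' @param n number of contaminant sequences.
#' @param length length of each, in nt.
#' @param k k-mer size of the guarantee (match the filter's `k`).
#' @param seed RNG seed.
#' @return named [Biostrings::DNAStringSet] (`rrna_1`, `rrna_2`, ...).
#' @export
generate_contaminants <- function(annotation, n = 2L, length = 1500L,
                                  k = 15L, seed = 1L) {
  stopifnot(inherits(annotation, "annotation_set"), length >= k)
  tx <- as.character(annotation$sequences)
  tx_kmers <- unique(unlist(lapply(tx, function(s) {
    nk <- nchar(s) - k + 1L
    substring(s, seq_len(nk), seq_len(nk) + k - 1L)
  }), use.names = FALSE))

  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      s <- .random_bases(length)
      for (iter in seq_len(200L)) {
        nk <- nchar(s) - k + 1L
        km <- substring(s, seq_len(nk), seq_len(nk) + k - 1L)
        bad <- which(data.table::`%chin%`(km, tx_kmers))
        if (length(bad) == 0L) return(s)
        # mutate the last base of each offending k-mer
        for (p in unique(pmin(bad + k - 1L, nchar(s)))) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      stop("could not generate a transcriptome-disjoint contaminant")
    }, character(1))
    dna <- Biostrings::DNAStringSet(out)
    names(dna) <- paste0("rrna_", seq_len(n))
    dna
  })
}

#' Plant rRNA contaminant reads into a simulated read set
#'
#' Each read is independently replaced, with probability
#' `cfg$rrna_fraction`, by a verbatim substring of a contaminant sequence
#' of the same insert length (the adapter is re-appended when the original
#' read carried one); the truth table is updated (`origin = "rrna"`,
#' `gene_id` = contaminant name, `true_pos_5p` = substring start).
#' Seeded with `cfg$seed + 3`.
#'
#' @param sim output of [simulate_footprints()] / [simulate_rnaseq()].
#' @param cfg a [sim_config()] with `rrna_seqs` set when
#'   `rrna_fraction > 0`.
#' @return the updated `sim` list.
#' @export
contaminate <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$rrna_fraction == 0) return(sim)
  if (is.null(cfg$rrna_seqs))
    stop("rrna_seqs must be provided when rrna_fraction > 0")
  rr <- as.character(cfg$rrna_seqs)
  rr_names <- names(cfg$rrna_seqs)
  if (is.null(rr_names)) rr_names <- paste0("rrna_", seq_along(rr))

  reads <- data.table::copy(sim$reads)
  truth <- data.table::copy(sim$truth)

  with_seed(cfg$seed + 3L, {
    hit <- which(runif(nrow(reads)) < cfg$rrna_fraction)
    if (length(hit) == 0L) {
      sim
    } else {
      ins_len <- truth$true_length[hit]
      if (any(nchar(rr) < max(ins_len)))
        stop("contaminant sequence shorter than a read insert (",
             max(ins_len), " nt)")
      if (any(ins_len < cfg$rrna_k))
        warning("some contaminant inserts are shorter than k = ", cfg$rrna_k,
                "; the k-mer filter will not remove them")

      si <- sample.int(length(rr), length(hit), replace = TRUE)
      start0 <- integer(length(hit))
      ins <- character(length(hit))
      redo <- rep(TRUE, length(hit))
      for (iter in seq_len(50L)) {
        if (!any(redo)) break
        if (iter == 50L) stop("could not place unambiguous contaminant inserts")
        n <- sum(redo)
        start0[redo] <- as.integer(floor(
          runif(n) * (nchar(rr)[si[redo]] - ins_len[redo] + 1L)))
        ins[redo] <- substring(rr[si[redo]], start0[redo] + 1L,
                               start0[redo] + ins_len[redo])
        redo[redo] <- .trim_ambiguous(ins[redo], cfg)
      }

      with_ad <- truth$was_adapter_appended[hit]
      new_bases <- ifelse(with_ad, paste0(ins, cfg$adapter), ins)
      reads[hit, `:=`(bases = new_bases, quals = strrep("I", nchar(new_bases)))]
      truth[hit, `:=`(origin = "rrna", gene_id = rr_names[si],
                      true_pos_5p = start0, frame = NA_integer_,
                      asite_codon = NA_integer_)]
      list(reads = reads, truth = truth, n_skipped = sim$n_skipped)
    }
  })
}

#' Write / read a truth table as TSV
#'
#' @param truth truth data.table (see [simulate_footprints()]).
#' @param path TSV path.
#' @return invisibly `path` (writer); the truth data.table (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA",
                    colClasses = list(character = c("read_id", "origin", "gene_id")))
}
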