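# End-to-end orchestration from a single config: simulate | prepare |
# count | qc | quantify | all. The command-line entry point
# (exec/ribopipe) is a thin wrapper over these functions.
#
# Config precedence is command line > YAML config > defaults; every stage
# writes its outputs plus a provenance snapshot (config, stage counts,
# package version) into the output directory, and logs counts at every
# stage boundary.

#' Default run configuration
#'
#' All paths and parameters of a pipeline run, overridable via a YAML file
#' ([load_run_config()]) and/or individual arguments.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    # paths
    fasta = NULL, gff = NULL, fastq = NULL, sam = NULL,
    contaminants = NULL, features = NULL, offsets = NULL,
    reference_panel_dir = NULL, outdir = "ribopipe_out",
    # identity
    dataset_id = "dataset", seed = 42L,
    # read prep
    adapter = "CTGTAGGCACC", min_overlap = 5L, max_mismatch_rate = 0,
    lmin = 25L, lmax = 35L, k = 15L,
    # qc
    min_reads = 64L, n_bins = 50L, window_up = 25L, window_down = 25L,
    candidate_periods = 2:10, peak_ratio_threshold = 2, min_total = 100L,
    # simulation (passed to sim_config(); seed is shared)
    sim = list()
  )
}

#' Load a run configuration from YAML
#'
#' Values in the file override the defaults; anything not mentioned keeps
#' its default. `overrides` (e.g. from command-line flags) take precedence
#' over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied last.
#' @return the merged configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      config[[k]] <- if (k == "sim") utils::modifyList(config$sim, user$sim)
                     else user[[k]]
    }
  }
  for (k in names(overrides)) {
    if (!is.null(overrides[[k]])) config[[k]] <- overrides[[k]]
  }
  config$seed <- as.integer(config$seed)
  config
}

.log_stage <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "[%H:%M:%S] "), ...)
  message(msg)
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

.write_provenance <- function(outdir, config, counts = NULL) {
  snap <- list(
    package = "ribopipe",
    version = as.character(utils::packageVersion("ribopipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1))],
    counts = counts
  )
  jsonlite::write_json(snap, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.params_sidecar <- function(path, params) {
  jsonlite::write_json(params, paste0(tools::file_path_sans_ext(path),
                                      ".params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Generate a complete synthetic fixture set
#'
#' Writes transcriptome FASTA/GFF3, footprint FASTQ (plus an RNA-seq-like
#' FASTQ), contaminant FASTA, per-read truth table, and an external feature
#' TSV (synthetic folding energies and poly(A) lengths) into
#' `config$outdir`. Everything is deterministic under `config$seed`.
#'
#' @param config a run configuration (see [load_run_config()]).
#' @return invisibly, a named list of the paths written (reusable directly
#'   as config entries for [run_prepare()]).
#' @export
run_simulate <- function(config = default_run_config()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
  cfg <- do.call(sim_config, sim_args)

  txome <- generate_transcriptome(cfg)
  paths <- list(fasta = file.path(outdir, "transcriptome.fa"),
                gff = file.path(outdir, "transcriptome.gff3"),
                fastq = file.path(outdir, "footprints.fastq"),
                fastq_rnaseq = file.path(outdir, "rnaseq.fastq"),
                truth = file.path(outdir, "truth.tsv"),
                truth_rnaseq = file.path(outdir, "truth_rnaseq.tsv"),
                contaminants = NULL,
                features = file.path(outdir, "features_external.tsv"))
  write_transcriptome(txome, paths$fasta, paths$gff)
  .log_stage(outdir, "simulate: ", nrow(txome$records), " genes written")

  if (cfg$rrna_fraction > 0 && is.null(cfg$rrna_seqs)) {
    cfg$rrna_seqs <- generate_contaminants(txome, k = cfg$rrna_k,
                                           seed = cfg$seed + 5L)
  }
  if (!is.null(cfg$rrna_seqs)) {
    paths$contaminants <- file.path(outdir, "contaminants.fa")
    Biostrings::writeXStringSet(cfg$rrna_seqs, paths$contaminants)
  }

  fp <- simulate_footprints(txome, cfg)
  fp <- contaminate(fp, cfg)
  write_fastq(fp$reads, paths$fastq)
  write_truth_tsv(fp$truth, paths$truth)
  .log_stage(outdir, "simulate: ", nrow(fp$reads), " footprint reads (",
             sum(fp$truth$origin == "rrna"), " rRNA-planted, ",
             fp$n_skipped, " skipped)")

  rs <- simulate_rnaseq(txome, cfg)
  write_fastq(rs$reads, paths$fastq_rnaseq)
  write_truth_tsv(rs$truth, paths$truth_rnaseq)
  .log_stage(outdir, "simulate: ", nrow(rs$reads), " RNA-seq-like reads")

  # synthetic external features (measured outside the pipeline in reality)
  with_seed(cfg$seed + 9L, {
    ext <- data.frame(
      gene_id = txome$records$gene_id,
      folding_energy = round(-runif(nrow(txome$records), 5, 60), 2),
      polya_length = as.integer(rpois(nrow(txome$records), 40))
    )
    data.table::fwrite(ext, paths$features, sep = "\t")
  })

  .write_provenance(outdir, config,
                    counts = list(n_genes = nrow(txome$records),
                                  n_footprint_reads = nrow(fp$reads),
                                  n_rnaseq_reads = nrow(rs$reads)))
  invisible(paths)
}

#' Run read preparation: trim, length-filter, rRNA-filter, align
#'
#' Stages raw FASTQ reads through adapter trimming, the length window,
#' k-mer rRNA filtering and the built-in exact aligner -- or ingests
#' SAM/BAM alignments when `config$sam` is set. Writes `alignments.tsv`,
#' `processed.fastq` (the accepted reads, trimmed), `prep_stats.tsv` and a
#' provenance snapshot to `config$outdir`.
#'
#' @param config run configuration with `fasta`, `gff` and `fastq` (or
#'   `sam`) set.
#' @return invisibly, list with `alignments`, `stats`, `annotation`,
#'   `reads` (the prepared read table).
#' @export
run_prepare <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  annotation <- load_transcriptome(config$fasta, config$gff)
  .log_stage(outdir, "prepare: annotation loaded (",
             nrow(annotation$records), " genes)")

  if (!is.null(config$sam)) {
    res <- read_alignments_sam(config$sam, annotation,
                               lmin = config$lmin, lmax = config$lmax)
    alignments <- res$alignments
    stats <- res$stats
    reads <- NULL
    .log_stage(outdir, "prepare: ingested ", stats$n_input,
               " SAM records, accepted ", stats$n_accepted)
  } else {
    reads <- read_fastq(config$fastq)
    n_input <- nrow(reads)
    .log_stage(outdir, "prepare: ", n_input, " reads in")

    n_trimmed <- 0L
    if (!is.null(config$adapter) && nzchar(config$adapter)) {
      reads <- trim_adapter(reads, config$adapter,
                            min_overlap = config$min_overlap,
                            max_mismatch_rate = config$max_mismatch_rate)
      n_trimmed <- sum(reads$adapter_trimmed)
      .log_stage(outdir, "prepare: adapter trimmed from ", n_trimmed, " reads")
    }

    fl <- filter_length(reads, config$lmin, config$lmax)
    .log_stage(outdir, "prepare: ", fl$discarded_count,
               " reads outside [", config$lmin, ", ", config$lmax, "] nt")

    n_rrna <- 0L
    kept <- fl$kept
    if (!is.null(config$contaminants)) {
      rr <- filter_rrna(kept, config$contaminants, k = config$k)
      kept <- rr$kept
      n_rrna <- rr$removed_count
      .log_stage(outdir, "prepare: ", n_rrna, " rRNA contaminant reads removed")
    }

    al <- align_exact(kept, annotation)
    alignments <- al$alignments
    stats <- prep_stats(
      n_input = n_input,
      n_adapter_trimmed = n_trimmed,
      n_too_short = fl$discarded_count,
      n_rrna_removed = n_rrna,
      n_unaligned = al$stats$n_unaligned,
      n_multimapped = al$stats$n_multimapped,
      n_accepted = al$stats$n_accepted
    )
    .log_stage(outdir, "prepare: aligned ", stats$n_accepted, " / ",
               n_input, " reads (", stats$n_multimapped, " multimapped, ",
               stats$n_unaligned, " unaligned)")
    if (nrow(kept) > 0L)
      write_fastq(kept[kept$read_id %in% alignments$read_id],
                  file.path(outdir, "processed.fastq"))
  }

  write_alignments_tsv(alignments, file.path(outdir, "alignments.tsv"))
  data.table::fwrite(data.table::as.data.table(unclass(stats)),
                     file.path(outdir, "prep_stats.tsv"), sep = "\t")
  .write_provenance(outdir, config, counts = unclass(stats))
  invisible(list(alignments = alignments, stats = stats,
                 annotation = annotation,
                 reads = if (is.null(config$sam)) kept else NULL))
}

#' Build the count store and persist it (HDF5 + TSV)
#'
#' @param config run configuration; uses `alignments.tsv` from
#'   `config$outdir` (as written by [run_prepare()]).
#' @return invisibly, the `dataset_store` (also written to `counts.h5` and
#'   per-gene TSVs under `genes/`).
#' @export
run_count <- function(config) {
  outdir <- config$outdir
  annotation <- load_transcriptome(config$fasta, config$gff)
  alignments <- read_alignments_tsv(file.path(outdir, "alignments.tsv"))
  store <- build_count_matrices(alignments, annotation,
                                lmin = config$lmin, lmax = config$lmax,
                                dataset_id = config$dataset_id)
  write_counts_h5(store, file.path(outdir, "counts.h5"))
  export_gene_tsv(store, file.path(outdir, "genes"))
  .log_stage(outdir, "count: ", sum(reads_per_gene(store)), " reads in ",
             length(store$matrices), " gene matrices -> counts.h5")
  invisible(store)
}

#' Run the QC / metagene suite
#'
#' Computes the frame distribution, the ORF periodicity spectrum, start and
#' stop metagene profiles, the read-length histogram, the positional
#' distribution along ORFs, and (when prepared reads are available)
#' position-specific nucleotide frequencies; writes one TSV per statistic
#' with a JSON parameter sidecar.
#'
#' @param config run configuration; reads `counts.h5`, `alignments.tsv` and
#'   `processed.fastq` from `config$outdir`.
#' @return invisibly, a named list of the computed statistics.
#' @export
run_qc <- function(config) {
  outdir <- config$outdir
  store <- read_counts_h5(file.path(outdir, "counts.h5"))
  out <- list()

  fr <- frame_distribution(store)
  f <- file.path(outdir, "frame_distribution.tsv")
  data.table::fwrite(data.table::data.table(
    frame = 0:2, count = as.integer(fr$counts), fraction = fr$fractions),
    f, sep = "\t")
  .params_sidecar(f, list(n_reads = fr$n_reads))
  out$frame <- fr

  prof <- orf_profile(store)
  sp <- periodicity_spectrum(prof,
                             candidate_periods = config$candidate_periods,
                             min_total = config$min_total,
                             peak_ratio_threshold = config$peak_ratio_threshold)
  f <- file.path(outdir, "periodicity.tsv")
  data.table::fwrite(data.table::data.table(
    period = sp$periods, power = sp$power, ratio = sp$ratio), f, sep = "\t")
  .params_sidecar(f, list(dominant_period = sp$dominant_period,
                          peak_to_mean = sp$peak_to_mean,
                          threshold = config$peak_ratio_threshold,
                          n_segments = sp$n_segments,
                          total_counts = sp$total_counts))
  out$periodicity <- sp
  .log_stage(outdir, "qc: dominant period ",
             if (is.na(sp$dominant_period)) "none" else sp$dominant_period)

  for (anchor in c("start", "stop")) {
    mg <- tryCatch(
      metagene_profile(store, anchor, window_up = config$window_up,
                       window_down = config$window_down,
                       min_reads = config$min_reads),
      error = function(e) NULL)
    if (is.null(mg)) {
      .log_stage(outdir, "qc: metagene (", anchor, ") skipped: no eligible gene")
      next
    }
    f <- file.path(outdir, paste0("metagene_", anchor, ".tsv"))
    data.table::fwrite(data.table::data.table(
      position = mg$positions, density = mg$density), f, sep = "\t")
    .params_sidecar(f, list(anchor = anchor, n_genes = mg$n_genes,
                            window_up = config$window_up,
                            window_down = config$window_down,
                            min_reads = config$min_reads))
    out[[paste0("metagene_", anchor)]] <- mg
  }

  lh <- read_length_hist(store)
  f <- file.path(outdir, "read_length_hist.tsv")
  data.table::fwrite(data.table::data.table(
    read_length = as.integer(names(lh)), count = as.integer(lh)), f, sep = "\t")
  .params_sidecar(f, list(lmin = store$lmin, lmax = store$lmax))
  out$length_hist <- lh

  pd <- tryCatch(positional_distribution(store, n_bins = config$n_bins,
                                         min_reads = config$min_reads),
                 error = function(e) NULL)
  if (!is.null(pd)) {
    f <- file.path(outdir, "positional_distribution.tsv")
    data.table::fwrite(data.table::data.table(
      bin_start = utils::head(pd$breaks, -1),
      bin_end = utils::tail(pd$breaks, -1),
      density = pd$density), f, sep = "\t")
    .params_sidecar(f, list(n_bins = config$n_bins,
                            min_reads = config$min_reads,
                            n_genes = pd$n_genes))
    out$positional <- pd
  }

  pf <- file.path(outdir, "processed.fastq")
  af <- file.path(outdir, "alignments.tsv")
  if (file.exists(pf) && file.exists(af)) {
    reads <- read_fastq(pf)
    alignments <- read_alignments_tsv(af)
    nf <- nucleotide_freqs(alignments, reads)
    f <- file.path(outdir, "nucleotide_freqs.tsv")
    data.table::fwrite(data.table::data.table(
      position = seq_len(nrow(nf$freq)), nf$freq, coverage = nf$coverage),
      f, sep = "\t")
    .params_sidecar(f, list(n_reads = nrow(alignments)))
    out$nuc_freq <- nf
  }

  .write_provenance(outdir, config)
  invisible(out)
}

#' Quantify expression and correlate with sequence features
#'
#' Writes the RPKM expression table, the Spearman correlation report of
#' RPKM against sequence features (merged with the external feature TSV
#' when `config$features` is set), and -- when a reference panel directory
#' is configured -- per-gene log2 relative abundances against the panel.
#'
#' @param config run configuration; reads `counts.h5` from `config$outdir`.
#' @return invisibly, list with `expression`, `correlations`,
#'   `relative_abundance` (or `NULL`).
#' @export
run_quantify <- function(config) {
  outdir <- config$outdir
  store <- read_counts_h5(file.path(outdir, "counts.h5"))
  annotation <- load_transcriptome(config$fasta, config$gff)

  expr <- compute_rpkm(store)
  write_expression_tsv(expr, file.path(outdir, "expression.tsv"))
  .log_stage(outdir, "quantify: ", attr(expr, "n_total_orf_reads"),
             " ORF reads over ", nrow(expr), " genes")

  features <- compute_sequence_features(annotation)
  if (!is.null(config$features))
    features <- join_external_features(features, config$features)
  corr <- feature_correlations(expr, features)
  data.table::fwrite(corr, file.path(outdir, "feature_correlations.tsv"),
                     sep = "\t")

  rel <- NULL
  if (!is.null(config$reference_panel_dir)) {
    panel <- load_reference_panel(config$reference_panel_dir)
    rel <- data.table::rbindlist(lapply(expr$gene_id, function(g) {
      r <- tryCatch(relative_abundance(g, expr, panel),
                    error = function(e) NULL)
      if (is.null(r)) NULL
      else data.table::data.table(gene_id = g, log2_ratio = r$log2_ratio,
                                  rpkm = r$rpkm, panel_median = r$panel_median,
                                  n_panel = r$n_panel, floored = r$floored)
    }))
    data.table::fwrite(rel, file.path(outdir, "relative_abundance.tsv"),
                       sep = "\t")
    .log_stage(outdir, "quantify: relative abundance for ", nrow(rel),
               " genes against ", length(panel), " reference datasets")
  }

  .write_provenance(outdir, config)
  invisible(list(expression = expr, correlations = corr,
                 relative_abundance = rel))
}

#' Run the whole pipeline on one configuration
#'
#' `simulate` (when no input FASTQ/SAM is configured) then `prepare`,
#' `count`, `qc`, `quantify`.
#'
#' @param config run configuration.
#' @return invisibly, list with the per-stage results.
#' @export
run_all <- function(config) {
  if (is.null(config$fastq) && is.null(config$sam)) {
    paths <- run_simulate(config)
    config$fasta <- paths$fasta
    config$gff <- paths$gff
    config$fastq <- paths$fastq
    config$contaminants <- paths$contaminants
    config$features <- paths$features
  }
  prep <- run_prepare(config)
  store <- run_count(config)
  qc <- run_qc(config)
  quant <- run_quantify(config)
  invisible(list(prepare = prep, store = store, qc = qc, quantify = quant))
}
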