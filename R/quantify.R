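# Gene-level quantification (RPKM), expression-vs-feature rank
# correlations, and relative abundance against a reference dataset panel.
#
# ORF membership of a read is decided by its 5'-end position (consistent
# with the store's keying), so quantification does not depend on the
# A-site offset table.

#' RPKM expression table from a dataset store
#'
#' Counts, per gene, reads whose 5' end lies inside the ORF (stop codon
#' included: `start_codon_pos <= pos_5p < stop_codon_pos + 3`) and
#' normalizes to reads per kilobase of ORF per million mapped ORF reads:
#' `rpkm = 1e9 * orf_read_count / (n_total_orf_reads * orf_length_nt)`.
#'
#' @param store a `dataset_store`.
#' @return object of class `expression_table`: data.frame with `gene_id`,
#'   `orf_read_count`, `orf_length`, `rpkm`; attributes `dataset_id` and
#'   `n_total_orf_reads`.
#' @export
compute_rpkm <- function(store) {
  stopifnot(inherits(store, "dataset_store"))
  fp <- store$fingerprint
  cnt <- vapply(seq_len(nrow(fp)), function(i) {
    m <- store$matrices[[fp$gene_id[i]]]
    cols <- (fp$start_codon_pos[i] + 1L):(fp$stop_codon_pos[i] + 3L)
    sum(m[, cols, drop = FALSE])
  }, numeric(1))
  total <- sum(cnt)
  if (total == 0) stop("no reads mapped inside any ORF; cannot compute RPKM")
  out <- data.frame(
    gene_id = fp$gene_id,
    orf_read_count = as.integer(cnt),
    orf_length = fp$orf_length,
    rpkm = 1e9 * cnt / (total * fp$orf_length),
    stringsAsFactors = FALSE
  )
  attr(out, "dataset_id") <- store$dataset_id
  attr(out, "n_total_orf_reads") <- as.integer(total)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Write / read an expression table as TSV
#'
#' @param expr an `expression_table`.
#' @param path TSV path.
#' @return invisibly `path` (writer); an `expression_table` (reader).
#' @export
write_expression_tsv <- function(expr, path) {
  df <- as.data.frame(expr)
  df$dataset_id <- attr(expr, "dataset_id")
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  dataset_id <- if ("dataset_id" %in% names(df)) df$dataset_id[1] else NA_character_
  df$dataset_id <- NULL
  attr(df, "dataset_id") <- dataset_id
  attr(df, "n_total_orf_reads") <- as.integer(sum(df$orf_read_count))
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Rank correlation of expression with sequence features
#'
#' Spearman correlation of RPKM against each sequence-based feature (ORF
#' length, 5' UTR length, UTR GC content, upstream ATG count, mRNA folding
#' energy, poly(A) tail length), pairwise-complete with average ranks for
#' ties. Rank correlation is used because the features span orders of
#' magnitude and the statistic is invariant to monotone transforms.
#'
#' @param expr an `expression_table`.
#' @param features a `feature_table` (see [compute_sequence_features()]).
#' @param min_n minimum pairwise-complete genes per feature (default 3);
#'   features below it are reported as `NA`.
#' @return object of class `correlation_report`: data.frame with
#'   `feature`, `rho`, `n`.
#' @export
feature_correlations <- function(expr, features, min_n = 3L) {
  stopifnot(inherits(expr, "expression_table"),
            inherits(features, "feature_table"))
  feat_cols <- setdiff(names(features), "gene_id")
  idx <- match(expr$gene_id, features$gene_id)
  out <- data.frame(feature = feat_cols, rho = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(feat_cols)) {
    x <- expr$rpkm
    y <- as.numeric(features[[feat_cols[i]]][idx])
    ok <- !is.na(x) & !is.na(y)
    out$n[i] <- sum(ok)
    # a constant feature (or constant expression) has no defined rank
    # correlation; report NA rather than warn
    if (sum(ok) >= min_n && var(x[ok]) > 0 && var(y[ok]) > 0)
      out$rho[i] <- stats::cor(x[ok], y[ok], method = "spearman")
  }
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Relative abundance of a gene against a reference panel
#'
#' `log2(rpkm in this dataset / median rpkm across the reference panel)`,
#' the per-gene comparison against a curated set of wild-type datasets.
#' A pseudo-RPKM floor (default 0.01) is applied to the numerator only
#' when it is zero, and flagged.
#'
#' @param gene gene id.
#' @param expr the dataset's `expression_table`.
#' @param reference_panel list of `expression_table`s (e.g. from
#'   [load_reference_panel()]).
#' @param pseudo_rpkm floor for a zero numerator.
#' @return list with `log2_ratio`, `rpkm`, `panel_median`, `n_panel`
#'   (reference datasets containing the gene) and `floored`.
#' @export
relative_abundance <- function(gene, expr, reference_panel, pseudo_rpkm = 0.01) {
  stopifnot(inherits(expr, "expression_table"), length(reference_panel) >= 1L)
  i <- match(gene, expr$gene_id)
  if (is.na(i)) stop("gene not in expression table: ", gene)
  ref <- unlist(lapply(reference_panel, function(tbl) {
    j <- match(gene, tbl$gene_id)
    if (is.na(j)) NULL else tbl$rpkm[j]
  }))
  if (is.null(ref) || length(ref) == 0L)
    stop("gene absent from every reference dataset: ", gene)
  if (!any(ref > 0))
    stop("gene has zero abundance across the reference panel: ", gene)
  panel_median <- stats::median(ref)
  if (panel_median <= 0)
    stop("zero median reference abundance for gene: ", gene)

  x <- expr$rpkm[i]
  floored <- x == 0
  if (floored) x <- pseudo_rpkm
  list(log2_ratio = log2(x / panel_median), rpkm = expr$rpkm[i],
       panel_median = panel_median, n_panel = length(ref),
       floored = floored)
}

#' Load a directory of expression tables as a reference panel
#'
#' One TSV per reference dataset, as written by [write_expression_tsv()].
#'
#' @param dir directory of `.tsv` expression tables.
#' @return named list of `expression_table`s.
#' @export
load_reference_panel <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop("no .tsv expression tables in ", dir)
  panel <- lapply(files, read_expression_tsv)
  names(panel) <- tools::file_path_sans_ext(basename(files))
  panel
}
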