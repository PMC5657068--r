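# ORF-centric transcriptome annotation: FASTA + GFF3 loading, validation,
# and sequence-derived gene features.
#
# Coordinate convention: everything internal is 0-based half-open on the
# transcript. GFF3 input/output is 1-based inclusive and converted at the
# boundary. For a transcript laid out as
#   [ 5' buffer | ORF (ATG .. stop, length %% 3 == 0) | 3' buffer ]
# start_codon_pos is the 0-based position of the A of the ATG (== buffer_left)
# and stop_codon_pos is the 0-based position of the first base of the stop
# codon (start_codon_pos + orf_length - 3).

#' Load an ORF-centric transcriptome from FASTA + GFF3
#'
#' Reads one transcript sequence per gene from `fasta_path` and one CDS
#' feature per gene from `gff_path` (1-based inclusive coordinates on the
#' transcript itself, i.e. the GFF `seqid` is the gene id), and builds the
#' validated annotation set every downstream positional statistic is
#' computed against.
#'
#' Genes whose CDS length is not divisible by 3 are excluded (reading-frame
#' statistics would be meaningless) and listed in the validation report.
#' A non-ATG start codon is recorded as a warning but the gene is kept.
#'
#' @param fasta_path path to the transcript FASTA (one record per gene).
#' @param gff_path path to the GFF3 with one `CDS` feature per gene; the
#'   feature's `seqid` must equal the FASTA record name.
#' @return An object of class `annotation_set`: a list with
#'   `records` (data.frame: gene_id, tx_length, buffer_left, buffer_right,
#'   start_codon_pos, stop_codon_pos, orf_length), `sequences`
#'   (named [Biostrings::DNAStringSet] of the retained genes), `excluded`
#'   (data.frame gene_id/reason), `warnings` (character), and `source`.
#' @export
load_transcriptome <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

  gff <- rtracklayer::import(gff_path)
  gff <- gff[gff$type == "CDS"]
  if (length(gff) == 0L) stop("no CDS features in GFF: ", gff_path)
  gff_genes <- as.character(GenomicRanges::seqnames(gff))
  if (anyDuplicated(gff_genes))
    stop("more than one CDS feature for gene(s): ",
         paste(unique(gff_genes[duplicated(gff_genes)]), collapse = ", "))

  only_fasta <- setdiff(names(seqs), gff_genes)
  only_gff <- setdiff(gff_genes, names(seqs))
  if (length(only_fasta) || length(only_gff))
    stop("FASTA/GFF gene id mismatch; FASTA-only: [",
         paste(only_fasta, collapse = ", "), "], GFF-only: [",
         paste(only_gff, collapse = ", "), "]")

  ord <- match(names(seqs), gff_genes)
  start1 <- GenomicRanges::start(gff)[ord]  # 1-based inclusive
  end1 <- GenomicRanges::end(gff)[ord]
  tx_len <- Biostrings::width(seqs)

  records <- data.frame(
    gene_id = names(seqs),
    tx_length = tx_len,
    buffer_left = start1 - 1L,
    buffer_right = tx_len - end1,
    start_codon_pos = start1 - 1L,
    stop_codon_pos = NA_integer_,
    orf_length = end1 - start1 + 1L,
    stringsAsFactors = FALSE
  )
  records$stop_codon_pos <- records$start_codon_pos + records$orf_length - 3L

  bad_frame <- records$orf_length %% 3L != 0L
  bad_bounds <- records$buffer_left < 0L | records$buffer_right < 0L |
    records$orf_length < 6L
  excluded <- data.frame(
    gene_id = records$gene_id[bad_frame | bad_bounds],
    reason = ifelse(bad_frame[bad_frame | bad_bounds],
                    "CDS length not divisible by 3", "CDS outside sequence or too short"),
    stringsAsFactors = FALSE
  )
  if (nrow(excluded) > 0L)
    warning("excluded ", nrow(excluded), " gene(s): ",
            paste(excluded$gene_id, excluded$reason, sep = ": ", collapse = "; "))

  keep <- !(bad_frame | bad_bounds)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  seqs <- seqs[records$gene_id]

  warns <- character()
  if (nrow(records) > 0L) {
    starts <- as.character(Biostrings::subseq(
      seqs, records$start_codon_pos + 1L, records$start_codon_pos + 3L))
    non_atg <- starts != "ATG"
    if (any(non_atg)) {
      warns <- paste0("non-ATG start codon in ", records$gene_id[non_atg],
                      " (", starts[non_atg], ")")
      warning(length(warns), " gene(s) with non-ATG start codon")
    }
  }

  structure(
    list(records = records, sequences = seqs, excluded = excluded,
         warnings = warns,
         source = list(fasta = fasta_path, gff = gff_path)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$records), "genes")
  if (nrow(x$excluded)) cat(" (", nrow(x$excluded), " excluded)", sep = "")
  cat("\n")
  if (nrow(x$records)) {
    cat("  ORF length: ", min(x$records$orf_length), "-",
        max(x$records$orf_length), " nt; buffers ",
        x$records$buffer_left[1], "/", x$records$buffer_right[1], " nt\n", sep = "")
  }
  invisible(x)
}

#' Write an annotation set as FASTA + GFF3
#'
#' Inverse of [load_transcriptome()]: GFF coordinates are emitted 1-based
#' inclusive with one CDS feature per gene.
#'
#' @param annotation an `annotation_set`.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, a list with the two paths.
#' @export
write_transcriptome <- function(annotation, fasta_path, gff_path) {
  stopifnot(inherits(annotation, "annotation_set"))
  rec <- annotation$records
  Biostrings::writeXStringSet(annotation$sequences, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = rec$gene_id,
    ranges = IRanges::IRanges(start = rec$buffer_left + 1L,
                              end = rec$buffer_left + rec$orf_length),
    strand = "+",
    type = "CDS",
    source = "ribopipe",
    phase = 0L,
    ID = paste0("cds_", rec$gene_id)
  )
  GenomeInfoDb::seqlengths(gr) <- setNames(rec$tx_length, rec$gene_id)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Sequence-derived gene features
#'
#' Computes, per gene, the sequence features correlated with expression:
#' ORF length, 5' UTR (buffer) length, GC content of the 5' and 3' buffers,
#' and the number of upstream ATGs (overlapping occurrences, any frame,
#' within the 5' buffer). Externally measured features (mRNA folding energy,
#' poly(A) tail length) are initialised as missing and merged later with
#' [join_external_features()].
#'
#' @param annotation an `annotation_set`.
#' @return A `feature_table` data.frame with one row per gene and columns
#'   gene_id, orf_length, utr5_length, utr5_gc, utr3_gc, n_upstream_atg,
#'   folding_energy, polya_length. GC of an empty buffer is `NA`.
#' @export
compute_sequence_features <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  rec <- annotation$records
  seqs <- annotation$sequences

  gc_frac <- function(set, widths) {
    gc <- Biostrings::letterFrequency(set, letters = "GC")[, 1]
    ifelse(widths > 0L, gc / widths, NA_real_)
  }
  # subseq() with width 0 is legal and yields empty strings
  utr5 <- Biostrings::subseq(seqs, start = 1L, width = rec$buffer_left)
  utr3 <- Biostrings::subseq(seqs, start = rec$tx_length - rec$buffer_right + 1L,
                             width = rec$buffer_right)

  out <- data.frame(
    gene_id = rec$gene_id,
    orf_length = rec$orf_length,
    utr5_length = rec$buffer_left,
    utr5_gc = gc_frac(utr5, rec$buffer_left),
    utr3_gc = gc_frac(utr3, rec$buffer_right),
    n_upstream_atg = Biostrings::vcountPattern("ATG", utr5),
    folding_energy = NA_real_,
    polya_length = NA_real_,
    stringsAsFactors = FALSE
  )
  out$n_upstream_atg[rec$buffer_left == 0L] <- 0L
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Merge externally measured features into a feature table
#'
#' Folding energies and poly(A) tail lengths are measured outside this
#' package and supplied as a tab-delimited table with a `gene_id` column
#' and any of the columns `folding_energy`, `polya_length` (`NA` for
#' missing). Values are merged by gene id; genes absent from the TSV keep
#' missing values, extra TSV genes are ignored; both are reported.
#'
#' @param features a `feature_table` from [compute_sequence_features()].
#' @param tsv_path path to the external feature TSV.
#' @return The updated `feature_table`, with attributes `n_unmatched`
#'   (annotation genes absent from the TSV) and `n_extra` (TSV genes not in
#'   the annotation).
#' @export
join_external_features <- function(features, tsv_path) {
  stopifnot(inherits(features, "feature_table"))
  ext <- data.table::fread(tsv_path, sep = "\t", na.strings = c("NA", ""),
                           data.table = FALSE)
  if (!"gene_id" %in% names(ext)) stop("external feature TSV lacks a gene_id column")
  if (anyDuplicated(ext$gene_id))
    stop("duplicate gene_id rows in external feature TSV: ",
         paste(unique(ext$gene_id[duplicated(ext$gene_id)]), collapse = ", "))

  idx <- match(features$gene_id, ext$gene_id)
  for (col in intersect(c("folding_energy", "polya_length"), names(ext))) {
    hit <- !is.na(idx)
    features[[col]][hit] <- as.numeric(ext[[col]][idx[hit]])
  }
  n_unmatched <- sum(is.na(idx))
  n_extra <- length(setdiff(ext$gene_id, features$gene_id))
  if (n_unmatched > 0L)
    warning(n_unmatched, " gene(s) missing from external feature TSV")
  if (n_extra > 0L)
    message(n_extra, " TSV gene(s) not in annotation; ignored")
  attr(features, "n_unmatched") <- n_unmatched
  attr(features, "n_extra") <- n_extra
  features
}
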