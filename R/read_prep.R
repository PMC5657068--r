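# Read preparation: adapter trimming, length window, rRNA contaminant
# filtering, and transcript alignment (built-in exact aligner or SAM/BAM
# ingestion from an external aligner).
#
# Reads travel through the pipeline as a data.table with columns
# read_id / bases / quals (Phred+33); alignments as a data.table with
# read_id / gene_id / pos_5p (0-based transcript coordinate of the 5' end)
# / read_length.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return data.table with columns `read_id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L)
    return(data.table::data.table(read_id = character(), bases = character(),
                                  quals = character()))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    read_id = sub("\\s.*$", "", names(x)),
    bases = as.character(x),
    quals = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write a read table as FASTQ
#'
#' @param reads data.table with `read_id`, `bases`, `quals`.
#' @param path output path (gzip if it ends in `.gz`).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quals),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Trim 3' sequencing adapters
#'
#' Removes the adapter and everything 3' of it from each read. Scanning is
#' leftmost-first: the first (5'-most) position at which the remainder of
#' the read matches a prefix of the adapter wins. At a candidate position
#' the overlap is `min(nchar(adapter), bases remaining)`; it qualifies when
#' the overlap is at least `min_overlap` and the mismatch fraction over the
#' overlap is at most `max_mismatch_rate`. A full internal adapter
#' occurrence therefore removes the occurrence and everything downstream;
#' a terminal partial occurrence removes the matching suffix.
#'
#' @param reads read table (see [read_fastq()]).
#' @param adapter adapter sequence (3' adapter, e.g. `"CTGTAGGCACC"`).
#' @param min_overlap minimum suffix/prefix overlap to trim (>= 1).
#' @param max_mismatch_rate maximum mismatches per overlap base; 0 for
#'   exact matching (the default).
#' @return The read table with trimmed `bases`/`quals` and a logical column
#'   `adapter_trimmed`. Reads may come back with zero length; the caller
#'   filters them (see [filter_length()]).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, max_mismatch_rate = 0) {
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 1L,
            max_mismatch_rate >= 0, max_mismatch_rate < 1)
  out <- data.table::as.data.table(reads)
  n <- nrow(out)
  if (n == 0L) {
    out[, `:=`(adapter_trimmed = logical(0))]
    return(out[])
  }
  len <- nchar(out$bases)
  max_len <- max(len)
  a_chars <- strsplit(adapter, "", fixed = TRUE)[[1]]
  a_len <- length(a_chars)

  # read base matrix, NA beyond each read's length
  m <- matrix(NA_character_, nrow = n, ncol = max_len)
  for (j in seq_len(max_len)) {
    cj <- substring(out$bases, j, j)
    cj[cj == ""] <- NA_character_
    m[, j] <- cj
  }

  trim_at <- rep(NA_integer_, n)
  for (i in seq_len(max_len)) {
    overlap <- pmin(a_len, len - i + 1L)
    cand <- is.na(trim_at) & overlap >= min_overlap
    if (!any(cand)) next
    jmax <- min(max_len, i + a_len - 1L)
    w <- jmax - i + 1L
    neq <- m[, i:jmax, drop = FALSE] !=
      matrix(a_chars[seq_len(w)], nrow = n, ncol = w, byrow = TRUE)
    neq[is.na(neq)] <- FALSE  # beyond read end: outside the overlap
    mm <- rowSums(neq)
    ok <- cand & mm <= max_mismatch_rate * overlap
    trim_at[ok] <- i
  }

  trimmed <- !is.na(trim_at)
  out[trimmed, `:=`(bases = substr(bases, 1L, trim_at[trimmed] - 1L),
                    quals = substr(quals, 1L, trim_at[trimmed] - 1L))]
  out[, `:=`(adapter_trimmed = trimmed)]
  out[]
}

#' Keep reads within a length window
#'
#' Footprints are ~28-32 nt; the window removes untrimmed or degenerate
#' reads. Counts are conserved: `nrow(kept) + discarded_count == nrow(reads)`.
#'
#' @param reads read table.
#' @param lmin,lmax inclusive length bounds in nt.
#' @return list with `kept` (read table) and `discarded_count`.
#' @export
filter_length <- function(reads, lmin, lmax) {
  stopifnot(lmin <= lmax, lmin >= 1L)
  len <- nchar(reads$bases)
  keep <- len >= lmin & len <= lmax
  list(kept = data.table::as.data.table(reads)[keep],
       discarded_count = sum(!keep))
}

#' Remove rRNA contaminant reads by exact k-mer membership
#'
#' A read is removed iff it shares at least one exact k-mer with any
#' contaminant sequence (sense strand only: riboseq libraries are
#' strand-specific against a transcriptome reference). The contaminant
#' k-mer index is built once.
#'
#' @param reads read table.
#' @param contaminant_seqs contaminant sequences: a
#'   [Biostrings::DNAStringSet], character vector, or path to a FASTA file.
#' @param k k-mer size; must not exceed the shortest read length considered.
#' @return list with `kept`, `removed` (read tables) and `removed_count`.
#' @export
filter_rrna <- function(reads, contaminant_seqs, k = 15L) {
  stopifnot(k >= 1L)
  if (is.character(contaminant_seqs) && length(contaminant_seqs) == 1L &&
      file.exists(contaminant_seqs))
    contaminant_seqs <- Biostrings::readDNAStringSet(contaminant_seqs)
  cont <- as.character(contaminant_seqs)
  cont <- cont[nchar(cont) >= k]
  reads <- data.table::as.data.table(reads)
  if (length(cont) == 0L) {
    warning("empty contaminant set; no reads removed")
    return(list(kept = reads, removed = reads[0L], removed_count = 0L))
  }
  kmer_index <- unique(unlist(lapply(cont, function(s) {
    nk <- nchar(s) - k + 1L
    substring(s, seq_len(nk), seq_len(nk) + k - 1L)
  }), use.names = FALSE))

  len <- nchar(reads$bases)
  nk <- pmax(len - k + 1L, 0L)
  idx <- rep(seq_len(nrow(reads)), nk)
  starts <- sequence(nk)
  hits <- data.table::`%chin%`(
    substring(reads$bases[idx], starts, starts + k - 1L), kmer_index)
  removed <- logical(nrow(reads))
  removed[unique(idx[hits])] <- TRUE
  list(kept = reads[!removed], removed = reads[removed],
       removed_count = sum(removed))
}

#' Pipeline stage counts
#'
#' Constructor for the per-run summary statistics. The length-window,
#' rRNA, alignment and acceptance counts partition the input:
#' `n_input == n_too_short + n_rrna_removed + n_unaligned + n_multimapped +
#' n_accepted` (`n_too_short` counts every length-window discard, long
#' reads included; `n_adapter_trimmed` is informational and outside the
#' partition). The partition is validated at construction.
#'
#' @param n_input,n_adapter_trimmed,n_too_short,n_rrna_removed,n_unaligned,n_multimapped,n_accepted counts.
#' @return object of class `prep_stats`.
#' @export
prep_stats <- function(n_input = 0L, n_adapter_trimmed = 0L, n_too_short = 0L,
                       n_rrna_removed = 0L, n_unaligned = 0L,
                       n_multimapped = 0L, n_accepted = 0L) {
  s <- list(n_input = as.integer(n_input),
            n_adapter_trimmed = as.integer(n_adapter_trimmed),
            n_too_short = as.integer(n_too_short),
            n_rrna_removed = as.integer(n_rrna_removed),
            n_unaligned = as.integer(n_unaligned),
            n_multimapped = as.integer(n_multimapped),
            n_accepted = as.integer(n_accepted))
  if (s$n_input != s$n_too_short + s$n_rrna_removed + s$n_unaligned +
      s$n_multimapped + s$n_accepted)
    stop("prep_stats partition violated: n_input != sum of outcome counts")
  structure(s, class = "prep_stats")
}

#' @export
print.prep_stats <- function(x, ...) {
  cat("prep_stats:\n")
  for (f in names(x)) cat(sprintf("  %-18s %d\n", f, x[[f]]))
  invisible(x)
}

#' Align reads to transcripts by exact substring search
#'
#' Each read is searched as an exact substring of every transcript (sense
#' strand only). Reads with exactly one occurrence across the whole
#' transcriptome yield one alignment; reads with none are unaligned; reads
#' with two or more (any transcript, any position) are discarded as
#' multimapped. This is the built-in stand-in for an external aligner;
#' alignments produced by bowtie/hisat2 can be ingested instead with
#' [read_alignments_sam()].
#'
#' @param reads read table (adapter-trimmed).
#' @param annotation an `annotation_set`.
#' @return list with `alignments` (data.table read_id/gene_id/pos_5p/
#'   read_length) and `stats` (a [prep_stats()] covering only the alignment
#'   outcomes).
#' @export
align_exact <- function(reads, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  reads <- data.table::as.data.table(reads)
  n <- nrow(reads)
  empty <- data.table::data.table(read_id = character(), gene_id = character(),
                                  pos_5p = integer(), read_length = integer())
  if (n == 0L)
    return(list(alignments = empty, stats = prep_stats()))

  rec <- annotation$records
  seq_strings <- as.character(annotation$sequences)
  spacer <- strrep("N", 8L)
  subject <- Biostrings::DNAString(paste(seq_strings, collapse = spacer))
  # 1-based start of each gene inside the concatenated subject
  gene_start1 <- cumsum(c(1L, utils::head(rec$tx_length + 8L, -1L)))

  len <- nchar(reads$bases)
  clean <- len >= 1L & !grepl("[^ACGT]", reads$bases)
  status <- integer(n)      # occurrence count; NA-free, 0 = unaligned
  hit_gene <- rep(NA_character_, n)
  hit_pos <- rep(NA_integer_, n)

  for (L in sort(unique(len[clean]))) {
    sel <- which(clean & len == L)
    upat <- unique(reads$bases[sel])
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(upat))
    m <- Biostrings::matchPDict(pd, subject)
    cnt <- S4Vectors::elementNROWS(m)
    first_start <- rep(NA_integer_, length(upat))
    single <- cnt == 1L
    if (any(single))
      first_start[single] <- unlist(IRanges::start(m)[single], use.names = FALSE)
    ui <- match(reads$bases[sel], upat)
    status[sel] <- cnt[ui]
    st1 <- first_start[ui]
    ok <- !is.na(st1)
    gi <- findInterval(st1[ok], gene_start1)
    hit_gene[sel[ok]] <- rec$gene_id[gi]
    hit_pos[sel[ok]] <- st1[ok] - gene_start1[gi]
  }

  accepted <- status == 1L
  alignments <- data.table::data.table(
    read_id = reads$read_id[accepted],
    gene_id = hit_gene[accepted],
    pos_5p = hit_pos[accepted],
    read_length = len[accepted]
  )
  stats <- prep_stats(
    n_input = n,
    n_unaligned = sum(status == 0L),
    n_multimapped = sum(status >= 2L),
    n_accepted = sum(accepted)
  )
  list(alignments = alignments, stats = stats)
}

#' Ingest transcriptome alignments from SAM/BAM
#'
#' Reads alignments produced by an external aligner against the same
#' ORF-centric reference (`@SQ` names must be gene ids of the annotation).
#' Secondary and supplementary records are dropped before counting input.
#' Kept records are primary, mapped, forward-strand, and unclipped with a
#' pure-match CIGAR (`nM`): `pos_5p` must mean the sequenced 5' terminus,
#' so any soft/hard clip (or indel) disqualifies a record rather than being
#' un-clipped. Excluded mapped records are tallied as unaligned; the length
#' window is applied afterwards.
#'
#' @param path SAM (text) or BAM file; reference names must be annotation
#'   gene ids.
#' @param annotation an `annotation_set`.
#' @param lmin,lmax inclusive read-length window in nt.
#' @return list with `alignments` and `stats` as in [align_exact()].
#' @export
read_alignments_sam <- function(path, annotation, lmin = 15L, lmax = 50L) {
  stopifnot(inherits(annotation, "annotation_set"), lmin <= lmax)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]

  primary <- bitwAnd(b$flag, 0x900L) == 0L
  qname <- b$qname[primary]
  flag <- b$flag[primary]
  rname <- as.character(b$rname[primary])
  pos <- b$pos[primary]
  cigar <- b$cigar[primary]
  strand <- as.character(b$strand[primary])
  qlen <- Biostrings::width(b$seq)[primary]

  n_input <- length(qname)
  mapped <- bitwAnd(flag, 0x4L) == 0L

  unknown <- setdiff(unique(rname[mapped]), annotation$records$gene_id)
  if (length(unknown))
    stop("SAM reference name(s) absent from annotation: ",
         paste(unknown, collapse = ", "))

  usable <- mapped & strand == "+" & grepl("^[0-9]+M$", cigar)
  in_window <- qlen >= lmin & qlen <= lmax
  accepted <- usable & in_window

  rec <- annotation$records
  if (any(accepted)) {
    tx_len <- rec$tx_length[match(rname[accepted], rec$gene_id)]
    if (any(pos[accepted] - 1L + qlen[accepted] > tx_len))
      stop("alignment extends past transcript end; annotation mismatch?")
  }

  alignments <- data.table::data.table(
    read_id = qname[accepted],
    gene_id = rname[accepted],
    pos_5p = pos[accepted] - 1L,
    read_length = qlen[accepted]
  )
  stats <- prep_stats(
    n_input = n_input,
    n_too_short = sum(usable & !in_window),
    n_unaligned = sum(!usable),
    n_accepted = sum(accepted)
  )
  list(alignments = alignments, stats = stats)
}

#' Write / read an alignment table as TSV
#'
#' Tab-delimited with header `read_id  gene_id  pos_5p  read_length`;
#' `pos_5p` is the 0-based transcript coordinate of the read's 5' end.
#'
#' @param alignments alignment data.table.
#' @param path output path.
#' @return invisibly `path` (writer); the alignment data.table (reader).
#' @export
write_alignments_tsv <- function(alignments, path) {
  data.table::fwrite(alignments, path, sep = "\t")
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("read_id", "gene_id"),
                                      integer = c("pos_5p", "read_length")))
}
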