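# Per-gene read-length x 5'-position count matrices and their HDF5
# persistence -- the central data structure everything downstream queries.
#
# A gene's matrix has (lmax - lmin + 1) rows (read length, rownames are the
# lengths) and tx_length columns (column j holds counts of 5' ends at
# 0-based position j - 1). Counts are keyed by the 5' end, not the A-site:
# A-site shifting is a downstream view (see assign_asites()), so a single
# store serves any offset table.
#
# HDF5 schema (versioned, this package's own contract):
#   /<dataset_id>/<gene_id>/reads/data   integer matrix, gzip-chunked
#   gene group attrs: lengths (lmin..lmax), buffer_left, buffer_right,
#                     start_codon_pos, stop_codon_pos, reads_total
#   root attrs: schema_version, dataset_id, provenance (JSON text)

H5_SCHEMA_VERSION <- "1.0"

#' Build per-gene count matrices from alignments
#'
#' Tallies each accepted alignment into its gene's (read length, 5'-end
#' position) cell. Alignments outside the length window are excluded and
#' counted. The tally is order-independent.
#'
#' @param alignments alignment data.table (read_id/gene_id/pos_5p/
#'   read_length).
#' @param annotation an `annotation_set`.
#' @param lmin,lmax inclusive read-length window defining the matrix rows.
#' @param dataset_id name of the dataset (HDF5 top group).
#' @return object of class `dataset_store`: list with `dataset_id`, `lmin`,
#'   `lmax`, `matrices` (named list of integer matrices), `fingerprint`
#'   (per-gene coordinate frame), and `provenance`.
#' @export
build_count_matrices <- function(alignments, annotation, lmin = 15L, lmax = 50L,
                                 dataset_id = "dataset") {
  stopifnot(inherits(annotation, "annotation_set"), lmin <= lmax)
  al <- data.table::as.data.table(alignments)
  rec <- annotation$records

  unknown <- setdiff(unique(al$gene_id), rec$gene_id)
  if (length(unknown))
    stop("alignment(s) to gene(s) absent from annotation: ",
         paste(unknown, collapse = ", "))

  in_window <- al$read_length >= lmin & al$read_length <= lmax
  n_out <- sum(!in_window)
  al <- al[in_window]
  if (nrow(al) > 0L) {
    bad <- al$pos_5p < 0L |
      al$pos_5p + al$read_length > rec$tx_length[match(al$gene_id, rec$gene_id)]
    if (any(bad)) stop(sum(bad), " alignment(s) out of transcript bounds")
  }

  n_len <- lmax - lmin + 1L
  matrices <- lapply(seq_len(nrow(rec)), function(i) {
    m <- matrix(0L, nrow = n_len, ncol = rec$tx_length[i],
                dimnames = list(as.character(lmin:lmax), NULL))
    m
  })
  names(matrices) <- rec$gene_id

  if (nrow(al) > 0L) {
    tal <- al[, .N, by = .(gene_id, read_length, pos_5p)]
    for (g in unique(tal$gene_id)) {
      tg <- tal[gene_id == g]
      idx <- cbind(tg$read_length - lmin + 1L, tg$pos_5p + 1L)
      matrices[[g]][idx] <- matrices[[g]][idx] + tg$N
    }
  }

  structure(
    list(dataset_id = dataset_id, lmin = as.integer(lmin),
         lmax = as.integer(lmax), matrices = matrices,
         fingerprint = rec[, c("gene_id", "tx_length", "buffer_left",
                               "buffer_right", "start_codon_pos",
                               "stop_codon_pos", "orf_length")],
         provenance = list(
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           n_alignments_in = nrow(alignments),
           n_out_of_window = n_out,
           n_counted = nrow(al),
           package_version = as.character(utils::packageVersion("ribopipe"))
         )),
    class = "dataset_store"
  )
}

#' @export
print.dataset_store <- function(x, ...) {
  cat("dataset_store '", x$dataset_id, "': ", length(x$matrices),
      " genes, lengths ", x$lmin, "-", x$lmax, ", ",
      sum(reads_per_gene(x)), " reads\n", sep = "")
  invisible(x)
}

#' Total counted reads per gene
#'
#' @param store a `dataset_store`.
#' @return named integer vector of matrix sums, one per gene.
#' @export
reads_per_gene <- function(store) {
  vapply(store$matrices, sum, numeric(1))
}

#' Persist a dataset store as HDF5
#'
#' Writes the per-gene matrices and coordinate-frame attributes under
#' `/<dataset_id>/<gene_id>/reads/data`, gzip-chunked by whole gene, plus
#' root attributes `schema_version`, `dataset_id` and a JSON `provenance`
#' snapshot.
#'
#' @param store a `dataset_store`.
#' @param path output `.h5` path (overwritten).
#' @return invisibly, `path`.
#' @export
write_counts_h5 <- function(store, path) {
  stopifnot(inherits(store, "dataset_store"))
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create HDF5 file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(H5_SCHEMA_VERSION, fid, "schema_version")
  rhdf5::h5writeAttribute(store$dataset_id, fid, "dataset_id")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(store$provenance, auto_unbox = TRUE)),
    fid, "provenance")
  rhdf5::H5Fclose(fid)

  rhdf5::h5createGroup(path, store$dataset_id)
  fp <- store$fingerprint
  for (i in seq_len(nrow(fp))) {
    g <- fp$gene_id[i]
    grp <- paste0(store$dataset_id, "/", g)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5createGroup(path, paste0(grp, "/reads"))
    m <- store$matrices[[g]]
    dset <- paste0(grp, "/reads/data")
    rhdf5::h5createDataset(path, dset, dims = dim(m), storage.mode = "integer",
                           chunk = dim(m), level = 6L)
    rhdf5::h5write(m, path, dset)
    gid <- rhdf5::H5Gopen(rhdf5::H5Fopen(path), grp)
    rhdf5::h5writeAttribute(store$lmin:store$lmax, gid, "lengths")
    rhdf5::h5writeAttribute(fp$buffer_left[i], gid, "buffer_left")
    rhdf5::h5writeAttribute(fp$buffer_right[i], gid, "buffer_right")
    rhdf5::h5writeAttribute(fp$start_codon_pos[i], gid, "start_codon_pos")
    rhdf5::h5writeAttribute(fp$stop_codon_pos[i], gid, "stop_codon_pos")
    rhdf5::h5writeAttribute(as.integer(sum(m)), gid, "reads_total")
    rhdf5::H5Gclose(gid)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Load a dataset store from HDF5
#'
#' @param path file written by [write_counts_h5()].
#' @param genes optional character vector restricting loading to a gene
#'   subset; an absent gene is an error naming it.
#' @return a `dataset_store`.
#' @export
read_counts_h5 <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("HDF5 file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  root_attrs <- tryCatch(rhdf5::h5readAttributes(path, "/"),
                         error = function(e) stop("unreadable HDF5 file: ",
                                                  path, " (", conditionMessage(e), ")"))
  ver <- root_attrs$schema_version
  if (is.null(ver)) stop("not a ribopipe count store (no schema_version): ", path)
  ver <- as.character(ver)  # rhdf5 returns attributes as 1-d arrays
  if (sub("\\..*$", "", ver) != sub("\\..*$", "", H5_SCHEMA_VERSION))
    stop("unsupported schema_version '", ver, "' (reader supports major ",
         sub("\\..*$", "", H5_SCHEMA_VERSION), ")")
  dataset_id <- as.character(root_attrs$dataset_id)
  provenance <- tryCatch(jsonlite::fromJSON(as.character(root_attrs$provenance)),
                         error = function(e) list())

  ls_top <- rhdf5::h5ls(path, recursive = FALSE)
  if (!dataset_id %in% ls_top$name) stop("dataset group missing: ", dataset_id)
  ls_all <- rhdf5::h5ls(path)
  gene_names <- sort(ls_all$name[ls_all$group == paste0("/", dataset_id)])
  if (is.null(genes)) {
    genes <- gene_names
  } else {
    missing <- setdiff(genes, gene_names)
    if (length(missing))
      stop("gene(s) not in store: ", paste(missing, collapse = ", "))
  }

  lmin <- NA_integer_; lmax <- NA_integer_
  matrices <- vector("list", length(genes))
  names(matrices) <- genes
  fp <- data.frame(gene_id = genes, tx_length = NA_integer_,
                   buffer_left = NA_integer_, buffer_right = NA_integer_,
                   start_codon_pos = NA_integer_, stop_codon_pos = NA_integer_,
                   orf_length = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    grp <- paste0(dataset_id, "/", genes[i])
    m <- rhdf5::h5read(path, paste0(grp, "/reads/data"))
    at <- rhdf5::h5readAttributes(path, grp)
    lens <- as.integer(at$lengths)
    lmin <- lens[1]; lmax <- lens[length(lens)]
    storage.mode(m) <- "integer"
    rownames(m) <- as.character(lens)
    matrices[[i]] <- m
    fp$tx_length[i] <- ncol(m)
    fp$buffer_left[i] <- as.integer(at$buffer_left)
    fp$buffer_right[i] <- as.integer(at$buffer_right)
    fp$start_codon_pos[i] <- as.integer(at$start_codon_pos)
    fp$stop_codon_pos[i] <- as.integer(at$stop_codon_pos)
    if (sum(m) != as.integer(at$reads_total))
      stop("reads_total attribute mismatch for gene ", genes[i])
  }
  fp$orf_length <- fp$stop_codon_pos - fp$start_codon_pos + 3L

  structure(
    list(dataset_id = dataset_id, lmin = lmin, lmax = lmax,
         matrices = matrices, fingerprint = fp, provenance = provenance),
    class = "dataset_store"
  )
}

#' Export per-gene count matrices as flat TSV files
#'
#' Writes one `<gene_id>.tsv` per gene (column `position` = 0-based 5'-end
#' coordinate, then one `len_<L>` column per read length) plus a
#' `summary.tsv` with per-gene totals and the coordinate frame. The TSVs
#' re-import to identical matrices with [read_gene_counts_tsv()].
#'
#' @param store a `dataset_store`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, character vector of files written.
#' @export
export_gene_tsv <- function(store, out_dir) {
  stopifnot(inherits(store, "dataset_store"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in names(store$matrices)) {
    m <- store$matrices[[g]]
    df <- data.table::as.data.table(t(m))
    data.table::setnames(df, paste0("len_", rownames(m)))
    df[, position := .I - 1L]
    data.table::setcolorder(df, "position")
    f <- file.path(out_dir, paste0(g, ".tsv"))
    data.table::fwrite(df, f, sep = "\t")
    files <- c(files, f)
  }
  fp <- data.table::as.data.table(store$fingerprint)
  fp[, reads_total := as.integer(reads_per_gene(store)[gene_id])]
  sf <- file.path(out_dir, "summary.tsv")
  data.table::fwrite(fp, sf, sep = "\t")
  invisible(c(files, sf))
}

#' Re-import a per-gene count TSV written by [export_gene_tsv()]
#'
#' @param path a `<gene_id>.tsv` file.
#' @return integer matrix with read-length rownames, identical to the
#'   exported matrix.
#' @export
read_gene_counts_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  stopifnot(identical(names(df)[1], "position"))
  lens <- sub("^len_", "", names(df)[-1])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(lens, NULL)
  m
}
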