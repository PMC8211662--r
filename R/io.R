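#' Read a 10x-style count matrix triple
#'
#' Reads a MatrixMarket coordinate matrix plus the accompanying features and
#' barcodes TSV files (the 10x Genomics on-disk convention: genes as rows,
#' cells as columns) and, optionally, a per-cell metadata sidecar TSV keyed
#' by barcode with columns `barcode`, `embryo_id`, `stage_dpf`, `source`.
#' Datasets deposited with a different layout can be adapted by preparing
#' this triple; the reader itself is deliberately minimal.
#'
#' @param matrix_path path to the `.mtx` file (coordinate, integer).
#' @param features_path path to the features/genes TSV (first column = symbol).
#' @param barcodes_path path to the barcodes TSV (one barcode per line).
#' @param meta_path optional path to the metadata TSV; when absent all cells
#'   carry an unknown stage so that, e.g., cell-line data can flow through
#'   the projection module.
#' @return A [gene_matrix].
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        meta_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  bars <- utils::read.delim(barcodes_path, header = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop("features TSV has ", nrow(feats), " rows but matrix declares ",
         nrow(m), " genes")
  if (nrow(bars) != ncol(m))
    stop("barcodes TSV has ", nrow(bars), " rows but matrix declares ",
         ncol(m), " cells")
  if (length(m@x) && any(m@x < 0)) stop("matrix contains negative entries")
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, header = TRUE,
                              stringsAsFactors = FALSE)
    if (!"barcode" %in% names(meta)) stop("metadata TSV needs a 'barcode' column")
  }
  gene_matrix(m, feats[[1]], bars[[1]], meta)
}

#' Write a gene_matrix as a 10x-style triple
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), `features.tsv`,
#' `barcodes.tsv` and `meta.tsv` under `dir_path`. Lossless for integer
#' counts: [read_counts] on the result reproduces the input exactly.
#'
#' @param m a [gene_matrix].
#' @param dir_path output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_counts <- function(m, dir_path) {
  stopifnot(inherits(m, "gene_matrix"))
  if (!dir.exists(dir_path))
    if (!dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", dir_path)
  paths <- c(matrix = file.path(dir_path, "matrix.mtx"),
             features = file.path(dir_path, "features.tsv"),
             barcodes = file.path(dir_path, "barcodes.tsv"),
             meta = file.path(dir_path, "meta.tsv"))
  tm <- methods::as(m$counts, "TsparseMatrix")
  # Matrix::writeMM declares a "real" field for numeric matrices; counts are
  # integers by contract so write the integer-field header ourselves.
  con <- file(paths[["matrix"]], "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    writeLines(paste(tm@i + 1L, tm@j + 1L, format(tm@x, scientific = FALSE,
                                                  trim = TRUE)), con)
  utils::write.table(data.frame(m$gene_ids, m$gene_ids,
                                rep("Gene Expression", length(m$gene_ids))),
                     paths[["features"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(m$cell_ids, paths[["barcodes"]])
  utils::write.table(m$cell_meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read gene sets (regulons) from a GMT file
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are removed; duplicate set names across
#' lines are an error (a transcription factor has one regulon).
#'
#' @param path path to the GMT file.
#' @return A `regulon_set`: a named list of character vectors of target genes,
#'   names are transcription-factor names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    list(name = f[[1]], targets = unique(f[-(1:2)]))
  })
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate regulon name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(entries, `[[`, "targets")
  if (any(lengths(sets) == 0)) stop("regulon with empty target set")
  names(sets) <- nms
  structure(sets, class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat("regulon_set with", length(x), "regulons;",
      "median targets:", stats::median(lengths(x)), "\n")
  invisible(x)
}
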