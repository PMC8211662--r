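#' Gene-by-cell count matrix with per-cell metadata
#'
#' `gene_matrix()` builds the central container used throughout the package:
#' a genes x cells matrix of non-negative integer counts, unique gene and
#' cell identifiers, a per-cell metadata table (embryo of origin, embryonic
#' stage in days post-fertilisation, data source) and a logical mask marking
#' mitochondrial genes.
#'
#' Mitochondrial genes are recognised by the `"MT-"` symbol prefix, the
#' convention of GRCh38 gene annotations.
#'
#' @param counts genes x cells matrix (base matrix or `Matrix` sparse matrix)
#'   of non-negative integer counts.
#' @param gene_ids character vector of unique gene symbols, length `nrow(counts)`.
#' @param cell_ids character vector of unique cell barcodes, length `ncol(counts)`.
#' @param cell_meta optional data.frame with one row per cell and columns
#'   `embryo_id`, `stage_dpf`, `source`. If `NULL`, all cells get
#'   `embryo_id = NA`, unknown stage (`NA`) and `source = "unknown"`.
#' @return An object of class `gene_matrix`: a list with elements `counts`
#'   (a `dgCMatrix` with dimnames), `gene_ids`, `cell_ids`, `cell_meta` and
#'   `mito_mask`.
#' @examples
#' m <- gene_matrix(matrix(c(5L, 0L, 0L, 3L), 2, 2),
#'                  gene_ids = c("MT-CO1", "GAPDH"),
#'                  cell_ids = c("AAAC", "AAAG"))
#' m$mito_mask
#' @export
gene_matrix <- function(counts, gene_ids, cell_ids, cell_meta = NULL) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE, doDiag = FALSE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids),
         ") does not match matrix rows (", nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids),
         ") does not match matrix columns (", ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    if (any(x != round(x))) stop("counts must be integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(
      barcode = as.character(cell_ids),
      embryo_id = NA_character_,
      stage_dpf = NA_integer_,
      source = "unknown",
      stringsAsFactors = FALSE
    )
  } else {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    if (!"barcode" %in% names(cell_meta)) cell_meta$barcode <- as.character(cell_ids)
    needed <- c("embryo_id", "stage_dpf", "source")
    for (col in needed) if (!col %in% names(cell_meta))
      cell_meta[[col]] <- if (col == "stage_dpf") NA_integer_ else NA_character_
    idx <- match(cell_ids, cell_meta$barcode)
    if (anyNA(idx)) stop("cell_meta is missing rows for some barcodes")
    cell_meta <- cell_meta[idx, c("barcode", needed), drop = FALSE]
    rownames(cell_meta) <- NULL
    stg <- cell_meta$stage_dpf
    bad <- !is.na(stg) & !stg %in% c(5L, 6L, 7L, 9L, 11L)
    if (any(bad))
      stop("stage_dpf must be one of 5, 6, 7, 9, 11 or NA (unknown)")
    cell_meta$stage_dpf <- as.integer(stg)
  }
  structure(
    list(counts = counts,
         gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         cell_meta = cell_meta,
         mito_mask = startsWith(as.character(gene_ids), "MT-")),
    class = "gene_matrix"
  )
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("gene_matrix: ", length(x$gene_ids), " genes x ", length(x$cell_ids),
      " cells\n", sep = "")
  cat("  total counts: ", sum(x$counts), "; mitochondrial genes: ",
      sum(x$mito_mask), "\n", sep = "")
  stg <- x$cell_meta$stage_dpf
  if (any(!is.na(stg))) {
    tab <- table(stg, useNA = "ifany")
    cat("  stages (d.p.f.):", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.gene_matrix <- function(x) dim(x$counts)

#' Subset a gene_matrix by genes and/or cells
#'
#' @param x a `gene_matrix`.
#' @param genes gene index (logical, integer or character); default all.
#' @param cells cell index (logical, integer or character); default all.
#' @return A `gene_matrix` restricted to the selected genes and cells.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "gene_matrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else cells
  cnt <- x$counts[gi, ci, drop = FALSE]
  meta <- x$cell_meta[match(colnames(cnt), x$cell_meta$barcode), , drop = FALSE]
  gene_matrix(cnt, rownames(cnt), colnames(cnt), meta)
}
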