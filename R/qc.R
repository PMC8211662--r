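#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the mitochondrial fraction (counts on `MT-`
#' genes over total counts) and the number of detectable genes (count >= 1).
#' Cells with zero total counts get a mitochondrial fraction of 0.
#'
#' @param m a [gene_matrix].
#' @return data.frame with columns `barcode`, `mito_fraction`,
#'   `n_detected_genes`.
#' @export
compute_cell_qc <- function(m) {
  stopifnot(inherits(m, "gene_matrix"))
  tot <- Matrix::colSums(m$counts)
  mito <- Matrix::colSums(m$counts[m$mito_mask, , drop = FALSE])
  frac <- ifelse(tot > 0, mito / tot, 0)
  data.frame(barcode = m$cell_ids,
             mito_fraction = as.numeric(frac),
             n_detected_genes = as.integer(Matrix::colSums(m$counts > 0)),
             stringsAsFactors = FALSE)
}

#' Cell quality filter
#'
#' Removes cells whose mitochondrial genes account for more than
#' `mito_max` of total expression, or with fewer than `min_genes`
#' detectable genes. Both readings are strict: a cell exactly at 20%
#' mitochondrial expression or exactly 1000 genes is kept.
#'
#' @param qc data.frame from [compute_cell_qc].
#' @param mito_max maximum allowed mitochondrial fraction (default 0.20).
#' @param min_genes minimum detectable genes (default 1000).
#' @return Logical keep mask, one entry per cell.
#' @export
filter_cells <- function(qc, mito_max = 0.20, min_genes = 1000) {
  stopifnot(mito_max >= 0, mito_max <= 1, min_genes >= 0)
  qc$mito_fraction <= mito_max & qc$n_detected_genes >= min_genes
}

#' Library-size log-normalisation
#'
#' Per cell, `x -> log(1 + scale * x / total)`. All-zero cells are left
#' at zero. This is the standard normalisation underlying z-scored marker
#' heatmaps and signature scoring.
#'
#' @param m a [gene_matrix].
#' @param scale size factor target (default 1e4).
#' @return A genes x cells `dgCMatrix` of normalised expression, with
#'   dimnames.
#' @export
normalize_log <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "gene_matrix"))
  tot <- Matrix::colSums(m$counts)
  sf <- ifelse(tot > 0, scale / tot, 0)
  x <- m$counts %*% Matrix::Diagonal(x = sf)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(m$counts)
  methods::as(x, "CsparseMatrix")
}

#' Signature scores for lineage annotation
#'
#' For each marker set, the score of a cell is the mean over the set's genes
#' of the gene's z-scored normalised expression (z-scoring across cells;
#' zero-variance genes contribute 0). Marker genes missing from the matrix
#' are dropped with a warning; a set losing all genes is an error.
#'
#' @param norm normalised matrix from [normalize_log] (genes x cells,
#'   rownames = gene symbols).
#' @param marker_sets named list of character vectors (default
#'   [lineage_markers()]).
#' @return cells x signatures numeric matrix of scores.
#' @export
score_signatures <- function(norm, marker_sets = lineage_markers()) {
  stopifnot(length(marker_sets) > 0)
  out <- matrix(NA_real_, nrow = ncol(norm), ncol = length(marker_sets),
                dimnames = list(colnames(norm), names(marker_sets)))
  for (nm in names(marker_sets)) {
    genes <- marker_sets[[nm]]
    hit <- intersect(genes, rownames(norm))
    if (length(hit) < length(genes))
      warning("signature ", nm, ": ", length(genes) - length(hit),
              " marker gene(s) absent from matrix")
    if (length(hit) == 0)
      stop("signature ", nm, " has no genes present in the matrix")
    x <- as.matrix(norm[hit, , drop = FALSE])
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    out[, nm] <- colMeans(z)
  }
  out
}

#' Assign lineage labels from signature scores
#'
#' Each cell gets the arg-max signature; when the top two scores differ by
#' less than `min_margin` the cell is `UNASSIGNED`. Exact ties are broken
#' deterministically by the fixed order EPI < HYP < CTB < STB (then by the
#' column order of any additional signatures).
#'
#' @param scores cells x signatures matrix from [score_signatures].
#' @param min_margin minimum lead of the best score over the runner-up
#'   (default 0: always assign).
#' @return Character vector of labels, one per cell.
#' @export
assign_lineages <- function(scores, min_margin = 0) {
  stopifnot(all(is.finite(scores)))
  canonical <- c("EPI", "HYP", "CTB", "STB")
  ord <- c(intersect(canonical, colnames(scores)),
           setdiff(colnames(scores), canonical))
  scores <- scores[, ord, drop = FALSE]
  apply(scores, 1, function(s) {
    top <- which.max(s)  # first max = fixed-order tie-break
    if (ncol(scores) > 1) {
      runner <- max(s[-top])
      if (s[top] - runner < min_margin) return("UNASSIGNED")
    }
    colnames(scores)[top]
  })
}

#' Embryo inclusion by lineage presence
#'
#' An embryo is retained only when all three lineages are present: at least
#' `min_cells_per_lineage` epiblast cells, as many hypoblast cells, and as
#' many trophoblast cells (cytotrophoblast and syncytiotrophoblast pooled).
#'
#' @param labels character lineage labels per cell.
#' @param embryo_ids character embryo id per cell.
#' @param min_cells_per_lineage minimum cells per lineage (default 1).
#' @return Character vector of kept embryo ids.
#' @export
embryo_inclusion <- function(labels, embryo_ids, min_cells_per_lineage = 1) {
  stopifnot(length(labels) == length(embryo_ids))
  keep <- vapply(unique(embryo_ids), function(e) {
    l <- labels[embryo_ids == e]
    sum(l == "EPI") >= min_cells_per_lineage &&
      sum(l == "HYP") >= min_cells_per_lineage &&
      sum(l %in% c("CTB", "STB")) >= min_cells_per_lineage
  }, logical(1))
  unique(embryo_ids)[keep]
}

#' Rank cluster-defining marker genes
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene per lineage on
#' normalised expression, with a log2 fold change of mean de-logged
#' expression (pseudocount 1e-9) and the fraction of expressing cells inside
#' and outside the lineage. P-values are Benjamini-Hochberg adjusted within
#' each lineage; rows are sorted by q, then by decreasing |log2 fold change|.
#'
#' @param norm normalised matrix (genes x cells).
#' @param labels lineage label per cell; lineages with fewer than
#'   `min_cells` cells are skipped with a warning.
#' @param min_cells minimum group size (default 3).
#' @return data.frame with columns `gene`, `lineage`, `log2_fold_change`,
#'   `p_raw`, `q_bh`, `frac_expressing_in`, `frac_expressing_out`.
#' @export
rank_markers <- function(norm, labels, min_cells = 3) {
  stopifnot(ncol(norm) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 lineages")
  # rank a lineage if it has enough cells and a non-empty rest group
  lins <- names(tab)[tab >= min_cells & tab < length(labels)]
  if (length(lins) < length(tab))
    warning("skipping lineage(s) with < ", min_cells, " cells: ",
            paste(setdiff(names(tab), lins), collapse = ", "))
  if (length(lins) == 0) stop("no lineage with at least ", min_cells, " cells")
  dense <- as.matrix(norm)
  res <- lapply(lins, function(lin) {
    inside <- labels == lin
    p <- apply(dense, 1, function(v) {
      if (stats::sd(v) == 0) return(1)
      suppressWarnings(
        stats::wilcox.test(v[inside], v[!inside], exact = NULL)$p.value)
    })
    mean_in <- rowMeans(expm1(dense[, inside, drop = FALSE]))
    mean_out <- rowMeans(expm1(dense[, !inside, drop = FALSE]))
    lfc <- log2((mean_in + 1e-9) / (mean_out + 1e-9))
    d <- data.frame(gene = rownames(dense), lineage = lin,
                    log2_fold_change = lfc,
                    p_raw = ifelse(is.na(p), 1, p),
                    q_bh = NA_real_,
                    frac_expressing_in = rowMeans(dense[, inside, drop = FALSE] > 0),
                    frac_expressing_out = rowMeans(dense[, !inside, drop = FALSE] > 0),
                    stringsAsFactors = FALSE)
    d$q_bh <- bh_adjust(d$p_raw)
    d[order(d$q_bh, -abs(d$log2_fold_change)), ]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
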