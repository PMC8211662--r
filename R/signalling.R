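#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving on the input:
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j`, clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Co-expression of a target gene with an antagonist panel
#'
#' Correlates the normalised expression of a target gene (default `CER1`)
#' with each gene of a panel of secreted WNT/BMP/NODAL antagonists across
#' the cells of one lineage, with Benjamini-Hochberg correction over the
#' panel. Spearman rank correlation is the default (robust for sparse
#' counts); Pearson is available.
#'
#' @param norm normalised genes x cells matrix restricted to one lineage
#'   (e.g. the hypoblast).
#' @param target target gene symbol (default `"CER1"`).
#' @param panel character vector of panel genes (default
#'   [ave_antagonist_panel()]); genes absent from the matrix are dropped
#'   with a warning.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns `gene_a`, `gene_b`, `rho`, `p_raw`,
#'   `q_bh`, `n_cells`. If the target has zero variance all `rho` are `NA`
#'   and the result carries attribute `constant_target = TRUE`.
#' @export
correlate_with_target <- function(norm, target = "CER1",
                                  panel = ave_antagonist_panel(),
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!target %in% rownames(norm)) stop("target gene absent from matrix")
  present <- intersect(panel, rownames(norm))
  if (length(present) == 0) stop("no panel genes present in matrix")
  if (length(present) < length(panel))
    warning("dropping ", length(panel) - length(present),
            " panel gene(s) absent from matrix")
  if (ncol(norm) < 10) stop("need at least 10 cells")
  tv <- as.numeric(norm[target, ])
  out <- data.frame(gene_a = target, gene_b = present,
                    rho = NA_real_, p_raw = NA_real_, q_bh = NA_real_,
                    n_cells = ncol(norm), stringsAsFactors = FALSE)
  if (stats::sd(tv) == 0) {
    attr(out, "constant_target") <- TRUE
    warning("target gene is constant across cells; correlations undefined")
    return(out)
  }
  for (i in seq_along(present)) {
    gv <- as.numeric(norm[present[i], ])
    if (stats::sd(gv) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(tv, gv, method = method, exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p_raw[i] <- ct$p.value
  }
  ok <- !is.na(out$p_raw)
  out$q_bh[ok] <- bh_adjust(out$p_raw[ok])
  out
}

#' Sub-partition the cells of a lineage
#'
#' Principal-component reduction (centred, top `n_pcs`) followed by k-means
#' with 50 random restarts under a fixed seed. The sub-cluster with the
#' highest mean expression of `focus_gene` is reported as the putative
#' anterior sub-cluster. This simple partitioning stands in for graph-based
#' sub-clustering and is not intended to replicate any specific published
#' clustering.
#'
#' @param norm normalised genes x cells matrix restricted to one lineage.
#' @param k number of sub-clusters (default 3).
#' @param n_pcs number of principal components (default 10, capped).
#' @param seed mandatory RNG seed.
#' @param focus_gene gene whose high-expression sub-cluster is flagged
#'   (default `"CER1"`).
#' @param nstart k-means restarts (default 50).
#' @return List with `labels` (integer sub-cluster per cell, 0-based),
#'   `focus_cluster` (0-based label of the focus-gene-high sub-cluster, or
#'   `NA` if the gene is absent), `centers_pca`.
#' @export
partition_cells <- function(norm, k = 3, n_pcs = 10, seed,
                            focus_gene = "CER1", nstart = 50) {
  if (missing(seed)) stop("seed is mandatory")
  n <- ncol(norm)
  if (k > n) stop("k exceeds the number of cells")
  if (n < 5 * k) stop("need at least 5*k cells")
  x <- t(as.matrix(norm))
  keep <- apply(x, 2, stats::sd) > 0
  pcs <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  d <- min(n_pcs, ncol(pcs$x))
  emb <- pcs$x[, seq_len(d), drop = FALSE]
  km <- with_seed(seed, stats::kmeans(emb, centers = k, nstart = nstart,
                                      iter.max = 100))
  labels <- km$cluster - 1L
  focus <- NA_integer_
  if (focus_gene %in% rownames(norm)) {
    mu <- tapply(as.numeric(norm[focus_gene, ]), labels, mean)
    focus <- as.integer(names(mu)[which.max(mu)])
  }
  list(labels = labels, focus_cluster = focus, centers_pca = km$centers)
}

#' Regulon activity scores (rank-based AUC)
#'
#' For every cell, genes are ranked by expression (descending; ties broken
#' lexicographically by gene symbol for reproducibility). A regulon's
#' recovery curve is the cumulative number of its target genes found within
#' the top `x` ranks, for `x = 1 .. ceiling(top_fraction * G)`; its score is
#' the area under this curve normalised by the maximum achievable area, so
#' scores lie in `[0, 1]` and reach 1 only when all targets sit at the very
#' top of the ranking. The score depends on ranks only, hence is invariant
#' to monotone rescaling of expression.
#'
#' @param norm normalised (or raw) genes x cells matrix.
#' @param regulons a `regulon_set` from [read_gmt] (or a named list of
#'   character vectors). Targets absent from the matrix are dropped with a
#'   warning; regulons losing all targets are dropped.
#' @param top_fraction fraction of top-ranked genes forming the scoring
#'   window (default 0.05).
#' @return cells x regulons matrix of AUC scores in `[0, 1]`.
#' @export
regulon_activity <- function(norm, regulons, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  genes <- rownames(norm)
  G <- length(genes)
  win <- ceiling(top_fraction * G)
  sets <- lapply(regulons, function(tg) intersect(tg, genes))
  dropped_genes <- sum(lengths(regulons) - lengths(sets))
  if (dropped_genes > 0)
    warning(dropped_genes, " regulon target(s) absent from matrix; dropped")
  keep <- lengths(sets) > 0
  if (!all(keep))
    warning("dropping regulon(s) with no surviving targets: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0) stop("no regulons left after filtering")
  dense <- as.matrix(norm)
  lex <- order(genes)   # secondary key: gene symbol
  scores <- matrix(0, nrow = ncol(dense), ncol = length(sets),
                   dimnames = list(colnames(dense), names(sets)))
  for (ci in seq_len(ncol(dense))) {
    v <- dense[lex, ci]
    ord <- lex[order(-v)]            # stable: ties resolved by symbol order
    rank_of <- integer(G)
    rank_of[ord] <- seq_len(G)
    for (si in seq_along(sets)) {
      tr <- sort(rank_of[match(sets[[si]], genes)])
      n_t <- length(tr)
      # AUC = sum over x = 1..win of hits(x), where hits(x) counts targets
      # with rank <= x; normalised by the area with all targets at the top
      hits_in <- tr[tr <= win]
      auc <- sum(win - hits_in + 1)
      kmax <- min(n_t, win)
      max_auc <- sum(win - seq_len(kmax) + 1)
      scores[ci, si] <- if (max_auc > 0) auc / max_auc else 0
    }
  }
  scores
}

#' Per-stage median expression of pluripotency panels
#'
#' Summarises panels of naive, primed and core pluripotency markers as the
#' median normalised expression per gene per developmental stage.
#'
#' @param norm normalised genes x cells matrix.
#' @param stage_dpf stage (days post-fertilisation) per cell; `NA` cells are
#'   dropped.
#' @param panels named list of gene panels (default [pluripotency_panels()]).
#' @return Long-format data.frame with columns `panel`, `gene`, `stage_dpf`,
#'   `median_expr`, `missing` (gene absent from the matrix).
#' @export
pluripotency_panel <- function(norm, stage_dpf, panels = pluripotency_panels()) {
  stopifnot(ncol(norm) == length(stage_dpf))
  keep <- !is.na(stage_dpf)
  if (!any(keep)) stop("need at least one cell with a known stage")
  norm <- norm[, keep, drop = FALSE]
  stage_dpf <- stage_dpf[keep]
  stages <- sort(unique(stage_dpf))
  rows <- list()
  for (pn in names(panels)) for (gene in panels[[pn]]) {
    missing <- !gene %in% rownames(norm)
    for (st in stages) {
      med <- if (missing) NA_real_ else
        stats::median(as.numeric(norm[gene, stage_dpf == st]))
      rows[[length(rows) + 1]] <- data.frame(
        panel = pn, gene = gene, stage_dpf = st,
        median_expr = med, missing = missing, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
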