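#' Fit a reference-projection model
#'
#' Fits an L2-regularised multinomial (softmax) logistic regression of
#' reference class labels on normalised expression, after selecting the most
#' variable reference genes. The convex objective makes the fit
#' deterministic for fixed data and `lambda`. Query cells (other embryo
#' datasets, cell lines) are then mapped onto the reference classes with
#' [score_cells] / `predict()`, and summarised per group with
#' [group_match_scores].
#'
#' @param reference_norm normalised genes x cells matrix (see
#'   [normalize_log]); rownames are gene symbols.
#' @param labels class label per reference cell (e.g. lineage or
#'   stage-resolved epiblast clusters); every class needs >= 5 cells.
#' @param lambda L2 penalty strength (default 1.0), expressed against the
#'   summed (not mean) log-likelihood - the convention of standard logistic
#'   regression frameworks, so the effective shrinkage does not grow with
#'   reference size. Intercepts are never penalised, so as `lambda` grows
#'   the predictions shrink to the class priors.
#' @param n_features number of most-variable reference genes used as
#'   features (default 2000; capped at the gene count).
#' @return Object of class `embryo_projection` with elements `class_names`,
#'   `feature_genes`, `weights` (classes x (genes + 1), intercept first),
#'   `lambda`.
#' @export
fit_projection <- function(reference_norm, labels, lambda = 1.0,
                           n_features = 2000) {
  stopifnot(ncol(reference_norm) == length(labels))
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 5))
    stop("class(es) with fewer than 5 cells: ",
         paste(names(tab)[tab < 5], collapse = ", "))
  n <- ncol(reference_norm)
  mu <- Matrix::rowMeans(reference_norm)
  v <- (Matrix::rowSums(reference_norm^2) - n * mu^2) / (n - 1)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_features, nrow(reference_norm)))]
  feature_genes <- rownames(reference_norm)[sort(keep)]
  x <- Matrix::t(reference_norm[feature_genes, , drop = FALSE])
  # glmnet penalises the per-observation mean log-likelihood, so divide by n
  # to express lambda against the summed log-likelihood
  lam <- lambda / n
  fit <- glmnet::glmnet(x, factor(labels), family = "multinomial",
                        alpha = 0, lambda = lam, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  cf <- glmnet::coef.glmnet(fit, s = lam)
  classes <- names(cf)
  weights <- t(vapply(cf, function(b) as.numeric(b), numeric(length(feature_genes) + 1)))
  dimnames(weights) <- list(classes, c("(Intercept)", feature_genes))
  structure(list(class_names = classes,
                 feature_genes = feature_genes,
                 weights = weights,
                 lambda = lambda),
            class = "embryo_projection")
}

#' @export
print.embryo_projection <- function(x, ...) {
  cat("embryo_projection: ", length(x$class_names), " classes (",
      paste(x$class_names, collapse = ", "), "), ",
      length(x$feature_genes), " feature genes, lambda = ", x$lambda,
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.embryo_projection <- function(object, ...) object$weights

#' Class probabilities for query cells
#'
#' Applies the fitted softmax model to query cells. Query genes are matched
#' to the model's feature genes by symbol; feature genes absent from the
#' query are imputed as 0 (with a warning), the conservative choice for
#' log-normalised data.
#'
#' @param model an `embryo_projection` from [fit_projection].
#' @param query_norm normalised genes x cells matrix for the query.
#' @return cells x classes matrix of probabilities; each row sums to 1.
#' @export
score_cells <- function(model, query_norm) {
  stopifnot(inherits(model, "embryo_projection"))
  present <- intersect(model$feature_genes, rownames(query_norm))
  if (length(present) == 0) stop("no feature genes present in query")
  if (length(present) < length(model$feature_genes))
    warning(length(model$feature_genes) - length(present),
            " feature gene(s) absent from query; imputed as 0")
  x <- matrix(0, nrow = ncol(query_norm), ncol = length(model$feature_genes),
              dimnames = list(colnames(query_norm), model$feature_genes))
  x[, present] <- t(as.matrix(query_norm[present, , drop = FALSE]))
  eta <- cbind(1, x) %*% t(model$weights)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  colnames(p) <- model$class_names
  p
}

#' @export
predict.embryo_projection <- function(object, query_norm,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- score_cells(object, query_norm)
  if (type == "class") colnames(p)[max.col(p, ties.method = "first")] else p
}

#' Group-level match scores
#'
#' Mean predicted class probability per query group: the quantitative
#' matching score between a query group (e.g. a cell line or an external
#' embryo cluster) and each reference class. Rows sum to 1 because per-cell
#' probability vectors do.
#'
#' @param per_cell_probs cells x classes matrix from [score_cells].
#' @param group_ids group label per query cell.
#' @return groups x classes matrix of mean probabilities.
#' @export
group_match_scores <- function(per_cell_probs, group_ids) {
  stopifnot(nrow(per_cell_probs) == length(group_ids))
  groups <- unique(as.character(group_ids))
  empty <- setdiff(groups, group_ids)
  if (length(empty)) warning("dropping empty group(s)")
  out <- t(vapply(groups, function(g) {
    colMeans(per_cell_probs[group_ids == g, , drop = FALSE])
  }, numeric(ncol(per_cell_probs))))
  dimnames(out) <- list(groups, colnames(per_cell_probs))
  out
}
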