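unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

#' Embryo axis (origin, distal direction, lateral reference)
#'
#' Defines the hemispheric 0-180 degree coordinate: `origin` is the
#' reference centre, `distal` the unit proximal-to-distal direction, and
#' `lateral` the unit 0-degree direction in the plane orthogonal to
#' `distal`. `lateral` may be `NULL` until set by [reference_direction].
#'
#' @param origin 3-vector (micrometres).
#' @param distal unit 3-vector.
#' @param lateral unit 3-vector orthogonal to `distal`, or `NULL`.
#' @return Object of class `embryo_axis`.
#' @export
embryo_axis <- function(origin, distal, lateral = NULL) {
  stopifnot(length(origin) == 3, length(distal) == 3)
  distal <- unit3(as.numeric(distal))
  if (!is.null(lateral)) {
    lateral <- unit3(as.numeric(lateral))
    if (abs(sum(distal * lateral)) > 1e-9)
      stop("lateral must be orthogonal to distal")
  }
  structure(list(origin = as.numeric(origin), distal = distal,
                 lateral = lateral),
            class = "embryo_axis")
}

#' @export
print.embryo_axis <- function(x, ...) {
  cat("embryo_axis\n  origin :", signif(x$origin, 6),
      "\n  distal :", signif(x$distal, 6),
      "\n  lateral:", if (is.null(x$lateral)) "<unset>" else signif(x$lateral, 6),
      "\n")
  invisible(x)
}

#' Fit the proximal-distal axis of an embryo
#'
#' The distal direction is the unit vector from the epiblast centroid to the
#' hypoblast centroid; the origin is the epiblast centroid (a proxy for the
#' middle of the epiblast's proximal surface; a different centring rule can
#' be supplied downstream via the `axis_fitter` hooks). The lateral
#' reference is left unset.
#'
#' @param g an [embryo_geometry] with at least 3 epiblast and 3 hypoblast cells.
#' @return An [embryo_axis] without `lateral`.
#' @export
fit_axis <- function(g) {
  stopifnot(inherits(g, "embryo_geometry"))
  pos <- positions(g)
  epi <- pos[g$lineage == "EPI", , drop = FALSE]
  hyp <- pos[g$lineage == "HYP", , drop = FALSE]
  if (nrow(epi) < 3 || nrow(hyp) < 3)
    stop("need >= 3 epiblast and >= 3 hypoblast cells")
  ce <- colMeans(epi); ch <- colMeans(hyp)
  delta <- ch - ce
  if (sqrt(sum(delta^2)) < 1e-6)
    stop("degenerate geometry: coincident epiblast/hypoblast centroids")
  embryo_axis(origin = ce, distal = delta)
}

lateral_component <- function(pos, axis) {
  q <- sweep(pos, 2, axis$origin)
  q - outer(as.numeric(q %*% axis$distal), axis$distal)
}

#' Set the 0-degree reference from the marker-positive majority side
#'
#' The lateral reference `r` points toward the side where the majority of
#' marker-positive hypoblast cells lie: the mean over marker-positive
#' hypoblast cells of the component of `p - origin` orthogonal to the distal
#' axis, normalised. Angles measured against `r` therefore place the marker
#' majority near 0 degrees.
#'
#' @param g an [embryo_geometry].
#' @param axis an [embryo_axis] (lateral may be unset).
#' @param marker marker column used for the reference (default `"CER1"`).
#' @return The axis with `lateral` set.
#' @export
reference_direction <- function(g, axis, marker = "CER1") {
  stopifnot(inherits(g, "embryo_geometry"), inherits(axis, "embryo_axis"))
  sel <- g$lineage == "HYP" & g[[marker]]
  if (!any(sel)) stop("reference undefined: no ", marker, "+ hypoblast cells")
  pos <- positions(g)
  lat <- lateral_component(pos[sel, , drop = FALSE], axis)
  v <- colMeans(lat)
  hyp <- pos[g$lineage == "HYP", , drop = FALSE]
  radius <- mean(sqrt(rowSums(sweep(hyp, 2, axis$origin)^2)))
  if (sqrt(sum(v^2)) < 1e-6 * radius)
    stop("degenerate reference: ", marker,
         "+ cells are laterally symmetric about the axis")
  embryo_axis(axis$origin, axis$distal, lateral = v)
}

#' Hemispheric angle of a point
#'
#' The angle between `p - origin` and the lateral reference, in degrees:
#' 0 at the marker-majority side, 90 at the distal pole, 180 on the
#' opposite side. Invariant under rigid motions applied jointly to points
#' and axis.
#'
#' @param p a 3-vector, or an n x 3 matrix of points.
#' @param axis a complete [embryo_axis] (lateral set).
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
cell_angle <- function(p, axis) {
  stopifnot(inherits(axis, "embryo_axis"))
  if (is.null(axis$lateral)) stop("axis is incomplete: lateral reference unset")
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  q <- sweep(p, 2, axis$origin)
  nq <- sqrt(rowSums(q^2))
  if (any(nq < 1e-12)) stop("undefined angle: point coincides with the origin")
  cosang <- pmin(1, pmax(-1, as.numeric(q %*% axis$lateral) / nq))
  acos(cosang) * 180 / pi
}

#' Localisation-bias permutation test
#'
#' Tests whether marker-positive hypoblast cells concentrate toward one side
#' of the hypoblast. The statistic is the mean resultant length of the unit
#' lateral (azimuthal) projections of the marker-positive cells - a
#' reference-free measure, so the test is not biased by choosing the
#' 0-degree side from the same data. The null distribution is obtained by
#' permuting marker labels among hypoblast cells; the reported p-value is
#' `(1 + #(T_perm >= T_obs)) / (n_perm + 1)`.
#'
#' @param g an [embryo_geometry] with >= 3 marker-positive and >= 3
#'   marker-negative hypoblast cells (otherwise `NA` is returned).
#' @param axis optional [embryo_axis]; computed with `axis_fitter` if `NULL`.
#' @param marker marker column (default `"CER1"`).
#' @param n_perm number of label permutations (default 10000).
#' @param seed mandatory RNG seed.
#' @param axis_fitter function `g -> embryo_axis` (default [fit_axis]).
#' @return The permutation p-value (`NA_real_` when cell numbers are
#'   insufficient), with attribute `"statistic"` (observed mean resultant
#'   length).
#' @export
bias_test <- function(g, axis = NULL, marker = "CER1", n_perm = 10000, seed,
                      axis_fitter = fit_axis) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(g, "embryo_geometry"))
  if (is.null(axis)) axis <- axis_fitter(g)
  hyp <- g$lineage == "HYP"
  pos <- g[[marker]][hyp]
  n <- sum(hyp); m <- sum(pos)
  if (m < 3 || n - m < 3) return(NA_real_)
  lat <- lateral_component(positions(g)[hyp, , drop = FALSE], axis)
  nl <- sqrt(rowSums(lat^2))
  u <- lat / ifelse(nl > 1e-12, nl, 1)
  u[nl <= 1e-12, ] <- 0          # cells on the axis carry no azimuth
  t_obs <- sqrt(sum(colSums(u[pos, , drop = FALSE])^2)) / m
  t_perm <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n, m))
    sx <- matrix(u[, 1][idx], nrow = m)
    sy <- matrix(u[, 2][idx], nrow = m)
    sz <- matrix(u[, 3][idx], nrow = m)
    sqrt(colSums(sx)^2 + colSums(sy)^2 + colSums(sz)^2) / m
  })
  p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
  attr(p, "statistic") <- t_obs
  p
}

#' Angular profile of marker-positive hypoblast cells
#'
#' Computes the hemispheric angles of all marker-positive hypoblast cells,
#' bins them into eighteen 10-degree bins (right-open except the last), and
#' attaches the mean angle and the localisation-bias p-value.
#'
#' @param g an [embryo_geometry].
#' @param axis a complete [embryo_axis]; if `NULL`, [fit_axis] then
#'   [reference_direction] are applied.
#' @param marker marker column (default `"CER1"`).
#' @param n_perm permutations for [bias_test].
#' @param seed mandatory RNG seed (used by the bias test).
#' @return Object of class `angular_profile`: list with `embryo_id`,
#'   `angles`, `bin_edges`, `bin_counts`, `mean_angle`, `n_marker_pos`,
#'   `bias_p`, `seed`.
#' @export
angular_profile <- function(g, axis = NULL, marker = "CER1",
                            n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(g, "embryo_geometry"))
  if (is.null(axis)) axis <- reference_direction(g, fit_axis(g), marker)
  if (is.null(axis$lateral)) axis <- reference_direction(g, axis, marker)
  sel <- g$lineage == "HYP" & g[[marker]]
  if (!any(sel)) stop("no ", marker, "+ hypoblast cells")
  ang <- cell_angle(positions(g)[sel, , drop = FALSE], axis)
  edges <- seq(0, 180, by = 10)
  counts <- tabulate(findInterval(ang, edges, rightmost.closed = TRUE),
                     nbins = 18L)
  structure(list(embryo_id = g$embryo_id[1],
                 angles = ang,
                 bin_edges = edges,
                 bin_counts = counts,
                 mean_angle = mean(ang),
                 n_marker_pos = length(ang),
                 bias_p = as.numeric(bias_test(g, axis = axis, marker = marker,
                                               n_perm = n_perm, seed = seed)),
                 seed = seed),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat("angular_profile (", x$embryo_id, "): ", x$n_marker_pos,
      " marker+ cells, mean angle ", round(x$mean_angle, 1),
      " deg, bias p = ", signif(x$bias_p, 3), "\n", sep = "")
  invisible(x)
}

#' Pool angular profiles across embryos
#'
#' @param profiles list of [angular_profile] objects sharing bin edges.
#' @param alpha significance level for flagging biased embryos (default 0.05).
#' @return List with `bin_edges`, `pooled_counts` (elementwise sum) and
#'   `table` (per embryo: `embryo_id`, `n_marker_pos`, `mean_angle`,
#'   `bias_p`, `biased`).
#' @export
align_profiles <- function(profiles, alpha = 0.05) {
  stopifnot(length(profiles) > 0)
  edges <- profiles[[1]]$bin_edges
  for (p in profiles)
    if (!identical(p$bin_edges, edges)) stop("profiles have mismatched bins")
  pooled <- Reduce(`+`, lapply(profiles, `[[`, "bin_counts"))
  tab <- data.frame(
    embryo_id = vapply(profiles, `[[`, "", "embryo_id"),
    n_marker_pos = vapply(profiles, `[[`, 0L, "n_marker_pos"),
    mean_angle = vapply(profiles, `[[`, 0, "mean_angle"),
    bias_p = vapply(profiles, `[[`, 0, "bias_p"),
    stringsAsFactors = FALSE)
  tab$biased <- !is.na(tab$bias_p) & tab$bias_p < alpha
  list(bin_edges = edges, pooled_counts = pooled, table = tab)
}

#' Marker-positive fraction of a compartment
#'
#' @param g an [embryo_geometry].
#' @param numerator_marker marker column (default `"CER1"`).
#' @param denominator_lineage compartment (default `"HYP"`, the hypoblast).
#' @return Fraction in `[0, 1]`; `NA_real_` if the compartment is empty.
#' @export
marker_fraction <- function(g, numerator_marker = "CER1",
                            denominator_lineage = "HYP") {
  stopifnot(inherits(g, "embryo_geometry"))
  den <- g$lineage == denominator_lineage
  if (!any(den)) return(NA_real_)
  sum(g[[numerator_marker]][den]) / sum(den)
}

#' Distance from marker-positive cells to a marker domain
#'
#' Euclidean nearest-neighbour distance from each epiblast cell to the set
#' of marker-positive hypoblast cells, compared between epiblast cells with
#' and without the `from_marker` (e.g. nuclear pSMAD1.5 versus the CER1
#' domain) by a two-sided rank-sum test.
#'
#' @param g an [embryo_geometry].
#' @param from_marker epiblast marker (default `"pSMAD15"`).
#' @param to_marker hypoblast domain marker (default `"CER1"`).
#' @return List with `dist_pos`, `dist_neg` (nearest distances, micrometres),
#'   `median_pos`, `median_neg`, `p_value`.
#' @export
marker_domain_distance <- function(g, from_marker = "pSMAD15",
                                   to_marker = "CER1") {
  stopifnot(inherits(g, "embryo_geometry"))
  epi <- g$lineage == "EPI"
  dom <- g$lineage == "HYP" & g[[to_marker]]
  if (!any(epi) || !any(dom))
    stop("need at least one epiblast cell and one ", to_marker,
         "+ hypoblast cell")
  pos <- positions(g)
  pe <- pos[epi, , drop = FALSE]
  pd <- pos[dom, , drop = FALSE]
  d2 <- outer(rowSums(pe^2), rep(1, nrow(pd))) +
    outer(rep(1, nrow(pe)), rowSums(pd^2)) - 2 * pe %*% t(pd)
  nearest <- sqrt(pmax(0, apply(d2, 1, min)))
  fm <- g[[from_marker]][epi]
  p <- if (sum(fm) >= 1 && sum(!fm) >= 1)
    suppressWarnings(stats::wilcox.test(nearest[fm], nearest[!fm])$p.value)
  else NA_real_
  list(dist_pos = nearest[fm], dist_neg = nearest[!fm],
       median_pos = stats::median(nearest[fm]),
       median_neg = stats::median(nearest[!fm]),
       p_value = p)
}
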