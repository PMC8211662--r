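# Run expr under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Parameters for the synthetic count generator
#'
#' Defaults reproduce the scale of the reference embryo cohort: four lineages
#' with 166 epiblast, 136 hypoblast, 2182 cytotrophoblast and 2336
#' syncytiotrophoblast cells across 16 embryos (half at 9, half at 11
#' d.p.f.), plus a block of injected low-quality cells that fail the standard
#' quality filters (high mitochondrial load, few detected genes).
#'
#' @param n_cells_per_lineage named integer vector; names from
#'   `EPI`, `HYP`, `CTB`, `STB`.
#' @param marker_programs named list per lineage with elements `genes`
#'   (character) and `boost` (added mean expression for those genes).
#' @param baseline_mean mean count of a background gene in a healthy cell.
#' @param nb_dispersion negative-binomial size parameter (`Inf` = Poisson).
#' @param mito_fraction_mean expected mitochondrial fraction of healthy cells.
#' @param n_lowquality_cells number of injected low-quality cells.
#' @param lowquality_mito expected mitochondrial fraction of low-quality cells.
#' @param lowquality_depth depth scaling of low-quality cells (reduces
#'   detected genes below the filter threshold).
#' @param n_genes total gene universe size (markers + panels + mitochondrial
#'   genes + filler genes).
#' @param n_embryos number of embryos the cells are spread over.
#' @param seed mandatory RNG seed.
#' @return A list of class `synthetic_count_params`.
#' @export
count_params <- function(n_cells_per_lineage = c(EPI = 166L, HYP = 136L,
                                                 CTB = 2182L, STB = 2336L),
                         marker_programs = NULL,
                         baseline_mean = 1.5,
                         nb_dispersion = 2,
                         mito_fraction_mean = 0.05,
                         n_lowquality_cells = 250L,
                         lowquality_mito = 0.5,
                         lowquality_depth = 0.15,
                         n_genes = 2000L,
                         n_embryos = 16L,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(n_cells_per_lineage) == 0) stop("empty lineage map")
  if (!all(names(n_cells_per_lineage) %in% c("EPI", "HYP", "CTB", "STB")))
    stop("lineage names must be among EPI, HYP, CTB, STB")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (mito_fraction_mean < 0 || mito_fraction_mean > 1 ||
      lowquality_mito < 0 || lowquality_mito > 1)
    stop("mitochondrial fractions must lie in [0, 1]")
  if (is.null(marker_programs)) {
    marker_programs <- lapply(lineage_markers()[names(n_cells_per_lineage)],
                              function(g) list(genes = g, boost = 30))
  }
  structure(list(n_cells_per_lineage = n_cells_per_lineage,
                 marker_programs = marker_programs,
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion,
                 mito_fraction_mean = mito_fraction_mean,
                 n_lowquality_cells = as.integer(n_lowquality_cells),
                 lowquality_mito = lowquality_mito,
                 lowquality_depth = lowquality_depth,
                 n_genes = as.integer(n_genes),
                 n_embryos = as.integer(n_embryos),
                 seed = seed),
            class = "synthetic_count_params")
}

# Gene universe: named genes first (markers, panels, antagonists, target
# genes), then mitochondrial genes, padded with filler genes to n_genes.
synthetic_gene_universe <- function(p) {
  named <- unique(c(
    unlist(lapply(p$marker_programs, `[[`, "genes"), use.names = FALSE),
    unlist(pluripotency_panels(), use.names = FALSE),
    "CER1", ave_antagonist_panel()
  ))
  named <- setdiff(named, mito_gene_symbols())
  n_fill <- p$n_genes - length(named) - length(mito_gene_symbols())
  if (n_fill < 0) stop("n_genes smaller than the named gene set")
  c(named, mito_gene_symbols(),
    sprintf("FILLER%04d", seq_len(n_fill)))
}

draw_counts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, size = size, mu = mu)
}

#' Simulate a synthetic embryo count matrix
#'
#' Draws negative-binomial counts with lineage-specific marker programs
#' (elevated means on each lineage's marker genes), mitochondrial genes
#' calibrated to a target mitochondrial fraction, and a block of low-quality
#' cells with reduced depth and elevated mitochondrial load. Cells are
#' allocated round-robin to embryos, half annotated at 9 d.p.f. and half at
#' 11 d.p.f.
#'
#' @param p a [count_params] object.
#' @return A list with `matrix` (a [gene_matrix]) and `labels` (character:
#'   true lineage per cell, `"LQ"` for injected low-quality cells).
#' @export
simulate_counts <- function(p) {
  stopifnot(inherits(p, "synthetic_count_params"))
  with_seed(p$seed, {
    genes <- synthetic_gene_universe(p)
    G <- length(genes)
    mito <- startsWith(genes, "MT-")
    n_mito <- sum(mito)

    base_mu <- rep(p$baseline_mean, G)
    names(base_mu) <- genes
    lineages <- names(p$n_cells_per_lineage)

    mu_for_lineage <- function(lin) {
      mu <- base_mu
      prog <- p$marker_programs[[lin]]
      if (!is.null(prog)) {
        hit <- intersect(prog$genes, genes)
        mu[hit] <- mu[hit] + prog$boost
      }
      # mito means chosen so E[mito counts] / E[total] = mito_fraction_mean
      non_mito_total <- sum(mu[!mito])
      mu[mito] <- p$mito_fraction_mean / (1 - p$mito_fraction_mean) *
        non_mito_total / n_mito
      mu
    }

    blocks <- list(); labels <- character(0)
    for (lin in lineages) {
      n <- p$n_cells_per_lineage[[lin]]
      if (n == 0) next
      mu <- mu_for_lineage(lin)
      x <- matrix(draw_counts(G * n, mu = mu, size = p$nb_dispersion),
                  nrow = G, ncol = n)
      blocks[[lin]] <- x
      labels <- c(labels, rep(lin, n))
    }
    if (p$n_lowquality_cells > 0) {
      mu <- base_mu * p$lowquality_depth
      non_mito_total <- sum(mu[!mito])
      mu[mito] <- p$lowquality_mito / (1 - p$lowquality_mito) *
        non_mito_total / n_mito
      x <- matrix(draw_counts(G * p$n_lowquality_cells, mu = mu,
                              size = p$nb_dispersion),
                  nrow = G, ncol = p$n_lowquality_cells)
      blocks[["LQ"]] <- x
      labels <- c(labels, rep("LQ", p$n_lowquality_cells))
    }
    counts <- do.call(cbind, blocks)
    n_cells <- ncol(counts)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))

    embryo_ids <- sprintf("embryo%02d", rep_len(seq_len(p$n_embryos), n_cells))
    stage <- ifelse(as.integer(sub("embryo", "", embryo_ids)) <=
                      ceiling(p$n_embryos / 2), 9L, 11L)
    meta <- data.frame(barcode = cell_ids, embryo_id = embryo_ids,
                       stage_dpf = stage, source = "synthetic",
                       stringsAsFactors = FALSE)
    m <- gene_matrix(counts, genes, cell_ids, meta)
    list(matrix = m, labels = labels)
  })
}

#' Parameters for the synthetic embryo geometry generator
#'
#' The geometry emulates a segmented post-implantation embryo: epiblast
#' nuclei inside a proximal ball, hypoblast nuclei on a distal hemispherical
#' shell, and marker-positive hypoblast cells concentrated toward an anterior
#' direction with a von Mises-Fisher-style kernel
#' `exp(kappa * cos(angle to anterior))`, rescaled so the expected
#' marker-positive fraction equals `marker_fraction`. `kappa = 0` gives a
#' spatially uniform marker domain (the widespread 7 d.p.f. regime);
#' increasing `kappa` concentrates the domain to one side (the asymmetric
#' 9 d.p.f. regime).
#'
#' @param n_epiblast,n_hypoblast cell numbers per compartment.
#' @param radius_um embryo radius in micrometres (default 50).
#' @param marker_fraction expected fraction of marker-positive hypoblast cells.
#' @param fraction_shape Beta concentration (a+b) for per-embryo variation of
#'   the marker fraction; `Inf` (default) fixes the fraction.
#' @param concentration_kappa angular concentration (>= 0; 0 = uniform).
#' @param anterior_direction 3-vector; its component orthogonal to the
#'   proximal-distal axis defines the planted anterior side.
#' @param psmad_fraction fraction of epiblast cells with nuclear pSMAD1.5,
#'   placed preferentially opposite the anterior direction (anti-correlated
#'   with the marker domain).
#' @param embryo_id,stage_dpf identifiers stamped on every cell.
#' @param seed mandatory RNG seed.
#' @return A list of class `synthetic_geometry_params`.
#' @export
geometry_params <- function(n_epiblast = 30L, n_hypoblast = 25L,
                            radius_um = 50,
                            marker_fraction = 0.3,
                            fraction_shape = Inf,
                            concentration_kappa = 0,
                            anterior_direction = c(1, 0, 0),
                            psmad_fraction = 0.3,
                            embryo_id = "embryo01",
                            stage_dpf = 9L,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_hypoblast == 0) stop("n_hypoblast must be positive")
  if (marker_fraction < 0 || marker_fraction > 1)
    stop("marker_fraction must lie in [0, 1]")
  if (concentration_kappa < 0) stop("concentration_kappa must be >= 0")
  if (radius_um <= 0) stop("radius_um must be positive")
  structure(list(n_epiblast = as.integer(n_epiblast),
                 n_hypoblast = as.integer(n_hypoblast),
                 radius_um = radius_um,
                 marker_fraction = marker_fraction,
                 fraction_shape = fraction_shape,
                 concentration_kappa = concentration_kappa,
                 anterior_direction = anterior_direction,
                 psmad_fraction = psmad_fraction,
                 embryo_id = embryo_id,
                 stage_dpf = as.integer(stage_dpf),
                 seed = seed),
            class = "synthetic_geometry_params")
}

#' Stage presets for the geometry generator
#'
#' `geometry_params_7dpf()`: widespread marker domain (`kappa = 0`), marker
#' fraction 0.755 (the centre of the 69-82% interquartile band reported for
#' attached embryos), 40 hypoblast cells; per-embryo counting noise alone
#' accounts for the band's width. `geometry_params_9dpf()`: one-sided domain
#' (`kappa = 4`), marker fraction 0.30 (centre of the 17-43% band) with
#' per-embryo Beta heterogeneity (`fraction_shape = 20`), 25 hypoblast cells.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [geometry_params].
#' @return A `synthetic_geometry_params` object.
#' @export
geometry_params_7dpf <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_hypoblast = 40L, marker_fraction = 0.755, fraction_shape = Inf,
         concentration_kappa = 0, stage_dpf = 7L, seed = seed),
    list(...))
  do.call(geometry_params, args)
}

#' @rdname geometry_params_7dpf
#' @export
geometry_params_9dpf <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_hypoblast = 25L, marker_fraction = 0.30, fraction_shape = 20,
         concentration_kappa = 4, stage_dpf = 9L, seed = seed),
    list(...))
  do.call(geometry_params, args)
}

# Uniform points on the unit sphere.
runif_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Solve for a such that mean(pmin(1, a * w)) == f (f in (0,1], w > 0).
solve_marker_scale <- function(w, f) {
  if (f <= 0) return(0)
  g <- function(loga) mean(pmin(1, exp(loga) * w)) - f
  lo <- log(f / max(w)) - 1
  hi <- log(1 / min(w)) + 1    # all probabilities 1 -> mean 1 >= f
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate a synthetic embryo geometry
#'
#' @param p a [geometry_params] object (or stage preset).
#' @return An [embryo_geometry] data frame: positions in micrometres,
#'   lineage labels, and logical marker columns `CER1`, `GATA6`, `OCT4`,
#'   `LEFTY1`, `pSMAD15`.
#' @export
simulate_geometry <- function(p) {
  stopifnot(inherits(p, "synthetic_geometry_params"))
  with_seed(p$seed, {
    r <- p$radius_um
    d0 <- c(0, 0, 1)                      # proximal -> distal

    # epiblast: uniform ball, strictly proximal of the equatorial plane
    u <- runif_sphere(p$n_epiblast) * (stats::runif(p$n_epiblast)^(1 / 3) * 0.5 * r)
    epi <- sweep(u, 2, c(0, 0, -0.6 * r), `+`)

    # hypoblast: distal hemispherical shell
    hv <- runif_sphere(p$n_hypoblast)
    hv[, 3] <- abs(hv[, 3])
    hyp <- hv * r

    ant <- p$anterior_direction - sum(p$anterior_direction * d0) * d0
    if (sqrt(sum(ant^2)) < 1e-12)
      stop("anterior_direction must have a lateral component")
    ant <- ant / sqrt(sum(ant^2))

    f <- p$marker_fraction
    if (is.finite(p$fraction_shape) && f > 0 && f < 1)
      f <- stats::rbeta(1, f * p$fraction_shape, (1 - f) * p$fraction_shape)

    w <- exp(p$concentration_kappa * (hv %*% ant)[, 1])
    a <- solve_marker_scale(w, f)
    cer1 <- stats::runif(p$n_hypoblast) < pmin(1, a * w)

    # LEFTY1 drawn from the same spatial kernel, independently of CER1
    a2 <- solve_marker_scale(w, f)
    lefty1_hyp <- stats::runif(p$n_hypoblast) < pmin(1, a2 * w)

    # pSMAD1.5 in epiblast cells, anti-correlated with the anterior domain
    epi_u <- epi / sqrt(rowSums(epi^2))
    wp <- exp(p$concentration_kappa * (-(epi_u %*% ant)[, 1]))
    ap <- solve_marker_scale(wp, p$psmad_fraction)
    psmad_epi <- stats::runif(p$n_epiblast) < pmin(1, ap * wp)

    n <- p$n_epiblast + p$n_hypoblast
    pos <- rbind(epi, hyp)
    lineage <- c(rep("EPI", p$n_epiblast), rep("HYP", p$n_hypoblast))
    embryo_geometry(data.frame(
      cell_id = sprintf("%s_c%04d", p$embryo_id, seq_len(n)),
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      lineage = lineage,
      CER1 = c(rep(FALSE, p$n_epiblast), cer1),
      GATA6 = lineage == "HYP",
      OCT4 = lineage == "EPI",
      LEFTY1 = c(rep(FALSE, p$n_epiblast), lefty1_hyp),
      pSMAD15 = c(psmad_epi, rep(FALSE, p$n_hypoblast)),
      embryo_id = p$embryo_id,
      stage_dpf = p$stage_dpf,
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate a cohort of embryo geometries
#'
#' Convenience wrapper generating `n_embryos` embryos from a stage preset
#' (or explicit parameter overrides), each with its own sub-seed derived
#' deterministically from `seed`.
#'
#' @param n_embryos number of embryos.
#' @param stage `"7dpf"` or `"9dpf"` preset.
#' @param seed master seed; embryo `i` uses `seed + i`.
#' @param ... overrides forwarded to the preset.
#' @return List of [embryo_geometry] objects.
#' @export
simulate_cohort <- function(n_embryos, stage = c("9dpf", "7dpf"), seed, ...) {
  stage <- match.arg(stage)
  maker <- if (stage == "7dpf") geometry_params_7dpf else geometry_params_9dpf
  lapply(seq_len(n_embryos), function(i) {
    simulate_geometry(maker(seed = seed + i,
                            embryo_id = sprintf("embryo%03d", i), ...))
  })
}
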