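# Shared fixtures built in code.

# Small count matrix with named genes, deterministic entries.
toy_gene_matrix <- function() {
  genes <- c("MT-CO1", "GAPDH", "POU5F1", "GATA6", "CGA")
  counts <- matrix(c(
    30, 70, 0, 0, 0,    # cell 1: mito 0.3
    0, 10, 90, 0, 0,    # cell 2
    5, 5, 0, 90, 0,     # cell 3
    0, 0, 0, 0, 0,      # cell 4: all-zero
    1, 1, 1, 1, 1       # cell 5
  ), nrow = 5, ncol = 5, byrow = FALSE,
  dimnames = NULL)
  gene_matrix(counts, genes, paste0("bc", 1:5))
}

# Scaled-down synthetic embryo for annotation/projection tests.
small_sim <- function(seed = 11, n = 120, lq = 30) {
  simulate_counts(count_params(
    n_cells_per_lineage = c(EPI = n, HYP = n, CTB = n, STB = n),
    n_lowquality_cells = lq, n_genes = 600, n_embryos = 8, seed = seed))
}

# Hand-built geometry: epiblast triangle proximal, hypoblast cells at known
# positions on a shell of radius 10 around the epiblast centroid.
handmade_geometry <- function(hyp_xyz, cer1, epi_n = 3) {
  epi <- matrix(c(0, 0, -10,
                  1, 0, -10,
                  -1, 0, -10), ncol = 3, byrow = TRUE)[seq_len(epi_n), , drop = FALSE]
  n_h <- nrow(hyp_xyz)
  embryo_geometry(data.frame(
    cell_id = sprintf("c%02d", seq_len(epi_n + n_h)),
    x_um = c(epi[, 1], hyp_xyz[, 1]),
    y_um = c(epi[, 2], hyp_xyz[, 2]),
    z_um = c(epi[, 3], hyp_xyz[, 3]),
    lineage = c(rep("EPI", epi_n), rep("HYP", n_h)),
    CER1 = c(rep(FALSE, epi_n), cer1),
    GATA6 = c(rep(FALSE, epi_n), rep(TRUE, n_h)),
    OCT4 = c(rep(TRUE, epi_n), rep(FALSE, n_h)),
    LEFTY1 = FALSE,
    pSMAD15 = FALSE,
    stringsAsFactors = FALSE))
}

# Random rigid motion (rotation + translation).
random_rigid <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  list(R = qr_q, t = rnorm(3, sd = 20))
}

apply_rigid <- function(g, motion) {
  pos <- positions(g) %*% t(motion$R)
  pos <- sweep(pos, 2, motion$t, `+`)
  g$x_um <- pos[, 1]; g$y_um <- pos[, 2]; g$z_um <- pos[, 3]
  g
}
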