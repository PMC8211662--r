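test_that("axis fitting matches the closed form and centroid oracle", {
  hyp <- matrix(c(0, 0, 10, 1, 0, 10, -1, 0, 10), ncol = 3, byrow = TRUE)
  g <- handmade_geometry(hyp, cer1 = rep(TRUE, 3))
  g$z_um[g$lineage == "EPI"] <- 0   # epiblast centroid at z = 0
  ax <- fit_axis(g)
  expect_equal(ax$origin, c(0, 0, 0))
  expect_equal(ax$distal, c(0, 0, 1))
  # random configurations vs brute-force centroids
  for (s in 1:20) {
    set.seed(s)
    pos <- matrix(rnorm(60, sd = 30), ncol = 3)
    g2 <- handmade_geometry(pos[4:20, ], cer1 = rep(TRUE, 17))
    g2$x_um[1:3] <- pos[1:3, 1]; g2$y_um[1:3] <- pos[1:3, 2]; g2$z_um[1:3] <- pos[1:3, 3]
    ax2 <- fit_axis(g2)
    ce <- colMeans(pos[1:3, ]); ch <- colMeans(pos[4:20, ])
    expect_equal(ax2$origin, ce, tolerance = 1e-9)
    expect_equal(ax2$distal, (ch - ce) / sqrt(sum((ch - ce)^2)), tolerance = 1e-9)
  }
  # translation equivariance
  g3 <- g
  g3$x_um <- g3$x_um + 5; g3$y_um <- g3$y_um - 2; g3$z_um <- g3$z_um + 1
  ax3 <- fit_axis(g3)
  expect_equal(ax3$origin, ax$origin + c(5, -2, 1))
  expect_equal(ax3$distal, ax$distal)
  # coincident centroids are degenerate
  bad <- handmade_geometry(matrix(c(0, 0, -10, 1, 0, -10, -1, 0, -10),
                                  ncol = 3, byrow = TRUE), rep(TRUE, 3))
  expect_error(fit_axis(bad), "degenerate")
})

test_that("reference direction points at the marker majority and detects symmetry", {
  hyp <- matrix(c(10, 0, 0, 10, 0, 1, 10, 0, -1, -10, 0, 0),
                ncol = 3, byrow = TRUE)
  g <- handmade_geometry(hyp, cer1 = c(TRUE, TRUE, TRUE, FALSE))
  ax <- embryo_axis(c(0, 0, 0), c(0, 0, 1))
  axr <- reference_direction(g, ax)
  expect_equal(axr$lateral, c(1, 0, 0))
  # two exactly opposed marker cells -> degenerate
  g2 <- handmade_geometry(matrix(c(10, 0, 0, -10, 0, 0, 0, 10, 0),
                                 ncol = 3, byrow = TRUE),
                          cer1 = c(TRUE, TRUE, FALSE))
  expect_error(reference_direction(g2, ax), "degenerate reference")
  g3 <- handmade_geometry(hyp, cer1 = rep(FALSE, 4))
  expect_error(reference_direction(g3, ax), "reference undefined")
})

test_that("cell angles hit the 0/90/180 landmarks and match brute force", {
  ax <- embryo_axis(c(1, 2, 3), distal = c(0, 0, 1), lateral = c(1, 0, 0))
  expect_equal(cell_angle(c(1, 2, 3) + c(5, 0, 0), ax), 0)
  expect_equal(cell_angle(c(1, 2, 3) + c(0, 0, 7), ax), 90)
  expect_equal(cell_angle(c(1, 2, 3) + c(-2, 0, 0), ax), 180)
  expect_error(cell_angle(c(1, 2, 3), ax), "undefined angle")
  expect_error(cell_angle(c(9, 9, 9), embryo_axis(c(0, 0, 0), c(0, 0, 1))),
               "incomplete")
  set.seed(33)
  pts <- matrix(rnorm(300, sd = 10), ncol = 3)
  got <- cell_angle(pts, ax)
  oracle <- apply(pts, 1, function(p) {
    v <- p - ax$origin
    acos(sum(v * ax$lateral) / sqrt(sum(v^2))) * 180 / pi
  })
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_true(all(got >= 0 & got <= 180))
})

test_that("angles are invariant under rigid motions and mirror symmetry", {
  g <- simulate_geometry(geometry_params(n_hypoblast = 40, marker_fraction = 0.4,
                                         concentration_kappa = 2, seed = 9))
  ax <- reference_direction(g, fit_axis(g))
  sel <- g$lineage == "HYP" & g$CER1
  ang <- cell_angle(positions(g)[sel, ], ax)
  motion <- random_rigid(5)
  g2 <- apply_rigid(g, motion)
  ax2 <- embryo_axis(as.numeric(motion$R %*% ax$origin + motion$t),
                     as.numeric(motion$R %*% ax$distal),
                     as.numeric(motion$R %*% ax$lateral))
  expect_equal(cell_angle(positions(g2)[sel, ], ax2), ang, tolerance = 1e-9)
  # mirror through the (distal, lateral) plane: y -> -y for canonical axes
  axc <- embryo_axis(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  pts <- positions(g)[sel, ]
  mir <- pts; mir[, 2] <- -mir[, 2]
  expect_equal(cell_angle(mir, axc), cell_angle(pts, axc), tolerance = 1e-12)
})

test_that("angular profile bins and means match brute-force binning", {
  # 3 cells at 0, 90, 180 degrees
  hyp <- matrix(c(10, 0, 0, 0, 0, 10, -10, 0, 0, 0, 5, 5),
                ncol = 3, byrow = TRUE)
  g <- handmade_geometry(hyp, cer1 = c(TRUE, TRUE, TRUE, FALSE))
  ax <- embryo_axis(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  prof <- angular_profile(g, axis = ax, n_perm = 50, seed = 1)
  expect_equal(prof$mean_angle, 90)
  expect_equal(prof$n_marker_pos, 3L)
  expected <- integer(18); expected[c(1, 10, 18)] <- 1L
  expect_identical(prof$bin_counts, expected)
  expect_true(is.na(prof$bias_p))    # too few cells for the test
  # histogram equals brute-force binning on random angles
  set.seed(8)
  u <- runif_pts <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 10
  g2 <- handmade_geometry(u, cer1 = rep(TRUE, 300))
  prof2 <- angular_profile(g2, axis = ax, n_perm = 50, seed = 2)
  ang <- cell_angle(u, ax)
  brute <- sapply(1:18, function(b)
    sum(ang >= (b - 1) * 10 & (ang < b * 10 | (b == 18 & ang == 180))))
  expect_identical(prof2$bin_counts, as.integer(brute))
  expect_equal(sum(prof2$bin_counts), prof2$n_marker_pos)
  expect_equal(prof2$mean_angle, mean(ang))
})

test_that("large uniform geometry has mean angle 90 and kappa shifts it down", {
  g <- simulate_geometry(geometry_params(n_hypoblast = 10000, marker_fraction = 0.5,
                                         concentration_kappa = 0, seed = 31))
  # measure against the true planted axis (anterior = +x)
  ax <- embryo_axis(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  sel <- g$lineage == "HYP" & g$CER1
  expect_equal(mean(cell_angle(positions(g)[sel, ], ax)), 90, tolerance = 2 / 90)
  # parameter recovery: mean angle decreases monotonically in kappa
  means <- sapply(c(0, 1, 2, 4, 8), function(k) {
    gk <- simulate_geometry(geometry_params(n_hypoblast = 5000,
                                            marker_fraction = 0.3,
                                            concentration_kappa = k, seed = 77))
    sk <- gk$lineage == "HYP" & gk$CER1
    mean(cell_angle(positions(gk)[sk, ], ax))
  })
  expect_true(all(diff(means) < 0))
})

test_that("bias test is extreme for separated markers and forced for all-positive", {
  set.seed(14)
  neg <- matrix(rnorm(60), ncol = 3); neg <- neg / sqrt(rowSums(neg^2)) * 10
  neg[, 3] <- abs(neg[, 3])
  pos <- matrix(rep(c(10, 0, 0.5), each = 20), ncol = 3) +
    matrix(rnorm(60, sd = .1), ncol = 3)
  g <- handmade_geometry(rbind(pos, neg), cer1 = rep(c(TRUE, FALSE), each = 20))
  expect_lte(as.numeric(bias_test(g, n_perm = 2000, seed = 3)), 0.01)
  g_all <- handmade_geometry(rbind(pos, neg), cer1 = rep(TRUE, 40))
  expect_true(is.na(bias_test(g_all, n_perm = 100, seed = 3)))  # no negatives
  # determinism under a fixed seed
  p1 <- bias_test(g, n_perm = 500, seed = 99)
  p2 <- bias_test(g, n_perm = 500, seed = 99)
  expect_identical(p1, p2)
})

test_that("Monte-Carlo bias p-values match exhaustive enumeration for small hypoblasts", {
  ax_stat <- function(u, idx) {
    m <- length(idx)
    sqrt(sum(colSums(u[idx, , drop = FALSE])^2)) / m
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 8; m <- 4
    hyp <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
    cer1 <- rep(FALSE, n); cer1[sample(n, m)] <- TRUE
    g <- handmade_geometry(hyp, cer1)
    ax <- fit_axis(g)
    p_mc <- as.numeric(bias_test(g, n_perm = 4000, seed = 100 + s))
    # exhaustive oracle over all C(8,4) subsets
    lat <- positions(g)[g$lineage == "HYP", , drop = FALSE]
    q <- sweep(lat, 2, ax$origin)
    q <- q - outer(as.numeric(q %*% ax$distal), ax$distal)
    u <- q / sqrt(rowSums(q^2))
    t_obs <- ax_stat(u, which(cer1))
    subsets <- combn(n, m)
    t_all <- apply(subsets, 2, function(ix) ax_stat(u, ix))
    p_exact <- mean(t_all >= t_obs - 1e-12)
    expect_lt(abs(p_mc - p_exact), 0.02)
  }
})

test_that("pooled profiles add counts and flag biased embryos", {
  g1 <- simulate_geometry(geometry_params(n_hypoblast = 30, marker_fraction = 0.4,
                                          concentration_kappa = 0, seed = 41,
                                          embryo_id = "e1"))
  g2 <- simulate_geometry(geometry_params(n_hypoblast = 30, marker_fraction = 0.4,
                                          concentration_kappa = 6, seed = 42,
                                          embryo_id = "e2"))
  p1 <- angular_profile(g1, n_perm = 500, seed = 1)
  p2 <- angular_profile(g2, n_perm = 500, seed = 2)
  pooled <- align_profiles(list(p1, p2))
  expect_identical(pooled$pooled_counts, p1$bin_counts + p2$bin_counts)
  expect_equal(sum(pooled$pooled_counts),
               p1$n_marker_pos + p2$n_marker_pos)
  expect_identical(pooled$table$embryo_id, c("e1", "e2"))
  expect_true(pooled$table$biased[2])   # strongly concentrated embryo
  bad <- p2; bad$bin_edges <- seq(0, 180, 20)
  expect_error(align_profiles(list(p1, bad)), "mismatched")
})

test_that("marker fractions are exact count ratios", {
  hyp <- matrix(rnorm(60, sd = 10), ncol = 3)
  g <- handmade_geometry(hyp, cer1 = rep(c(TRUE, FALSE), c(5, 15)))
  expect_equal(marker_fraction(g), 0.25)
  g_epi_only <- g[g$lineage == "EPI", ]
  class(g_epi_only) <- class(g)
  expect_true(is.na(marker_fraction(g_epi_only)))
})

test_that("marker-to-domain distances obey isometry and detect anti-correlation", {
  one <- handmade_geometry(matrix(c(0, 0, 10), 1), cer1 = TRUE)
  one$pSMAD15[1] <- TRUE   # single epiblast cell at (0,0,-10): distance 20
  md <- marker_domain_distance(one)
  expect_equal(md$dist_pos[1], 20)
  # rigid rotation invariance
  g <- simulate_geometry(geometry_params(n_hypoblast = 40, n_epiblast = 40,
                                         marker_fraction = 0.3,
                                         concentration_kappa = 4, seed = 55))
  md1 <- marker_domain_distance(g)
  g2 <- apply_rigid(g, random_rigid(6))
  md2 <- marker_domain_distance(g2)
  expect_equal(sort(md2$dist_pos), sort(md1$dist_pos), tolerance = 1e-9)
  # planted anti-correlated geometry: pSMAD+ epiblast opposite the CER1 domain
  epi_n <- 40
  theta <- seq(0, 2 * pi, length.out = epi_n + 1)[-1]
  epi <- cbind(8 * cos(theta), 8 * sin(theta), -10)
  hyp <- rbind(matrix(rep(c(10, 0, 2), each = 10), ncol = 3) + rnorm(30, sd = .2),
               matrix(rep(c(-10, 0, 2), each = 10), ncol = 3) + rnorm(30, sd = .2))
  gg <- embryo_geometry(data.frame(
    cell_id = sprintf("c%03d", 1:(epi_n + 20)),
    x_um = c(epi[, 1], hyp[, 1]), y_um = c(epi[, 2], hyp[, 2]),
    z_um = c(epi[, 3], hyp[, 3]),
    lineage = rep(c("EPI", "HYP"), c(epi_n, 20)),
    CER1 = rep(c(FALSE, TRUE, FALSE), c(epi_n, 10, 10)),
    GATA6 = rep(c(FALSE, TRUE), c(epi_n, 20)),
    OCT4 = rep(c(TRUE, FALSE), c(epi_n, 20)),
    LEFTY1 = FALSE,
    pSMAD15 = c(epi[, 1] < -4, rep(FALSE, 20))))  # pSMAD on the far side
  md3 <- marker_domain_distance(gg)
  expect_gt(md3$median_pos, md3$median_neg)
  expect_lt(md3$p_value, 0.05)
})
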