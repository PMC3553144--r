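test_that("Kabsch superposition removes rigid transforms exactly", {
  set.seed(121)
  X <- matrix(rnorm(60, sd = 6), 20, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  fit <- kabsch_superpose(X %*% t(R) + 4, X)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  fit2 <- kabsch_superpose(X + 5, X)
  expect_lt(fit2$rmsd, 1e-10)

  expect_error(kabsch_superpose(X, X, mask = c(TRUE, TRUE,
                                               rep(FALSE, 18))),
               "at least 3")
})

test_that("fitted RMSD is no worse than a coarse rotation grid search", {
  set.seed(122)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  B <- matrix(rnorm(30, sd = 5), 10, 3)
  fit <- kabsch_superpose(A, B)
  ctrA <- sweep(A, 2, colMeans(A)); ctrB <- sweep(B, 2, colMeans(B))
  grid_best <- min(replicate(200, {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    sqrt(mean(rowSums((ctrA %*% t(R) - ctrB)^2)))
  }))
  expect_lte(fit$rmsd, grid_best + 1e-9)
})

test_that("ensemble building matches residues and applies coverage/occupancy rules", {
  ank <- make_ankyrin_calpha(2, seed = 7)
  copies <- lapply(1:5, function(i) {
    s <- ank; s$id <- paste0("c", i); s
  })
  ens <- build_ensemble(copies)
  expect_equal(dim(ens$coords)[1], 5)
  expect_true(all(ens$mask))

  # one member missing 20% of positions: with 2 members occupancy drops to
  # 0.5 < 0.9 at those positions, so they are dropped ensemble-wide
  n <- nrow(ank$coords)
  short <- ca_structure("short", ank$coords[1:round(0.8 * n), , drop = FALSE],
                        sequence = substr(ank$sequence, 1, round(0.8 * n)))
  ens2 <- build_ensemble(list(copies[[1]], short), reference = copies[[1]])
  expect_equal(dim(ens2$coords)[2], round(0.8 * n))
  # with 10 full members the same position reaches 10/11 > 0.9 and is kept
  ens3 <- build_ensemble(c(lapply(1:10, function(i) copies[[1]]),
                           list(short)), reference = copies[[1]])
  expect_equal(dim(ens3$coords)[2], n)
  expect_false(all(ens3$mask[11, ]))

  # a structure matching under 40% of the reference is excluded and logged
  tiny <- ca_structure("tiny", ank$coords[1:15, ],
                       sequence = substr(ank$sequence, 1, 15))
  ens4 <- build_ensemble(c(copies, list(tiny)))
  expect_equal(dim(ens4$coords)[1], 5)
  expect_false(ens4$log$included[ens4$log$id == "tiny"])
})

test_that("NMR multi-model files contribute one conformer per model", {
  ank <- make_ankyrin_calpha(1, seed = 8)
  f_nmr <- tempfile(fileext = ".pdb"); f_x <- tempfile(fileext = ".pdb")
  m2 <- ank; m2$coords <- ank$coords + 0.5
  write_pdb_calpha(list(ank, m2), f_nmr)
  write_pdb_calpha(ank, f_x)
  structures <- c(read_pdb_calpha(f_nmr), read_pdb_calpha(f_x))
  ens <- build_ensemble(structures)
  expect_equal(dim(ens$coords)[1], 3)
})

test_that("iterative superposition converges and removes pure rigid motion", {
  ank <- make_ankyrin_calpha(2, seed = 9)
  copies <- lapply(1:4, function(i) { s <- ank; s$id <- paste0("c", i); s })
  ens <- iterative_superposition(build_ensemble(copies))
  expect_equal(length(ens$trace), 1)   # identical conformers: one pass
  expect_lt(max(ens$rmsd_to_mean), 1e-10)

  me <- make_ensemble(ank, variances = 1e-12, M = 15, noise_sd = 0,
                      seed = 10)  # rigid transforms only
  ens2 <- iterative_superposition(me$ensemble)
  expect_lt(max(ens2$rmsd_to_mean), 1e-6)

  me3 <- make_ensemble(ank, variances = 2, M = 30, seed = 11)
  ens3 <- iterative_superposition(me3$ensemble)
  expect_true(all(diff(ens3$trace) <= 1e-9))  # non-increasing total rmsd
})

test_that("ensemble PCA recovers planted structure and satisfies invariants", {
  ank <- make_ankyrin_calpha(2, seed = 12)
  me <- make_ensemble(ank, variances = 1, M = 100, seed = 13)
  expect_error(ensemble_pca(
    make_ensemble(ank, variances = 1, M = 2, seed = 1)$ensemble),
    "at least 3")
  pca <- ensemble_pca(iterative_superposition(me$ensemble))
  expect_gt(abs(sum(pca$vectors[, 1] * me$truth$directions[1, ])), 0.99)
  expect_equal(sum(pca$fractions), 1)
  expect_lt(max(abs(crossprod(pca$vectors) - diag(ncol(pca$vectors)))), 1e-8)
  expect_lt(abs(cor(pca$projections[, 1], pca$projections[, 2])), 0.1)
})

test_that("planted orthogonal subspace is recovered by the top PCs", {
  ank <- make_ankyrin_calpha(1, seed = 14)
  me <- make_ensemble(ank, variances = c(4, 1), M = 500, seed = 15)
  pca <- ensemble_pca(iterative_superposition(me$ensemble))
  Wt <- t(me$truth$directions)                    # 3N x 2 planted basis
  V <- pca$vectors[, 1:2]
  # principal angles between the two 2-d subspaces below 5 degrees
  sv <- svd(crossprod(Wt, V))$d
  expect_true(all(acos(pmin(sv, 1)) < 5 * pi / 180))
})

test_that("mode overlap: identity on itself, zero on orthogonal, complete basis", {
  ank <- make_ankyrin_calpha(1, seed = 16)
  modes <- anm_modes(build_hessian(ank))
  me <- make_ensemble(ank, directions = t(modes$vectors[, 1:2]),
                      variances = c(4, 1), M = 120, seed = 17)
  pca <- ensemble_pca(iterative_superposition(me$ensemble))
  ov <- mode_overlap(pca, modes, n_pc = 2, n_anm = 2)
  expect_gt(ov$overlap["PC1", "ANM1"], 0.9)
  expect_gt(ov$overlap["PC2", "ANM2"], 0.9)
  expect_lt(ov$overlap["PC1", "ANM2"], 0.3)
  expect_true(all(ov$overlap >= 0 & ov$overlap <= 1 + 1e-12))
  expect_gt(ov$projection_r["PC1", "ANM1"], 0.9)

  # complete-basis check: squared overlaps of each PC against the full ANM
  # basis (rigid block included) sum to one
  U <- cbind(modes$vectors, modes$rigid_vectors)
  V <- pca$vectors
  s2 <- rowSums(crossprod(V, U)^2)
  expect_true(all(abs(s2 - 1) < 1e-8))

  small <- anm_modes(build_hessian(make_ankyrin_calpha(2, seed = 1)))
  expect_error(mode_overlap(pca, small), "dimension mismatch")
})

test_that("PC-space clustering separates planted displacement regimes", {
  ank <- make_ankyrin_calpha(1, seed = 18)
  w <- ankevol:::rigid_basis(ank$coords)   # any orthonormal scaffold
  set.seed(19)
  v <- rnorm(3 * nrow(ank$coords)); v <- v - w %*% crossprod(w, v)
  v <- v / sqrt(sum(v^2))
  shift <- matrix(8 * v, nrow(ank$coords), 3, byrow = TRUE)
  g1 <- lapply(1:6, function(i) ca_structure(paste0("g1_", i),
    ank$coords + matrix(rnorm(length(ank$coords), 0, 0.1),
                        nrow(ank$coords), 3), sequence = ank$sequence))
  g2 <- lapply(1:6, function(i) ca_structure(paste0("g2_", i),
    ank$coords + shift + matrix(rnorm(length(ank$coords), 0, 0.1),
                                nrow(ank$coords), 3),
    sequence = ank$sequence))
  ens <- iterative_superposition(build_ensemble(c(g1, g2)))
  pca <- ensemble_pca(ens)
  labels <- rep(c("A", "B"), each = 6)
  cl <- pc_cluster(pca, labels)
  expect_gt(cl$separation, 0)
  expect_equal(nrow(cl$summary), 2)

  # label permutation relabels, geometry unchanged
  cl2 <- pc_cluster(pca, rev(labels))
  expect_equal(sort(cl$summary$spread), sort(cl2$summary$spread),
               tolerance = 1e-12)

  # identical conformers: zero spread
  same <- lapply(1:4, function(i) ca_structure(paste0("s", i), ank$coords,
                                               sequence = ank$sequence))
  pca0 <- ensemble_pca(iterative_superposition(build_ensemble(same)))
  cl0 <- pc_cluster(pca0, c("A", "A", "B", "B"))
  expect_equal(max(cl0$summary$spread), 0, tolerance = 1e-10)
})
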