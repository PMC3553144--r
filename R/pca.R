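#' Principal component analysis of a conformer ensemble
#'
#' Eigendecomposition of the covariance (divisor M - 1) of the flattened
#' 3N coordinate deviations across superposed conformers. Masked positions
#' are imputed from the ensemble mean, so they contribute no variance.
#'
#' @param ens a superposed `ca_ensemble` (run [iterative_superposition()]
#'   first; if `mean_coords` is absent it is computed here).
#' @return object of class `pca_result`: `mean_coords` (N x 3),
#'   `vectors` (3N x K orthonormal, descending variance), `values`
#'   (eigenvalues >= 0), `fractions` (`values / sum`), `projections`
#'   (M x K), `deviations` (M x 3N), `n_atoms`, `source = "pca"`.
#' @export
ensemble_pca <- function(ens) {
  stopifnot(inherits(ens, "ca_ensemble"))
  M <- dim(ens$coords)[1]
  if (M < 3L) stop("ensemble PCA needs at least 3 conformers (got ", M, ")")
  N <- dim(ens$coords)[2]
  mean_xyz <- if (!is.null(ens$mean_coords)) ens$mean_coords
  else masked_mean(ens$coords, ens$mask)
  X <- matrix(0, M, 3 * N)
  for (m in seq_len(M)) {
    xyz <- ens$coords[m, , ]
    miss <- !ens$mask[m, ]
    if (any(miss)) xyz[miss, ] <- mean_xyz[miss, ]  # imputed: zero deviation
    X[m, ] <- as.numeric(t(xyz - mean_xyz))
  }
  C <- crossprod(X) / (M - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(M - 1, 3 * N)
  structure(list(mean_coords = mean_xyz,
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 values = vals[seq_len(k)],
                 fractions = if (sum(vals) > 0) vals / sum(vals)
                 else rep(0, length(vals)),
                 projections = X %*% e$vectors[, seq_len(k), drop = FALSE],
                 deviations = X, n_atoms = N, source = "pca",
                 labels = ens$labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d conformers, top fractions: %s\n",
              nrow(x$projections),
              paste(sprintf("%.2f", utils::head(x$fractions, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Overlap between PCA directions and ANM modes
#'
#' `overlap[i, j] = |v_i . u_j|` with both vectors unit-normalized: the
#' absolute cosine between the i-th principal component and the j-th ANM
#' mode (eigenvector sign is arbitrary). `projection_r[i, j]` is the Pearson
#' correlation across conformers between their scores on the PC axis and on
#' the ANM mode axis.
#'
#' @param pca a `pca_result`.
#' @param modes a `mode_set` from [anm_modes()] on the same residue set.
#' @param n_pc,n_anm how many leading directions to compare (default 3).
#' @return object of class `overlap_report`: matrices `overlap` and
#'   `projection_r` (PCs in rows, ANM modes in columns) and `pc_fractions`.
#' @export
mode_overlap <- function(pca, modes, n_pc = 3, n_anm = 3) {
  stopifnot(inherits(pca, "pca_result"), inherits(modes, "mode_set"))
  if (nrow(pca$vectors) != nrow(modes$vectors))
    stop("dimension mismatch: PCA on 3N = ", nrow(pca$vectors),
         ", ANM on 3N = ", nrow(modes$vectors))
  n_pc <- min(n_pc, ncol(pca$vectors))
  n_anm <- min(n_anm, ncol(modes$vectors))
  V <- pca$vectors[, seq_len(n_pc), drop = FALSE]
  U <- modes$vectors[, seq_len(n_anm), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  U <- sweep(U, 2, sqrt(colSums(U^2)), `/`)
  ov <- abs(crossprod(V, U))
  pr <- matrix(NA_real_, n_pc, n_anm)
  sc_pc <- pca$deviations %*% V
  sc_anm <- pca$deviations %*% U
  for (i in seq_len(n_pc)) for (j in seq_len(n_anm)) {
    if (sd(sc_pc[, i]) > 1e-12 && sd(sc_anm[, j]) > 1e-12)
      pr[i, j] <- abs(cor(sc_pc[, i], sc_anm[, j]))
  }
  dimnames(ov) <- dimnames(pr) <-
    list(paste0("PC", seq_len(n_pc)), paste0("ANM", seq_len(n_anm)))
  structure(list(overlap = ov, projection_r = pr,
                 pc_fractions = pca$fractions[seq_len(n_pc)]),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> |cosine| overlap:\n")
  print(round(x$overlap, 3))
  invisible(x)
}

#' Cluster summary of conformers in PC1/PC2 space
#'
#' Per-group centroid and spread in the (PC1, PC2) plane plus a mean
#' silhouette separation score (1 = well separated, <= 0 = overlapping).
#'
#' @param pca a `pca_result`.
#' @param labels character vector of group labels per conformer (or named by
#'   conformer label).
#' @return list with `summary` data.frame (group, n, pc1, pc2, spread) and
#'   `separation` (mean silhouette over conformers; `NA` with < 2 groups).
#' @export
pc_cluster <- function(pca, labels) {
  stopifnot(inherits(pca, "pca_result"))
  M <- nrow(pca$projections)
  if (!is.null(names(labels))) labels <- labels[pca$labels]
  labels <- as.character(labels)
  stopifnot(length(labels) == M)
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  xy <- pca$projections[, 1:2, drop = FALSE]
  groups <- split(seq_len(M), labels)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    ctr <- colMeans(xy[i, , drop = FALSE])
    data.frame(group = g, n = length(i), pc1 = ctr[1], pc2 = ctr[2],
               spread = sqrt(mean(rowSums(
                 sweep(xy[i, , drop = FALSE], 2, ctr)^2))),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  dmat <- as.matrix(dist(xy))
  sil <- vapply(seq_len(M), function(i) {
    own <- setdiff(groups[[labels[i]]], i)
    a <- if (length(own)) mean(dmat[i, own]) else 0
    b <- min(vapply(setdiff(names(groups), labels[i]), function(g)
      mean(dmat[i, groups[[g]]]), 0))
    if (max(a, b) < 1e-12) 0 else (b - a) / max(a, b)
  }, 0)
  list(summary = summary, separation = mean(sil))
}
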