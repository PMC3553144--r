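#' Build the anisotropic network model Hessian
#'
#' Every pair of C-alpha nodes at distance `<= r_c` is connected by a
#' harmonic spring of uniform constant `gamma`. The off-diagonal 3x3
#' superblock for a connected pair (i, j) is
#' `-(gamma / r_ij^2) * (r_ij %o% r_ij)` with `r_ij` the equilibrium
#' inter-residue vector; diagonal superblocks enforce the zero-row-sum
#' contract, so the matrix is symmetric positive semidefinite with the six
#' rigid-body motions in its null space.
#'
#' @param structure a [ca_structure()] or an N x 3 coordinate matrix.
#' @param r_c distance cutoff in Angstrom (default 15).
#' @param gamma spring constant (default 1, arbitrary units; only relative
#'   fluctuations are used downstream).
#' @return object of class `anm_hessian`: list with `coords`, `r_c`,
#'   `gamma`, `H` (3N x 3N) and `connected` flag.
#' @export
build_hessian <- function(structure, r_c = 15, gamma = 1) {
  coords <- if (inherits(structure, "ca_structure")) structure$coords
  else as.matrix(structure)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 residues")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  dm <- as.matrix(dist(coords))
  if (any(dm[upper.tri(dm)] < 1e-9))
    stop("duplicate coordinates (zero inter-residue distance)")
  adj <- dm <= r_c
  diag(adj) <- FALSE
  connected <- network_connected(adj)
  if (!connected)
    warning("contact network is disconnected at r_c = ", r_c,
            "; more than 6 zero modes expected")
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rij <- coords[j, ] - coords[i, ]
    blk <- -(gamma / sum(rij^2)) * tcrossprod(rij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  structure(list(coords = coords, r_c = r_c, gamma = gamma, H = H,
                 connected = connected), class = "anm_hessian")
}

network_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(lapply(queue, function(i) which(adj[i, ] & !seen))))
    seen[nxt] <- TRUE
    queue <- nxt
  }
  all(seen)
}

#' Normal modes of an ANM Hessian
#'
#' Full symmetric eigendecomposition. Eigenvalues below
#' `tol * max(eigenvalue)` are classified as rigid-body modes; a connected
#' network must yield exactly six. The remaining `3N - 6` modes are returned
#' in ascending eigenvalue order with fractional contributions proportional
#' to `1 / eigenvalue` (the weight of each mode in the fluctuations).
#'
#' @param model an `anm_hessian` from [build_hessian()].
#' @param tol relative rigid-mode tolerance (default 1e-8).
#' @return object of class `mode_set`: list with `values` (ascending),
#'   `vectors` (3N x n_modes, orthonormal), `fractions`, `rigid_vectors`,
#'   `n_atoms`, `source = "anm"`.
#' @export
anm_modes <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "anm_hessian"))
  e <- eigen(model$H, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  thr <- tol * max(vals)
  rigid <- vals < thr
  n_rigid <- sum(rigid)
  if (n_rigid > 6L && model$connected)
    stop("internal consistency error: ", n_rigid,
         " near-zero modes on a connected network")
  if (n_rigid < 6L)
    stop("internal consistency error: only ", n_rigid, " near-zero modes")
  w <- 1 / vals[!rigid]
  structure(list(values = vals[!rigid],
                 vectors = vecs[, !rigid, drop = FALSE],
                 fractions = w / sum(w),
                 rigid_vectors = vecs[, rigid, drop = FALSE],
                 n_rigid = n_rigid,
                 n_atoms = nrow(model$coords), source = "anm"),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %s: %d modes over %d atoms (leading fraction %.2f)\n",
              x$source, length(x$values), x$n_atoms, x$fractions[1]))
  invisible(x)
}

#' Per-residue mean-square fluctuations from ANM modes
#'
#' `msf_i = sum_k |U_k(i)|^2 / lambda_k` over the non-rigid modes (or a
#' subset), i.e. the trace of the i-th 3x3 diagonal superblock of the
#' Hessian pseudo-inverse when all modes are used. Units are kT/gamma times
#' Angstrom^2; only relative values are meaningful.
#'
#' @param modes a `mode_set` from [anm_modes()].
#' @param mode_subset optional integer indices into the non-rigid modes
#'   (1 = lowest-frequency). Indices outside `1..n_modes` (i.e. rigid or
#'   absent modes) are an error.
#' @return object of class `fluct_profile`: list with `msf`,
#'   `b_theoretical` (`NULL` until [bfactor_compare()]), `pearson_r`.
#' @export
mean_square_fluctuation <- function(modes, mode_subset = NULL) {
  stopifnot(inherits(modes, "mode_set"), modes$source == "anm")
  k <- length(modes$values)
  if (is.null(mode_subset)) mode_subset <- seq_len(k)
  if (any(mode_subset < 1L) || any(mode_subset > k))
    stop("mode subset must index non-rigid modes in 1..", k)
  U <- modes$vectors[, mode_subset, drop = FALSE]
  lam <- modes$values[mode_subset]
  n <- modes$n_atoms
  contrib <- U^2 %*% (1 / lam)
  msf <- rowSums(matrix(contrib, nrow = n, byrow = TRUE))
  structure(list(msf = as.numeric(msf), b_theoretical = NULL,
                 pearson_r = NA_real_, modes_used = mode_subset),
            class = "fluct_profile")
}

#' Compare theoretical and experimental B-factors
#'
#' Scales `(8 * pi^2 / 3) * msf` onto the experimental B-factor column by
#' least squares and records the Pearson correlation.
#'
#' @param profile a `fluct_profile` from [mean_square_fluctuation()].
#' @param structure a [ca_structure()] carrying experimental B-factors.
#' @return the profile with `b_theoretical`, `pearson_r` and a per-residue
#'   `table` (data.frame residue, msf, b_theoretical, b_experimental).
#' @export
bfactor_compare <- function(profile, structure) {
  stopifnot(inherits(profile, "fluct_profile"),
            inherits(structure, "ca_structure"))
  bexp <- structure$bfactors
  if (is.null(bexp)) stop("structure carries no experimental B-factors")
  if (length(bexp) != length(profile$msf))
    stop("profile and structure differ in residue count")
  braw <- (8 * pi^2 / 3) * profile$msf
  if (sd(bexp) < 1e-12) {
    profile$pearson_r <- NA_real_
    profile$b_theoretical <- braw
    warning("experimental B-factor column is constant; correlation undefined")
  } else {
    fit <- lm(bexp ~ braw)
    profile$b_theoretical <- as.numeric(fitted(fit))
    profile$pearson_r <- cor(braw, bexp)
  }
  profile$table <- data.frame(residue = seq_along(braw),
                              msf = profile$msf,
                              b_theoretical = profile$b_theoretical,
                              b_experimental = bexp)
  profile
}
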