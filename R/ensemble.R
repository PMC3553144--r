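#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `target` over the
#' unmasked positions, with the SVD sign correction that guarantees a proper
#' rotation (det = +1).
#'
#' @param mobile,target N x 3 coordinate matrices.
#' @param mask optional logical vector; `TRUE` positions enter the fit (all
#'   positions are transformed). At least 3 unmasked positions are required.
#' @return list with `coords` (transformed mobile), `rmsd` (over unmasked
#'   positions), `rotation`, `translation`.
#' @export
kabsch_superpose <- function(mobile, target, mask = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  if (is.null(mask)) mask <- rep(TRUE, nrow(mobile))
  if (sum(mask) < 3L) stop("need at least 3 shared positions to superpose")
  mm <- mobile[mask, , drop = FALSE]; tt <- target[mask, , drop = FALSE]
  cm <- colMeans(mm); ct <- colMeans(tt)
  A <- crossprod(sweep(mm, 2, cm), sweep(tt, 2, ct))
  sv <- svd(A)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  moved <- sweep(mobile, 2, cm) %*% t(R)
  moved <- sweep(moved, 2, ct, `+`)
  rmsd <- sqrt(mean(rowSums((moved[mask, , drop = FALSE] - tt)^2)))
  list(coords = moved, rmsd = rmsd, rotation = R,
       translation = ct - as.numeric(R %*% cm))
}

new_ensemble <- function(reference, coords, mask, labels, log = NULL) {
  structure(list(reference = reference, coords = coords, mask = mask,
                 labels = labels, log = log), class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("<ca_ensemble> %d conformers x %d positions (occupancy %.2f)\n",
              dim(x$coords)[1], dim(x$coords)[2], mean(x$mask)))
  invisible(x)
}

#' Build a matched conformer ensemble on a reference residue set
#'
#' Each structure is matched to the reference by global sequence alignment
#' ([global_align()]); aligned residue pairs define its coordinates on the
#' reference frame, missing reference positions are masked. Structures
#' matching fewer than `min_coverage` of the reference positions are
#' excluded (logged). Reference positions observed in fewer than
#' `min_occupancy` of the retained members are dropped ensemble-wide.
#'
#' @param structures list of [ca_structure()] (each NMR model is its own
#'   conformer).
#' @param reference a [ca_structure()]; defaults to the first structure.
#' @param min_occupancy minimum fraction of members observing a retained
#'   reference position (default 0.9).
#' @param min_coverage minimum fraction of reference positions a member must
#'   match (default 0.4).
#' @return a `ca_ensemble`: conformer coordinate array `coords`
#'   (M x N x 3), logical occupancy `mask` (M x N), `reference`, `labels`,
#'   exclusion `log`.
#' @export
build_ensemble <- function(structures, reference = NULL, min_occupancy = 0.9,
                           min_coverage = 0.4) {
  if (inherits(structures, "ca_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 2L)
  if (is.null(reference)) reference <- structures[[1]]
  nref <- nrow(reference$coords)
  rows <- list(); masks <- list(); labels <- character(0)
  log <- data.frame(id = character(0), coverage = numeric(0),
                    included = logical(0), stringsAsFactors = FALSE)
  for (s in structures) {
    if (identical(s$sequence, reference$sequence) &&
        nrow(s$coords) == nref) {
      map_ref <- seq_len(nref); map_mem <- seq_len(nref)
    } else {
      al <- global_align(seq_record(s$id, s$sequence),
                         seq_record(reference$id, reference$sequence))
      am <- strsplit(al$aligned_a, "")[[1]]
      ar <- strsplit(al$aligned_b, "")[[1]]
      pm <- cumsum(am != "-"); pr <- cumsum(ar != "-")
      both <- am != "-" & ar != "-"
      map_ref <- pr[both]; map_mem <- pm[both]
    }
    cov <- length(map_ref) / nref
    log <- rbind(log, data.frame(id = s$id, coverage = cov,
                                 included = cov >= min_coverage,
                                 stringsAsFactors = FALSE))
    if (cov < min_coverage) next
    xyz <- matrix(NA_real_, nref, 3)
    xyz[map_ref, ] <- s$coords[map_mem, , drop = FALSE]
    rows[[length(rows) + 1L]] <- xyz
    masks[[length(masks) + 1L]] <- !is.na(xyz[, 1])
    labels <- c(labels, s$id)
  }
  if (length(rows) < 2L) stop("fewer than 2 structures matched the reference")
  M <- length(rows)
  mask <- do.call(rbind, masks)
  keep <- colMeans(mask) >= min_occupancy
  if (!any(keep)) stop("no reference position reaches the occupancy threshold")
  coords <- array(NA_real_, dim = c(M, sum(keep), 3))
  for (m in seq_len(M)) coords[m, , ] <- rows[[m]][keep, ]
  ref2 <- reference
  ref2$coords <- reference$coords[keep, , drop = FALSE]
  ref2$residue_ids <- reference$residue_ids[keep, , drop = FALSE]
  ref2$sequence <- paste(strsplit(reference$sequence, "")[[1]][keep],
                         collapse = "")
  if (!is.null(reference$bfactors)) ref2$bfactors <- reference$bfactors[keep]
  new_ensemble(ref2, coords, mask[, keep, drop = FALSE], labels, log)
}

#' Iterative superposition of an ensemble onto its mean
#'
#' Repeats superpose-all-members-onto-the-mean / recompute-the-mean until
#' the mean structure moves less than `tol` (RMSD) or `max_iter` is reached.
#' Records per-member RMSD to the converged mean and the total-RMSD trace.
#'
#' @param ens a `ca_ensemble`.
#' @param tol convergence tolerance on the mean shift in Angstrom
#'   (default 1e-5).
#' @param max_iter maximum iterations (default 100).
#' @return the ensemble with superposed `coords`, `mean_coords`,
#'   `rmsd_to_mean` (per member) and `trace` (total rmsd per iteration).
#' @export
iterative_superposition <- function(ens, tol = 1e-5, max_iter = 100) {
  stopifnot(inherits(ens, "ca_ensemble"))
  M <- dim(ens$coords)[1]
  coords <- ens$coords
  # anchor the first fit on the reference frame: averaging members that
  # carry arbitrary rigid transforms would give a meaningless start mean
  mean_xyz <- ens$reference$coords
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rmsds <- numeric(M)
    for (m in seq_len(M)) {
      fit <- kabsch_superpose(coords[m, , ], mean_xyz, ens$mask[m, ])
      coords[m, , ] <- fit$coords
      rmsds[m] <- fit$rmsd
    }
    new_mean <- masked_mean(coords, ens$mask)
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    trace <- c(trace, sqrt(mean(rmsds^2)))
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative superposition did not converge in ", max_iter,
            " iterations; returning last iterate")
  ens$coords <- coords
  ens$mean_coords <- mean_xyz
  ens$rmsd_to_mean <- vapply(seq_len(M), function(m)
    kabsch_superpose(coords[m, , ], mean_xyz, ens$mask[m, ])$rmsd, 0)
  ens$trace <- trace
  ens
}

masked_mean <- function(coords, mask) {
  N <- dim(coords)[2]
  out <- matrix(0, N, 3)
  for (j in seq_len(N)) {
    rows <- mask[, j]
    out[j, ] <- colMeans(coords[rows, j, , drop = FALSE])
  }
  out
}
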