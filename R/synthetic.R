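# circular-arc interpolation: n points between P and Q, consecutive chord
# `step`, bulging towards `out` (must not be parallel to Q - P)
arc_points <- function(P, Q, n, out, step = 3.8) {
  c0 <- sqrt(sum((Q - P)^2))
  m <- n + 1
  if (c0 >= step * m) stop("endpoints too far apart for ", n, " arc points")
  f <- function(phi) sin(phi) / sin(phi / m) - c0 / step
  phi <- uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root
  R <- c0 / (2 * sin(phi))
  e1 <- (Q - P) / c0
  e2 <- out - sum(out * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  h <- R * cos(phi)  # signed: centre crosses to the bulge side when phi > pi/2
  O <- (P + Q) / 2 - h * e2
  # sweep the arc of angle 2*phi that passes through the +e2 (bulge) side
  th <- (pi / 2 + phi) - 2 * phi * seq_len(n) / m
  t(vapply(th, function(a) O + R * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

#' Ideal-geometry ankyrin-like C-alpha chain
#'
#' Builds a synthetic stack of ankyrin-type repeats: each repeat is two
#' antiparallel helical segments (rise 1.5 A/residue, 100 degrees/residue,
#' radius 2.3 A) joined by a short hairpin turn, followed by a projecting
#' loop that connects to the next repeat in the stack (inter-repeat
#' translation 10 A). Consecutive C-alpha atoms sit ~3.8 A apart, so the
#' chain is connected at the 15 A ANM cutoff. A small seeded jitter
#' (sd 0.05 A) breaks exact symmetry. The default 33 residues per repeat
#' split as 11 + 3 + 11 + 8 (helix, turn, helix, loop).
#'
#' @param n_repeats number of repeats (>= 1).
#' @param residues_per_repeat residues per repeat (>= 29; default 33).
#' @param seed integer seed for the jitter and the random sequence.
#' @return a [ca_structure()] of `n_repeats * residues_per_repeat` residues.
#' @export
make_ankyrin_calpha <- function(n_repeats, residues_per_repeat = 33,
                                seed = 1) {
  stopifnot(n_repeats >= 1, residues_per_repeat >= 29)
  n_loop <- residues_per_repeat - 25L
  hr <- sqrt(3.8^2 - 1.5^2) / (2 * sin(50 * pi / 180))  # helix radius: 3.8 A chord
  helix <- function(x0, z0, y0, dir) {
    i <- 0:10
    ang <- (100 * pi / 180) * i + if (dir < 0) pi else 0
    cbind(x0 + hr * cos(ang), y0 + dir * 1.5 * i, z0 + hr * sin(ang))
  }
  coords <- NULL
  for (r in seq_len(n_repeats)) {
    zr <- 10 * (r - 1)
    hA <- helix(0, zr, 0, +1)
    hB <- helix(9, zr, 15, -1)
    turn <- arc_points(hA[11, ], hB[1, ], 3, c(0, 1, 0))
    nxtA <- helix(0, zr + 10, 0, +1)
    loop_pts <- arc_points(hB[11, ], nxtA[1, ], n_loop, c(0, -1, 0))
    coords <- rbind(coords, hA, turn, hB, loop_pts)
  }
  local_seed(seed, {
    coords <- coords + matrix(rnorm(length(coords), 0, 0.03),
                              nrow(coords), 3)
    seqn <- paste(sample(AA_STANDARD, nrow(coords), replace = TRUE),
                  collapse = "")
  })
  ca_structure(sprintf("synthetic_ankyrin_%dx%d", n_repeats,
                       residues_per_repeat),
               coords, sequence = seqn)
}

# orthonormal basis of the 6 rigid-body directions of a structure
rigid_basis <- function(coords) {
  n <- nrow(coords)
  ctr <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(apply(ctr, 1, function(x) crossprod_3(axes[k, ], x)))
    B[, 3 + k] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Synthetic conformer ensemble with planted deformation directions
#'
#' Members are `RigidTransform_m(base + sum_k z_mk w_k + eps)` with
#' `z_mk ~ N(0, variances[k])`, orthonormal internal directions `w_k`
#' (random directions have the six rigid-body components projected out) and
#' small isotropic noise `eps`. The ground truth (directions, variances) is
#' returned alongside, so principal-component recovery can be asserted.
#'
#' @param base a [ca_structure()].
#' @param directions q x 3N matrix of direction rows, or `"random"`.
#' @param variances length-q positive variances (A^2) of the planted modes.
#' @param M number of conformers.
#' @param rigid_noise apply a random rigid transform per member
#'   (default TRUE).
#' @param noise_sd isotropic per-coordinate noise sd (default 0.005 A; keep
#'   well below `sqrt(min(variances))` so the planted modes dominate the
#'   variance).
#' @param seed integer seed.
#' @return list with `ensemble` (a `ca_ensemble`, full occupancy) and
#'   `truth` (directions actually used, variances, seed).
#' @export
make_ensemble <- function(base, directions = "random", variances = 1,
                          M = 100, rigid_noise = TRUE, noise_sd = 0.005,
                          seed = 1) {
  stopifnot(inherits(base, "ca_structure"), all(variances > 0), M >= 2)
  n3 <- 3 * nrow(base$coords)
  q <- length(variances)
  if (q >= n3 - 6) stop("too many planted directions (q must be < 3N - 6)")
  rb <- rigid_basis(base$coords)
  local_seed(seed, {
    if (is.character(directions) && directions == "random") {
      W <- matrix(rnorm(n3 * q), n3, q)
    } else {
      W <- t(as.matrix(directions))
      if (ncol(W) != q || nrow(W) != n3)
        stop("directions must be q x 3N with q = length(variances)")
      G <- crossprod(W)
      if (max(abs(G - diag(q))) > 1e-6)
        warning("directions not orthonormal; re-orthonormalizing")
    }
    W <- W - rb %*% crossprod(rb, W)          # internal motions only
    W <- qr.Q(qr(W))[, seq_len(q), drop = FALSE]
    coords <- array(0, dim = c(M, nrow(base$coords), 3))
    z <- matrix(rnorm(M * q), M, q) %*% diag(sqrt(variances), q)
    for (m in seq_len(M)) {
      disp <- as.numeric(W %*% z[m, ]) + rnorm(n3, 0, noise_sd)
      xyz <- base$coords + matrix(disp, ncol = 3, byrow = TRUE)
      if (rigid_noise) {
        xyz <- xyz %*% t(random_rotation())
        xyz <- sweep(xyz, 2, runif(3, -20, 20), `+`)
      }
      coords[m, , ] <- xyz
    }
  })
  ens <- new_ensemble(base, coords,
                      matrix(TRUE, M, nrow(base$coords)),
                      sprintf("conf%03d", seq_len(M)))
  list(ensemble = ens,
       truth = list(directions = t(W), variances = variances, seed = seed))
}

#' Simulate a protein family on a known tree with planted rate shifts
#'
#' Sites draw a rate from a mean-1 gamma distribution (shape `alpha`).
#' With probability `theta` a site is rate-shifted: the subtree of
#' `clusterB` (stem edge included) evolves that site at an independently
#' drawn rate multiplied by `shift_factor`. Substitutions are Poisson along
#' each branch, each event replacing the state by one of the 19 alternatives
#' uniformly; the root sequence is uniform over the 20 residues.
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/site).
#' @param L alignment columns.
#' @param alpha gamma shape of among-site rates.
#' @param clusterB leaf set of the shifted clade (must be a clade; required
#'   when `theta > 0`).
#' @param theta planted fraction of rate-shifted sites.
#' @param shift_factor multiplier on the redrawn rate (default 1: pure rate
#'   decoupling).
#' @param seed integer seed.
#' @return list with `alignment` (an [msa()]) and `truth` (tree, theta,
#'   shifted site indices, alpha, shift_factor, seed).
#' @export
simulate_family <- function(tree, L, alpha = 0.5, clusterB = NULL,
                            theta = 0, shift_factor = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"), theta >= 0, theta <= 1, alpha > 0)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  if (theta > 0) {
    if (is.null(clusterB)) stop("clusterB required when theta > 0")
    check_clade(tree, clusterB, "clusterB")
  }
  nt <- ape::Ntip(tree)
  shifted_edges <- rep(FALSE, nrow(tree$edge))
  if (!is.null(clusterB) && length(clusterB)) {
    tr2 <- if (ape::is.rooted(tree)) tree else
      ape::root(tree, outgroup = setdiff(tree$tip.label, clusterB)[1],
                resolve.root = TRUE)
    # match edges by the tip set below them (robust to re-rooting)
    below <- function(tr, e) sort(tips_of_edge(tr, e))
    bset <- lapply(seq_len(nrow(tr2$edge)), function(e)
      paste(below(tr2, e), collapse = ","))
    inB <- vapply(seq_len(nrow(tr2$edge)), function(e)
      all(tips_of_edge(tr2, e) %in% clusterB), TRUE)
    want <- bset[inB]
    shifted_edges <- vapply(seq_len(nrow(tree$edge)), function(e)
      paste(sort(tips_of_edge(tree, e)), collapse = ",") %in% want, TRUE)
  }
  local_seed(seed, {
    shifted <- which(runif(L) < theta)
    lam <- rgamma(L, shape = alpha, rate = alpha)
    lamB <- rgamma(L, shape = alpha, rate = alpha) * shift_factor
    states <- matrix(0L, nt + tree$Nnode, L)
    root <- nt + 1L
    states[root, ] <- sample.int(20L, L, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      rate <- lam
      eidx <- which(tree$edge[, 1] == par & tree$edge[, 2] == ch)
      if (shifted_edges[eidx[1]] && length(shifted))
        rate[shifted] <- lamB[shifted]
      st <- states[par, ]
      nev <- rpois(L, rate * len)
      kmax <- if (length(nev)) max(nev) else 0L
      k <- 1L
      while (k <= kmax) {
        idx <- which(nev >= k)
        st[idx] <- ((st[idx] - 1L +
                       sample.int(19L, length(idx), replace = TRUE)) %% 20L) + 1L
        k <- k + 1L
      }
      states[ch, ] <- st
    }
    rows <- apply(states[seq_len(nt), , drop = FALSE], 1, function(s)
      paste(AA_STANDARD[s], collapse = ""))
  })
  names(rows) <- tree$tip.label
  list(alignment = msa(rows),
       truth = list(tree = tree, theta = theta, shifted_sites = shifted,
                    alpha = alpha, shift_factor = shift_factor, seed = seed))
}

tips_of_edge <- function(tree, e) {
  ch <- tree$edge[e, 2]
  nt <- ape::Ntip(tree)
  if (ch <= nt) tree$tip.label[ch] else tips_of(tree, ch)
}

codon_sim_tables <- function(kappa) {
  key <- paste0("codonsim_", kappa)
  if (!is.null(.ankevol_cache[[key]])) return(.ankevol_cache[[key]])
  cu <- codon_universe()
  sense <- setdiff(cu$codons, cu$stops)
  is_transition <- function(a, b) paste(sort(c(a, b)), collapse = "") %in%
    c("AG", "CT")
  nb <- lapply(sense, function(cd) {
    p <- strsplit(cd, "")[[1]]
    tg <- character(0); rt <- numeric(0); syn <- logical(0)
    for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), p[pos])) {
      alt <- p; alt[pos] <- nt
      alt <- paste(alt, collapse = "")
      if (alt %in% cu$stops) next
      tg <- c(tg, alt)
      rt <- c(rt, if (is_transition(p[pos], nt)) kappa else 1)
      syn <- c(syn, cu$code[[alt]] == cu$code[[cd]])
    }
    list(targets = match(tg, sense), rates = rt, syn = syn)
  })
  names(nb) <- sense
  # scale so a branch length of 1 is one expected substitution per codon
  # site under neutrality (omega = 1, uniform codon frequencies)
  mean_rate <- mean(vapply(nb, function(x) sum(x$rates), 0))
  for (i in seq_along(nb)) nb[[i]]$rates <- nb[[i]]$rates / mean_rate
  out <- list(sense = sense, nb = nb)
  .ankevol_cache[[key]] <- out
  out
}

#' Simulate a codon alignment with per-site omega on a known tree
#'
#' GY94-style continuous-time codon substitution with uniform codon
#' frequencies: single-nucleotide exchanges at rate `kappa` (transitions)
#' or 1 (transversions), multiplied by the site's `omega` for nonsynonymous
#' changes; stop codons are disallowed. Rates are scaled so one unit of
#' branch length is one expected substitution per codon site at
#' `omega = 1`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param L_codons number of codon sites.
#' @param omega_profile scalar or length-`L_codons` vector of omega >= 0.
#' @param kappa transition/transversion rate ratio (default 1, the neutral
#'   uniform model).
#' @param seed integer seed.
#' @return list with `alignment` (codon [msa()]) and `truth` (omega profile,
#'   kappa, tree, seed).
#' @export
simulate_codons <- function(tree, L_codons, omega_profile = 1, kappa = 1,
                            seed = 1) {
  stopifnot(inherits(tree, "phylo"), all(omega_profile >= 0))
  omega <- rep_len(omega_profile, L_codons)
  tb <- codon_sim_tables(kappa)
  ns <- length(tb$sense)
  nt <- ape::Ntip(tree)
  local_seed(seed, {
    states <- matrix(0L, nt + tree$Nnode, L_codons)
    states[nt + 1L, ] <- sample.int(ns, L_codons, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      st <- states[par, ]
      for (i in seq_len(L_codons)) {
        t <- 0; cur <- st[i]
        repeat {
          x <- tb$nb[[cur]]
          w <- x$rates * ifelse(x$syn, 1, omega[i])
          tot <- sum(w)
          if (tot <= 0) break
          t <- t + rexp(1, tot)
          if (t > len) break
          cur <- x$targets[sample.int(length(w), 1L, prob = w)]
        }
        st[i] <- cur
      }
      states[ch, ] <- st
    }
    rows <- apply(states[seq_len(nt), , drop = FALSE], 1, function(s)
      paste(tb$sense[s], collapse = ""))
  })
  names(rows) <- tree$tip.label
  list(alignment = msa(rows, codon = TRUE),
       truth = list(omega_profile = omega, kappa = kappa, tree = tree,
                    seed = seed))
}
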