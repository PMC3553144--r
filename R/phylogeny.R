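#' Jukes-Cantor protein distances with pairwise deletion
#'
#' For every sequence pair only columns where both rows carry a residue
#' (not gap, not `X`) are compared. The observed mismatch proportion `p` is
#' corrected with the 20-state Jukes-Cantor form
#' `d = -(19/20) * ln(1 - (20/19) * p)`. Pairs with `p >= 19/20` are
#' saturated: `d` is set to `ceiling` and flagged.
#'
#' @param aln an [msa()] alignment (>= 2 rows).
#' @param ceiling distance assigned to saturated pairs (default 5
#'   substitutions/site).
#' @return object of class `dist_jc`: list with `taxa`, `d` (symmetric
#'   matrix), `comparable_sites`, `saturated` (logical matrix).
#' @export
jc_distance <- function(aln, ceiling = 5) {
  m <- msa_matrix(aln)
  taxa <- rownames(m)
  n <- nrow(m)
  ok <- !(m == "-" | m == "X" | m == "?")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cs <- matrix(ncol(m), n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    nc <- sum(use)
    if (nc == 0L)
      stop("no comparable sites between '", taxa[i], "' and '", taxa[j], "'")
    p <- sum(m[i, use] != m[j, use]) / nc
    if (p >= 19 / 20) {
      d[i, j] <- d[j, i] <- ceiling
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- -(19 / 20) * log(1 - (20 / 19) * p)
    }
    cs[i, j] <- cs[j, i] <- nc
  }
  structure(list(taxa = taxa, d = d, comparable_sites = cs,
                 saturated = sat), class = "dist_jc")
}

#' @export
print.dist_jc <- function(x, ...) {
  cat(sprintf("<dist_jc> %d taxa, max distance %.3f%s\n", length(x$taxa),
              max(x$d), if (any(x$saturated)) " (saturated pairs present)" else ""))
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion.
#' Additive input distances are reproduced exactly by path lengths on the
#' output tree. Ties in Q are broken by the smallest (i, j) index pair;
#' negative branch lengths are clamped to zero with the deficit moved to the
#' sibling edge (the joined path length is preserved).
#'
#' @param D a `dist_jc` object, or a symmetric numeric matrix with taxon
#'   dimnames (>= 3 taxa, non-negative entries).
#' @return unrooted [ape::phylo] tree (basal trifurcation).
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "dist_jc")) D$d else as.matrix(D)
  taxa <- rownames(d)
  n <- nrow(d)
  if (is.null(taxa)) taxa <- colnames(d) <- rownames(d) <- paste0("t", 1:n)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  frag <- taxa  # newick fragment per active cluster
  repeat {
    n <- nrow(d)
    if (n == 3L) break
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], vi, frag[j], vj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- seq_len(nrow(d2))
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = nwk)
}

#' Root a tree on the edge subtending an outgroup
#'
#' The outgroup (single leaf or monophyletic leaf set in the unrooted tree)
#' defines the root edge, whose length is split 50/50 between the two basal
#' branches.
#'
#' @param tree an [ape::phylo] tree (rooted input is unrooted first).
#' @param outgroup character vector of leaf labels.
#' @return rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(outgroup %in% tips))
    stop("outgroup taxa not in tree: ",
         paste(setdiff(outgroup, tips), collapse = ", "))
  if (length(setdiff(tips, outgroup)) == 0L)
    stop("outgroup cannot contain all taxa")
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (length(outgroup) > 1L) {
    anchor <- setdiff(tips, outgroup)[1]
    tmp <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
    mrca <- ape::getMRCA(tmp, outgroup)
    clade_tips <- tips_of(tmp, mrca)
    if (!setequal(clade_tips, outgroup))
      stop("outgroup is not monophyletic; offending taxa: ",
           paste(setdiff(clade_tips, outgroup), collapse = ", "))
  }
  rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  rootnode <- ape::Ntip(rooted) + 1L
  ce <- which(rooted$edge[, 1] == rootnode)
  if (length(ce) == 2L) {
    tot <- sum(rooted$edge.length[ce])
    rooted$edge.length[ce] <- tot / 2
  }
  rooted
}

tips_of <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  desc <- node
  out <- integer(0)
  while (length(desc)) {
    ch <- tree$edge[tree$edge[, 1] %in% desc, 2]
    out <- c(out, ch[ch <= nt])
    desc <- ch[ch > nt]
  }
  tree$tip.label[out]
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement `replicates` times, rebuilds
#' the Jukes-Cantor + NJ tree per replicate, and attaches to every internal
#' node of the point-estimate tree the percentage of replicates containing
#' its bipartition. Replicates failing (e.g. a pair with no comparable
#' sites) are skipped and counted.
#'
#' @param aln an [msa()] alignment.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed (column indices drawn replicate-major from a
#'   single stream).
#' @param ceiling saturation ceiling passed to [jc_distance()].
#' @return the point-estimate NJ tree with `node.label` holding supports in
#'   percent (`NA` for the trivial basal node) and attribute `"bootstrap"`
#'   recording replicates used and skipped.
#' @export
bootstrap_support <- function(aln, replicates = 100, seed = 1, ceiling = 5) {
  stopifnot(replicates >= 1)
  m <- msa_matrix(aln)
  L <- ncol(m)
  point <- nj_tree(jc_distance(aln, ceiling = ceiling))
  trees <- vector("list", replicates)
  skipped <- 0L
  local_seed(seed, {
    for (r in seq_len(replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      tr <- tryCatch(nj_tree(jc_matrix_distance(m[, idx, drop = FALSE],
                                                ceiling = ceiling)),
                     error = function(e) NULL)
      if (is.null(tr)) skipped <- skipped + 1L else trees[[r]] <- tr
    }
  })
  trees <- trees[!vapply(trees, is.null, TRUE)]
  nused <- length(trees)
  if (!nused) stop("all bootstrap replicates failed")
  point_bp <- bipartitions(point)
  counts <- setNames(numeric(length(point_bp)), point_bp)
  for (tr in trees) {
    bp <- bipartitions(tr)
    hit <- point_bp %in% bp
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / nused
  point$node.label <- node_support_labels(point, support)
  attr(point, "bootstrap") <- list(replicates = replicates, used = nused,
                                   skipped = skipped)
  point
}

# map bipartition supports onto internal nodes of an unrooted tree
node_support_labels <- function(tree, support) {
  nt <- ape::Ntip(tree)
  labs <- rep(NA_real_, tree$Nnode)
  tips <- sort(tree$tip.label)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    side <- sort(tips_of(tree, node))
    other <- setdiff(tips, side)
    if (length(side) <= 1L || length(other) <= 1L) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = ",") < paste(other, collapse = ",")))
      side else other
    key <- paste(key, collapse = ",")
    if (key %in% names(support)) labs[node - nt] <- support[[key]]
  }
  labs
}

# jc distance on a raw character matrix (bootstrap inner loop)
jc_matrix_distance <- function(m, ceiling = 5) {
  taxa <- rownames(m)
  n <- nrow(m)
  ok <- !(m == "-" | m == "X" | m == "?")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    nc <- sum(use)
    if (nc == 0L)
      stop("no comparable sites between '", taxa[i], "' and '", taxa[j], "'")
    p <- sum(m[i, use] != m[j, use]) / nc
    d[i, j] <- d[j, i] <- if (p >= 19 / 20) ceiling else
      -(19 / 20) * log(1 - (20 / 19) * p)
  }
  d
}

# run code with a local, restored RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
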