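#' Pair of sequence clusters for functional-divergence analysis
#'
#' @param aln an [msa()] alignment.
#' @param tree [ape::phylo] tree whose leaf set covers both clusters.
#' @param clusterA,clusterB disjoint leaf-label sets, each with at least 4
#'   taxa and monophyletic in `tree`.
#' @param validate check monophyly now (default TRUE).
#' @return object of class `cluster_pair`.
#' @export
cluster_pair <- function(aln, tree, clusterA, clusterB, validate = TRUE) {
  stopifnot(inherits(aln, "msa"), inherits(tree, "phylo"))
  taxa <- msa_taxa(aln)
  for (cl in list(clusterA, clusterB)) {
    if (length(cl) < 4L)
      stop("each cluster needs at least 4 taxa (got ", length(cl), ")")
    if (!all(cl %in% taxa))
      stop("cluster taxa missing from alignment: ",
           paste(setdiff(cl, taxa), collapse = ", "))
    if (!all(cl %in% tree$tip.label))
      stop("cluster taxa missing from tree: ",
           paste(setdiff(cl, tree$tip.label), collapse = ", "))
  }
  if (length(intersect(clusterA, clusterB)))
    stop("clusters must be disjoint")
  if (validate) {
    check_clade(tree, clusterA, "clusterA")
    check_clade(tree, clusterB, "clusterB")
  }
  structure(list(msa = aln, tree = tree, clusterA = clusterA,
                 clusterB = clusterB), class = "cluster_pair")
}

check_clade <- function(tree, taxa, what = "cluster") {
  if (length(taxa) <= 1L) return(invisible(TRUE))
  if (length(setdiff(tree$tip.label, taxa)) == 0L) return(invisible(TRUE))
  tr <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = setdiff(tree$tip.label, taxa)[1],
              resolve.root = TRUE)
  mrca <- ape::getMRCA(tr, taxa)
  clade_tips <- tips_of(tr, mrca)
  extra <- setdiff(clade_tips, taxa)
  comp <- setdiff(tr$tip.label, taxa)
  # a set is a clade of the unrooted tree iff it or its complement is one
  # of the rooted representation
  if (length(extra)) {
    mrca2 <- ape::getMRCA(tr, comp)
    extra2 <- setdiff(tips_of(tr, mrca2), comp)
    if (length(extra2))
      stop(what, " is not monophyletic; offending taxa: ",
           paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Per-site substitution counts by Fitch parsimony
#'
#' For every alignment column and each cluster, computes the minimum number
#' of substitutions on the cluster's subtree (Fitch parsimony, state sets as
#' bit masks). Gaps and `X` are treated as missing: the leaf contributes the
#' full state set and no cost. Columns that are missing in every member of a
#' cluster get count 0 and a mask flag.
#'
#' @param pair a [cluster_pair()].
#' @return object of class `site_counts`: list with integer vectors `X_A`,
#'   `X_B` (length L) and logical `mask_A`, `mask_B`.
#' @export
fitch_counts <- function(pair) {
  stopifnot(inherits(pair, "cluster_pair"))
  m <- msa_matrix(pair$msa)
  a <- fitch_subtree_counts(pair$tree, pair$clusterA, m)
  b <- fitch_subtree_counts(pair$tree, pair$clusterB, m)
  structure(list(X_A = a$counts, X_B = b$counts,
                 mask_A = a$mask, mask_B = b$mask,
                 L = ncol(m)), class = "site_counts")
}

fitch_subtree_counts <- function(tree, taxa, m) {
  sub <- ape::keep.tip(tree, taxa)
  if (!ape::is.binary(sub)) sub <- ape::multi2di(sub)
  sub <- ape::reorder.phylo(sub, "postorder")
  nt <- ape::Ntip(sub)
  L <- ncol(m)
  full <- bitwShiftL(1L, 20L) - 1L  # all 20 states
  aa_bit <- setNames(bitwShiftL(1L, 0:19), AA_STANDARD)
  sets <- matrix(0L, nt + sub$Nnode, L)
  mask_counts <- integer(L)
  for (k in seq_len(nt)) {
    row <- m[sub$tip.label[k], ]
    miss <- row == "-" | row == "X" | row == "?"
    v <- rep(full, L)
    v[!miss] <- aa_bit[row[!miss]]
    sets[k, ] <- v
    mask_counts <- mask_counts + as.integer(miss)
  }
  counts <- integer(L)
  seen <- rep(FALSE, nt + sub$Nnode)
  for (e in seq_len(nrow(sub$edge))) {
    par <- sub$edge[e, 1]; ch <- sub$edge[e, 2]
    if (!seen[par]) {
      sets[par, ] <- sets[ch, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[ch, ])
      empty <- inter == 0L
      counts <- counts + as.integer(empty)
      sets[par, ] <- ifelse(empty, bitwOr(sets[par, ], sets[ch, ]), inter)
    }
  }
  mask <- mask_counts == nt
  counts[mask] <- 0L
  list(counts = counts, mask = mask)
}
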